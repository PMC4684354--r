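#' Pearson correlation matrix of site occupancies across experiments
#'
#' Correlates the 61-codon occupancy vectors of one tRNA binding site
#' between experiments; clustering this matrix separates experimental
#' protocols that report different codon-level dynamics.
#'
#' @param occupancy_tables Named list (>= 2) of [site_occupancies()] tables
#'   or named per-codon numeric vectors.
#' @param site `"A"`, `"P"` or `"E"` (used when tables are data.frames).
#' @return Symmetric Pearson correlation matrix (experiments x experiments,
#'   unit diagonal).
#' @export
experiment_correlation_matrix <- function(occupancy_tables, site = c("A", "P", "E")) {
  site <- match.arg(site)
  if (length(occupancy_tables) < 2L) {
    stop("need at least 2 experiments", call. = FALSE)
  }
  vecs <- lapply(occupancy_tables, function(tb) {
    if (is.data.frame(tb)) stats::setNames(tb[[site]], tb$codon) else tb
  })
  codons <- Reduce(intersect, lapply(vecs, names))
  if (length(codons) < 3L) stop("experiments share too few codons", call. = FALSE)
  m <- sapply(vecs, function(v) v[codons])
  if (any(apply(m, 2, stats::sd, na.rm = TRUE) == 0)) {
    stop("constant occupancy vector: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(m, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' UPGMA clustering of a correlation matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering on Euclidean distances
#' between the rows of the correlation matrix. Rows are ordered
#' lexicographically by label before clustering so the dendrogram is
#' deterministic across platforms.
#'
#' @param matrix Square symmetric numeric matrix with row/column names.
#' @return An `ape::phylo` tree with branch lengths (serialize with
#'   [ape::write.tree()] for newick output). The underlying `hclust` object
#'   is attached as attribute `hclust`.
#' @export
upgma_cluster <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("input must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- colnames(matrix) <- paste0("exp", seq_len(nrow(matrix)))
  }
  ord <- order(rownames(matrix))
  m <- matrix[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Wave-area conservation analysis between two offset profiles
#'
#' For every codon identity, compares a test profile against a reference
#' (a matched unperturbed experiment, or the flat unit baseline when none
#' exists): `delta_binding` is the summed enrichment change at the A-, P-
#' and E-sites (offsets 0, 1, 2); `wave_area` the summed enrichment
#' difference across the downstream `window`; `corrected_aggregate` the
#' test profile's summed binding-site enrichment plus the wave area, an
#' estimate of the codon's total decode-time signature before the
#' perturbation. If the downstream peaks are transient waves fed by the
#' binding-site changes, the ordinary least-squares regression of
#' `wave_area` on `delta_binding` across codons has slope -1.
#'
#' @param profile_test An `OffsetProfile` (the perturbed experiment).
#' @param profile_ref Matched reference `OffsetProfile`, or `NULL` for the
#'   unit baseline (reference enrichment identically 1).
#' @param window Integer `c(d_lo, d_hi)` of downstream offsets; `d_lo >= 3`
#'   so the window cannot overlap the tRNA binding sites. Conventional
#'   presets: `c(6, 65)` for matched pairs, `c(7, 90)` (default) for
#'   single-experiment corrected aggregates.
#' @param exclude_codons Codons left out of the regression (but kept in the
#'   table), e.g. the few extreme-shift codons used for robustness checks.
#' @return List of class `WaveAnalysisResult`: `table` (per-codon
#'   data.frame with `delta_binding`, `wave_area`, `corrected_aggregate`,
#'   `peak_center`, `peak_height`), `regression` (`slope`, `intercept`,
#'   `r_squared`, `n`; `NULL` with a flag when < 3 finite codons) and
#'   `window`.
#' @export
wave_analysis <- function(profile_test, profile_ref = NULL,
                          window = c(7L, 90L), exclude_codons = NULL) {
  stopifnot(inherits(profile_test, "OffsetProfile"))
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2]) {
    stop("`window` must be c(d_lo, d_hi) with d_lo <= d_hi", call. = FALSE)
  }
  if (window[1] < 3L) {
    stop("`window` must not overlap the tRNA binding sites (d_lo >= 3)",
         call. = FALSE)
  }
  need <- as.character(c(0:2, window[1]:window[2]))
  if (!all(need %in% colnames(profile_test$E))) {
    stop("test profile does not cover offsets {0,1,2} and the window", call. = FALSE)
  }
  E_test <- profile_test$E
  if (is.null(profile_ref)) {
    E_ref <- matrix(1, nrow(E_test), ncol(E_test), dimnames = dimnames(E_test))
  } else {
    stopifnot(inherits(profile_ref, "OffsetProfile"))
    if (!all(need %in% colnames(profile_ref$E))) {
      stop("reference profile does not cover offsets {0,1,2} and the window",
           call. = FALSE)
    }
    E_ref <- profile_ref$E[, colnames(E_test), drop = FALSE]
  }
  sites <- as.character(0:2)
  win <- as.character(window[1]:window[2])
  diffs <- E_test - E_ref
  delta_binding <- rowSums(diffs[, sites, drop = FALSE])
  wave_area <- rowSums(diffs[, win, drop = FALSE])
  cae <- rowSums(E_test[, sites, drop = FALSE]) + wave_area
  d_win <- window[1]:window[2]
  pk <- t(vapply(rownames(E_test), function(X) {
    exc <- diffs[X, win]
    pos <- pmax(exc, 0)
    if (all(is.na(exc)) || sum(pos, na.rm = TRUE) <= 0) {
      c(NA_real_, NA_real_)
    } else {
      c(sum(d_win * pos, na.rm = TRUE) / sum(pos, na.rm = TRUE),
        max(exc, na.rm = TRUE))
    }
  }, numeric(2)))
  tab <- data.frame(codon = rownames(E_test),
                    delta_binding = unname(delta_binding),
                    wave_area = unname(wave_area),
                    corrected_aggregate = unname(cae),
                    peak_center = pk[, 1], peak_height = pk[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  fit_tab <- tab[is.finite(tab$delta_binding) & is.finite(tab$wave_area) &
                   !(tab$codon %in% exclude_codons), ]
  if (nrow(fit_tab) >= 3L && stats::sd(fit_tab$delta_binding) > 0) {
    fit <- stats::lm(wave_area ~ delta_binding, data = fit_tab)
    reg <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                r_squared = summary(fit)$r.squared,
                n = nrow(fit_tab))
  } else {
    reg <- NULL
  }
  structure(list(table = tab, regression = reg, window = window),
            class = "WaveAnalysisResult")
}

#' @export
print.WaveAnalysisResult <- function(x, ...) {
  cat("WaveAnalysisResult: window [", x$window[1], ",", x$window[2], "];")
  if (is.null(x$regression)) {
    cat(" regression undefined (< 3 finite codons or constant predictor)\n")
  } else {
    cat(sprintf(" slope = %.3f, r^2 = %.3f (n = %d)\n",
                x$regression$slope, x$regression$r_squared, x$regression$n))
  }
  invisible(x)
}

#' Locate a downstream enrichment peak
#'
#' Centroid-based localization of the positive excess of a codon's offset
#' profile over a baseline: `center` is the excess-weighted mean offset,
#' `height` the maximum excess, `width` the excess-weighted standard
#' deviation. Flagged undefined when the profile never exceeds the baseline
#' in the window.
#'
#' With `support = "window"` every positive excess in the window
#' contributes; in noisy profiles the rectified sampling noise then pulls
#' the centroid toward the window midpoint, so for localization
#' `support = "contiguous"` restricts the weights to the contiguous run of
#' positive excess containing the maximum (the peak proper).
#'
#' @param profile An `OffsetProfile`.
#' @param codon Codon identity (row name).
#' @param window Integer `c(d_lo, d_hi)` inside the profile's offset range.
#' @param baseline Baseline enrichment (default 1).
#' @param support `"window"` (all positive excess) or `"contiguous"` (the
#'   positive run around the maximum).
#' @return List with `center`, `height`, `width`, `defined`.
#' @export
peak_center <- function(profile, codon, window, baseline = 1,
                        support = c("window", "contiguous")) {
  support <- match.arg(support)
  stopifnot(inherits(profile, "OffsetProfile"))
  if (!codon %in% rownames(profile$E)) stop("unknown codon: ", codon, call. = FALSE)
  window <- as.integer(window)
  cols <- as.character(window[1]:window[2])
  if (!all(cols %in% colnames(profile$E))) {
    stop("`window` outside the profile's offset range", call. = FALSE)
  }
  exc <- profile$E[codon, cols] - baseline
  d <- window[1]:window[2]
  pos <- pmax(exc, 0)
  if (all(is.na(exc)) || sum(pos, na.rm = TRUE) <= 0) {
    return(list(center = NA_real_, height = NA_real_, width = NA_real_,
                defined = FALSE))
  }
  if (support == "contiguous") {
    i_max <- which.max(ifelse(is.na(exc), -Inf, exc))
    run <- rep(FALSE, length(pos))
    i <- i_max
    while (i >= 1L && !is.na(pos[i]) && pos[i] > 0) { run[i] <- TRUE; i <- i - 1L }
    i <- i_max + 1L
    while (i <= length(pos) && !is.na(pos[i]) && pos[i] > 0) { run[i] <- TRUE; i <- i + 1L }
    pos[!run] <- 0
  }
  ctr <- sum(d * pos, na.rm = TRUE) / sum(pos, na.rm = TRUE)
  list(center = ctr,
       height = max(exc, na.rm = TRUE),
       width = sqrt(sum(pos * (d - ctr)^2, na.rm = TRUE) / sum(pos, na.rm = TRUE)),
       defined = TRUE)
}
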