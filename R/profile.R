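#' Mean relative enrichment at offsets around each codon identity
#'
#' For each of the 61 sense codon identities X and each offset d, averages
#' the relative enrichment at all included positions p (across all retained
#' genes) such that the codon at p - d is an occurrence of X, with both p
#' and p - d inside the gene's inclusion mask. Positive offsets are
#' downstream of the occurrence (the A-site has moved past the codon);
#' offsets 0, +1 and +2 are the A-, P- and E-site occupancies.
#'
#' @param enrichment A `RelativeEnrichment` from [relative_enrichment()].
#' @param cds The matching [coding_sequence_set()].
#' @param offsets Integer vector of offsets within `[-90, 90]`
#'   (default `-90:90`).
#' @return An object of class `OffsetProfile`: list with matrices `E` (mean
#'   enrichment; `NA` where no positions contribute), `n` (contributing
#'   position counts) and `se` (standard error of the stratum mean), each
#'   61 codons x offsets, plus `offsets`.
#' @export
offset_profile <- function(enrichment, cds, offsets = -90:90) {
  stopifnot(inherits(enrichment, "RelativeEnrichment"),
            inherits(cds, "CodingSequenceSet"))
  offsets <- as.integer(offsets)
  if (any(offsets < -90L | offsets > 90L)) {
    stop("offsets must lie within [-90, 90]", call. = FALSE)
  }
  genes <- names(enrichment$e)
  if (!all(genes %in% cds$gene_ids)) {
    stop("enrichment and CDS sets do not share genes", call. = FALSE)
  }
  sense <- sense_codons()
  pad <- max(91L, max(abs(offsets)) + 1L)
  # Flatten genes with `pad` sentinel positions between them so offset
  # arithmetic can never pair positions from different genes.
  e_all <- c(); cid_all <- c(); mask_all <- c()
  for (g in genes) {
    cid <- match(cds$codons[[g]], sense)
    e_all <- c(e_all, enrichment$e[[g]], rep(NA_real_, pad))
    cid_all <- c(cid_all, cid, rep(NA_integer_, pad))
    mask_all <- c(mask_all, enrichment$mask[[g]], rep(FALSE, pad))
  }
  p_inc <- which(mask_all)
  E <- matrix(NA_real_, 61L, length(offsets),
              dimnames = list(sense, as.character(offsets)))
  n <- matrix(0L, 61L, length(offsets), dimnames = dimnames(E))
  se <- E
  total <- length(mask_all)
  for (j in seq_along(offsets)) {
    d <- offsets[j]
    q <- p_inc - d
    ok <- q >= 1L & q <= total
    ok[ok] <- mask_all[q[ok]]
    p <- p_inc[ok]; q <- q[ok]
    if (!length(p)) next
    f <- factor(cid_all[q], levels = seq_len(61L))
    # rowsum() only emits rows for groups that occur: scatter back to 61
    rs <- rowsum(e_all[p], f)
    rq <- rowsum(e_all[p]^2, f)
    sums <- numeric(61L); sums[as.integer(rownames(rs))] <- rs[, 1]
    sqs <- numeric(61L); sqs[as.integer(rownames(rq))] <- rq[, 1]
    cnt <- as.integer(table(f))
    has <- cnt > 0L
    E[has, j] <- sums[has] / cnt[has]
    n[, j] <- cnt
    v <- rep(NA_real_, 61L)
    ok2 <- cnt > 1L
    v[ok2] <- pmax(sqs[ok2] / cnt[ok2] - (sums[ok2] / cnt[ok2])^2, 0) *
      cnt[ok2] / (cnt[ok2] - 1L)
    se[, j] <- sqrt(v / cnt)
  }
  structure(list(E = E, n = n, se = se, offsets = offsets),
            class = "OffsetProfile")
}

#' @export
print.OffsetProfile <- function(x, ...) {
  cat("OffsetProfile: 61 codons x", length(x$offsets), "offsets (",
      min(x$offsets), "..", max(x$offsets), "); median stratum size",
      stats::median(x$n), "\n")
  invisible(x)
}

#' A-, P- and E-site occupancies from an offset profile
#'
#' The tRNA-binding-site occupancies are the offset-profile columns at
#' offsets 0 (A-site), +1 (P-site) and +2 (E-site).
#'
#' @param profile An `OffsetProfile` covering offsets 0, 1, 2.
#' @return Data.frame with columns `codon`, `A`, `P`, `E` (and standard
#'   errors `A_se`, `P_se`, `E_se`).
#' @export
site_occupancies <- function(profile) {
  stopifnot(inherits(profile, "OffsetProfile"))
  need <- c("0", "1", "2")
  if (!all(need %in% colnames(profile$E))) {
    stop("profile must cover offsets 0, 1 and 2", call. = FALSE)
  }
  data.frame(codon = rownames(profile$E),
             A = profile$E[, "0"], P = profile$E[, "1"], E = profile$E[, "2"],
             A_se = profile$se[, "0"], P_se = profile$se[, "1"],
             E_se = profile$se[, "2"],
             row.names = NULL, stringsAsFactors = FALSE)
}
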