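#' Default wobble pairing penalties for tAI computation
#'
#' Pairing constraints between a codon's third base and an anticodon's first
#' (wobble) base, with selective penalties `s` in `[0, 1]`: Watson-Crick
#' pairings are unpenalized and the four conventional wobble pairings carry
#' the empirical penalties of the standard tAI formulation (anticodon A is
#' treated as inosine, hence the A:C and A:A rows).
#'
#' @return Data.frame with columns `codon_base` (third codon base),
#'   `anticodon_base` (first anticodon base) and `s` (penalty).
#' @export
default_wobble_weights <- function() {
  data.frame(
    codon_base     = c("T", "C", "A", "G", "T",   "C",   "A",      "G"),
    anticodon_base = c("A", "G", "T", "C", "G",   "A",   "A",      "T"),
    s              = c(0,    0,   0,   0,  0.41,  0.28,  0.9999,   0.68),
    stringsAsFactors = FALSE
  )
}

#' Compute the tRNA adaptation index of every sense codon
#'
#' For each codon X, the absolute adaptiveness is the weighted sum over the
#' anticodons that can decode it,
#'   W_X = sum_a (1 - s(pairing)) * tGCN_a,
#' where an anticodon `a` decodes X when its last two bases are the reverse
#' complement of X's first two bases and the (third codon base : first
#' anticodon base) pairing appears in `s_weights`. tAI_X = W_X / max_Y W_Y,
#' so the best-adapted codon scores 1. Codons with no decoding anticodon of
#' positive weight are an error.
#'
#' @param tgcn Named numeric vector of genomic tRNA gene copy numbers,
#'   names = anticodon triplets (DNA alphabet, 5'->3').
#' @param s_weights Penalty table as in [default_wobble_weights()]; all `s`
#'   in `[0, 1]`.
#' @param partial If `TRUE`, return only the codons with `W > 0` (useful for
#'   toy anticodon complements); the default errors when any sense codon is
#'   undecodable, which for a real genome signals a malformed input.
#' @return Data.frame of class `TAITable` with columns `codon`, `W`, `tai`;
#'   the inputs are attached as attributes `tgcn` and `s_weights`.
#' @export
compute_tai <- function(tgcn, s_weights = default_wobble_weights(),
                        partial = FALSE) {
  if (is.null(names(tgcn)) || any(!grepl("^[ACGT]{3}$", names(tgcn)))) {
    stop("`tgcn` must be named by anticodon triplets over A/C/G/T", call. = FALSE)
  }
  if (any(tgcn < 0) || anyNA(tgcn)) stop("copy numbers must be >= 0", call. = FALSE)
  if (any(s_weights$s < 0 | s_weights$s > 1)) {
    stop("penalties `s` must lie in [0, 1]", call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sense <- sense_codons()
  W <- stats::setNames(numeric(length(sense)), sense)
  anticodons <- names(tgcn)
  # body (non-wobble) part of each anticodon: bases 2-3 pair codon bases 2-1
  for (X in sense) {
    xb <- strsplit(X, "")[[1]]
    body <- paste0(comp[xb[2]], comp[xb[1]])   # anticodon positions 2,3
    rows <- s_weights[s_weights$codon_base == xb[3], , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      a <- paste0(rows$anticodon_base[r], body)
      if (a %in% anticodons) {
        W[X] <- W[X] + (1 - rows$s[r]) * tgcn[[a]]
      }
    }
  }
  if (any(W == 0)) {
    if (!partial) {
      stop("no decoding anticodon of positive weight for: ",
           paste(names(W)[W == 0], collapse = ", "), call. = FALSE)
    }
    if (all(W == 0)) stop("no codon is decodable with these inputs", call. = FALSE)
    W <- W[W > 0]
  }
  out <- data.frame(codon = names(W), W = unname(W), tai = unname(W / max(W)),
                    stringsAsFactors = FALSE)
  class(out) <- c("TAITable", "data.frame")
  attr(out, "tgcn") <- tgcn
  attr(out, "s_weights") <- s_weights
  out
}

#' Spearman rank correlation of a per-codon statistic with 1/tAI
#'
#' A positive correlation means codons decoded by scarce or wobble-paired
#' tRNAs carry larger values of the statistic (e.g. take longer to decode);
#' the one-tailed p-value tests for positive association.
#'
#' @param values Named numeric vector of per-codon values (names = codons).
#' @param tai A `TAITable` from [compute_tai()], or a named numeric vector
#'   of tAI values.
#' @return List with `rho`, `p_value` (one-tailed, greater), `n`.
#' @export
spearman_vs_inverse_tai <- function(values, tai) {
  if (inherits(tai, "TAITable")) tai <- stats::setNames(tai$tai, tai$codon)
  common <- intersect(names(values), names(tai))
  v <- values[common]
  inv <- 1 / tai[common]
  keep <- is.finite(v) & is.finite(inv)
  v <- v[keep]; inv <- inv[keep]
  if (length(v) < 4L) stop("need at least 4 codons with finite values", call. = FALSE)
  if (stats::sd(v) == 0 || stats::sd(inv) == 0) {
    stop("constant input: rank correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(v, inv, method = "spearman",
                        alternative = "greater", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = unname(ct$p.value), n = length(v))
}
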