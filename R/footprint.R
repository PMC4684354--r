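#' Assign footprint reads to ribosomal A-site codons
#'
#' Footprints of length 28 or 29 nt are assigned to the in-frame codon closest
#' to the nucleotide at 0-based offset +15 from the read's 5' end; length-30
#' footprints use offset +16. "Closest in-frame codon" means the target
#' nucleotide's position is rounded to the nearest codon start: distances 0
#' and 1 into a codon round down, distance 2 rounds up to the next codon
#' (distances over a 3-nt period are 0/1/2, so no ties exist). In a canonical
#' 28-nt footprint starting at CDS position 0 the A-site is the sixth codon
#' (0-based index 5).
#'
#' @param five_prime_pos Integer vector of 0-based 5'-end positions (nt).
#' @param length_nt Integer vector of read lengths (recycled as needed).
#' @param sense_length Optional integer vector of gene sense lengths (codons);
#'   when supplied, assignments outside `[0, sense_length)` are rejected with
#'   reason `"bounds"`.
#' @return A data.frame with columns `a_site` (0-based codon index, `NA` when
#'   rejected) and `reason` (`""`, `"length"` or `"bounds"`).
#' @export
assign_a_site <- function(five_prime_pos, length_nt, sense_length = NULL) {
  n <- max(length(five_prime_pos), length(length_nt))
  five_prime_pos <- rep_len(as.integer(five_prime_pos), n)
  length_nt <- rep_len(as.integer(length_nt), n)
  if (any(is.na(five_prime_pos)) || any(five_prime_pos < 0L)) {
    stop("`five_prime_pos` must be non-negative", call. = FALSE)
  }
  reason <- character(n)
  a_site <- rep(NA_integer_, n)
  acc <- length_nt %in% c(28L, 29L, 30L)
  reason[!acc] <- "length"
  offset <- ifelse(length_nt == 30L, 16L, 15L)
  target <- five_prime_pos + offset
  idx <- target %/% 3L + as.integer(target %% 3L == 2L)
  a_site[acc] <- idx[acc]
  if (!is.null(sense_length)) {
    sense_length <- rep_len(as.integer(sense_length), n)
    oob <- acc & (a_site < 0L | a_site >= sense_length)
    reason[oob] <- "bounds"
    a_site[oob] <- NA_integer_
  }
  data.frame(a_site = a_site, reason = reason, stringsAsFactors = FALSE)
}

#' Tally A-site read counts per codon position
#'
#' Applies [assign_a_site()] to every read record and accumulates counts into
#' per-gene vectors indexed by 0-based codon position. Reads with unaccepted
#' lengths or out-of-bounds assignments are tallied, not silently dropped:
#' retained + rejected counts always reconcile with the input.
#'
#' @param reads A [footprint_read_set()].
#' @param cds The [coding_sequence_set()] the reads were mapped against.
#' @return An object of class `PositionCounts`: a named list of integer
#'   count vectors (one per gene, length = sense length), with attributes
#'   `total_assigned`, `total_rejected` and `rejections` (a data.frame of
#'   rejected counts by reason and read length).
#' @export
counts_from_reads <- function(reads, cds) {
  validate_reads(reads)
  stopifnot(inherits(cds, "CodingSequenceSet"))
  unknown <- setdiff(unique(reads$gene_id), cds$gene_ids)
  if (length(unknown)) {
    stop("read set refers to gene(s) absent from the CDS set: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  lens <- sense_lengths(cds)
  counts <- lapply(lens, function(L) integer(L))
  if (nrow(reads) == 0L) {
    return(structure(counts, class = "PositionCounts", total_assigned = 0L,
                     total_rejected = 0L,
                     rejections = data.frame(reason = character(), length_nt = integer(),
                                             count = integer())))
  }
  gi <- match(reads$gene_id, cds$gene_ids)
  asn <- assign_a_site(reads$five_prime_pos, reads$length_nt,
                       sense_length = lens[gi])
  ok <- asn$reason == ""
  if (any(ok)) {
    # flat index over concatenated gene vectors
    off <- c(0L, cumsum(lens))[gi[ok]]
    flat <- off + asn$a_site[ok] + 1L
    acc <- rowsum(reads$count[ok], flat)
    flat_counts <- integer(sum(lens))
    flat_counts[as.integer(rownames(acc))] <- as.integer(acc[, 1])
    starts <- c(0L, cumsum(lens))
    for (i in seq_along(lens)) {
      counts[[i]] <- flat_counts[(starts[i] + 1L):starts[i + 1L]]
    }
    names(counts) <- cds$gene_ids
  }
  rej <- data.frame(reason = asn$reason[!ok],
                    length_nt = reads$length_nt[!ok],
                    count = reads$count[!ok])
  rej <- if (nrow(rej)) stats::aggregate(count ~ reason + length_nt, rej, sum) else
    data.frame(reason = character(), length_nt = integer(), count = integer())
  structure(counts, class = "PositionCounts",
            total_assigned = sum(reads$count[ok]),
            total_rejected = sum(reads$count[!ok]),
            rejections = rej)
}

#' @export
print.PositionCounts <- function(x, ...) {
  cat("PositionCounts:", length(x), "genes;",
      attr(x, "total_assigned"), "reads assigned,",
      attr(x, "total_rejected"), "rejected\n")
  invisible(x)
}

#' Per-gene relative enrichments with edge exclusion
#'
#' Within each gene, A-site counts at included (interior) positions are
#' divided by their mean so that the included-position mean enrichment is
#' exactly 1. The first and last `edge_exclusion` codons of every gene are
#' excluded from the mean and carry no enrichment value (to avoid the
#' poorly-understood density structure at CDS ends); 90 is the conventional
#' choice for occupancy work and 200 for downstream wave areas. Genes whose
#' interior is empty or has fewer than `min_included_reads` reads are dropped
#' and logged.
#'
#' @param counts A `PositionCounts` object from [counts_from_reads()].
#' @param edge_exclusion Codons excluded at each end of every gene.
#' @param min_included_reads Minimum total interior reads to retain a gene.
#' @return An object of class `RelativeEnrichment`: list with `e` (named list
#'   of numeric vectors, `NA` outside the inclusion mask), `mask` (named list
#'   of logical vectors), `dropped` (data.frame of gene, reason) and
#'   `edge_exclusion`.
#' @export
relative_enrichment <- function(counts, edge_exclusion = 90L,
                                min_included_reads = 1L) {
  stopifnot(inherits(counts, "PositionCounts"))
  if (!is_count(edge_exclusion, min = 0)) {
    stop("`edge_exclusion` must be a non-negative integer", call. = FALSE)
  }
  e <- list(); mask <- list()
  dropped <- data.frame(gene_id = character(), reason = character())
  for (g in names(counts)) {
    c_g <- counts[[g]]
    L <- length(c_g)
    m <- rep(FALSE, L)
    lo <- edge_exclusion + 1L
    hi <- L - edge_exclusion
    if (hi < lo) {
      dropped <- rbind(dropped, data.frame(gene_id = g, reason = "empty_interior"))
      next
    }
    m[lo:hi] <- TRUE
    tot <- sum(c_g[m])
    if (tot < min_included_reads) {
      dropped <- rbind(dropped, data.frame(gene_id = g, reason = "low_reads"))
      next
    }
    v <- rep(NA_real_, L)
    v[m] <- c_g[m] / mean(c_g[m])
    e[[g]] <- v
    mask[[g]] <- m
  }
  structure(list(e = e, mask = mask, dropped = dropped,
                 edge_exclusion = as.integer(edge_exclusion)),
            class = "RelativeEnrichment")
}

#' @export
print.RelativeEnrichment <- function(x, ...) {
  cat("RelativeEnrichment:", length(x$e), "genes retained,",
      nrow(x$dropped), "dropped; edge exclusion", x$edge_exclusion, "codons\n")
  invisible(x)
}

#' Reads per kilobase of CDS per million mapped reads
#'
#' RPKM_g = (reads_g / (sense_nt_g / 1000)) / (total_reads / 1e6), with
#' sense_nt the length of the sense region in nucleotides.
#'
#' @param counts A `PositionCounts` object.
#' @return Named numeric vector of per-gene RPKM values.
#' @export
gene_rpkm <- function(counts) {
  stopifnot(inherits(counts, "PositionCounts"))
  reads <- vapply(counts, sum, numeric(1))
  total <- sum(reads)
  if (total <= 0) stop("no mapped reads: RPKM undefined", call. = FALSE)
  nt <- vapply(counts, length, numeric(1)) * 3
  (reads / (nt / 1000)) / (total / 1e6)
}
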