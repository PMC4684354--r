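#' Coding sequence sets
#'
#' A `CodingSequenceSet` holds one in-frame coding sequence per gene, split
#' into sense codons plus a single terminal stop codon. It is the coordinate
#' frame for footprint assignment, simulation and all enrichment statistics:
#' codon positions are 0-based indices into the sense codons.
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @param codons List (one element per gene) of character vectors of sense
#'   codons (triplets over A/C/G/T, no stop codons).
#' @param stops Character vector of terminal stop codons, one per gene.
#'
#' @return An object of class `CodingSequenceSet` with elements `gene_ids`,
#'   `codons` (named list of sense-codon vectors) and `stops` (named).
#' @export
coding_sequence_set <- function(gene_ids, codons, stops) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique", call. = FALSE)
  if (length(codons) != length(gene_ids) || length(stops) != length(gene_ids)) {
    stop("`gene_ids`, `codons` and `stops` must have equal length", call. = FALSE)
  }
  sense <- sense_codons()
  stopc <- stop_codons()
  for (i in seq_along(gene_ids)) {
    cv <- codons[[i]]
    if (length(cv) < 1L) {
      stop("gene '", gene_ids[i], "': at least one sense codon required",
           call. = FALSE)
    }
    bad <- !(cv %in% sense)
    if (any(bad)) {
      stop("gene '", gene_ids[i], "': invalid or stop codon in sense region: ",
           paste(unique(cv[bad]), collapse = ", "), call. = FALSE)
    }
    if (!(stops[[i]] %in% stopc)) {
      stop("gene '", gene_ids[i], "': terminal codon '", stops[[i]],
           "' is not a stop codon", call. = FALSE)
    }
  }
  names(codons) <- gene_ids
  stops <- stats::setNames(as.character(stops), gene_ids)
  structure(list(gene_ids = gene_ids, codons = codons, stops = stops),
            class = "CodingSequenceSet")
}

#' @export
print.CodingSequenceSet <- function(x, ...) {
  lens <- sense_lengths(x)
  cat("CodingSequenceSet with", length(x$gene_ids), "genes; sense lengths",
      min(lens), "-", max(lens), "codons\n")
  invisible(x)
}

#' @export
length.CodingSequenceSet <- function(x) length(x$gene_ids)

#' Sense-codon lengths of a CodingSequenceSet
#'
#' @param cds A [coding_sequence_set()].
#' @return Named integer vector of sense lengths (codons, excluding the stop).
#' @export
sense_lengths <- function(cds) {
  stopifnot(inherits(cds, "CodingSequenceSet"))
  vapply(cds$codons, length, integer(1))
}

#' Read coding sequences from a FASTA file
#'
#' Each record must be an in-frame CDS: length divisible by 3, A/C/G/T only,
#' terminating in a stop codon. Internal stop codons are rejected or warned
#' about depending on `internal_stop`.
#'
#' @param path Path to a FASTA file of coding sequences (one record per gene).
#' @param internal_stop `"reject"` (default) to error on internal stop codons,
#'   `"warn"` to drop the offending genes with a warning and keep the rest.
#' @return A [coding_sequence_set()].
#' @export
read_cds_fasta <- function(path, internal_stop = c("reject", "warn")) {
  internal_stop <- match.arg(internal_stop)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- as.character(seqs)
  widths <- nchar(chars)
  if (any(widths %% 3L != 0L)) {
    stop("CDS length not a multiple of 3 for: ",
         paste(ids[widths %% 3L != 0L], collapse = ", "), call. = FALSE)
  }
  if (any(widths < 6L)) {
    stop("CDS shorter than two codons for: ",
         paste(ids[widths < 6L], collapse = ", "), call. = FALSE)
  }
  bad_alpha <- grepl("[^ACGT]", chars)
  if (any(bad_alpha)) {
    stop("non-ACGT characters in: ", paste(ids[bad_alpha], collapse = ", "),
         call. = FALSE)
  }
  codons <- lapply(chars, function(s) {
    substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
  })
  stopc <- stop_codons()
  terminal <- vapply(codons, function(cv) cv[length(cv)], character(1))
  if (any(!(terminal %in% stopc))) {
    stop("missing terminal stop codon for: ",
         paste(ids[!(terminal %in% stopc)], collapse = ", "), call. = FALSE)
  }
  sense <- lapply(codons, function(cv) cv[-length(cv)])
  internal <- vapply(sense, function(cv) any(cv %in% stopc), logical(1))
  if (any(internal)) {
    msg <- paste("internal stop codon in:", paste(ids[internal], collapse = ", "))
    if (internal_stop == "reject") stop(msg, call. = FALSE)
    warning(msg, "; gene(s) dropped", call. = FALSE)
    ids <- ids[!internal]; sense <- sense[!internal]; terminal <- terminal[!internal]
    if (!length(ids)) stop("no genes left after dropping internal-stop records",
                           call. = FALSE)
  }
  coding_sequence_set(ids, sense, terminal)
}

#' Write a CodingSequenceSet as FASTA
#'
#' @param cds A [coding_sequence_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  stopifnot(inherits(cds, "CodingSequenceSet"))
  seqs <- vapply(cds$gene_ids, function(g) {
    paste0(paste(cds$codons[[g]], collapse = ""), cds$stops[[g]])
  }, character(1))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- cds$gene_ids
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}
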