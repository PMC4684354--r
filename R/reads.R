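#' Footprint read sets
#'
#' A `FootprintReadSet` is a table of CDS-mapped ribosome footprints:
#' one row per distinct (gene, 5' position, length) with a count. Positions
#' are 0-based nucleotide offsets of the read's 5' end within the CDS
#' (stop codon included in the coordinate frame).
#'
#' @param gene_id Character vector of gene identifiers.
#' @param five_prime_pos Integer vector, 0-based 5'-end positions (nt).
#' @param length_nt Integer vector of read lengths in nucleotides.
#' @param count Positive integer vector of read counts (default 1).
#' @return A data.frame of class `FootprintReadSet` with columns
#'   `gene_id`, `five_prime_pos`, `length_nt`, `count`.
#' @export
footprint_read_set <- function(gene_id, five_prime_pos, length_nt, count = 1L) {
  df <- data.frame(gene_id = as.character(gene_id),
                   five_prime_pos = as.integer(five_prime_pos),
                   length_nt = as.integer(length_nt),
                   count = as.integer(count),
                   stringsAsFactors = FALSE)
  validate_reads(df)
  class(df) <- c("FootprintReadSet", "data.frame")
  df
}

validate_reads <- function(df, where = "footprint read set") {
  req <- c("gene_id", "five_prime_pos", "length_nt", "count")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(where, ": missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(df$five_prime_pos) | df$five_prime_pos < 0L |
               is.na(df$length_nt) | df$length_nt <= 0L |
               is.na(df$count) | df$count < 1L)
  if (length(bad)) {
    stop(where, ": invalid record at row ", bad[1],
         " (positions must be >= 0, lengths > 0, counts >= 1)", call. = FALSE)
  }
  invisible(df)
}

#' Read or write footprint reads as TSV
#'
#' The TSV format has columns `gene_id`, `five_prime_pos` (0-based nt within
#' the CDS), `length_nt` and `count`. Comment lines starting with `#` are
#' ignored on input and used for provenance headers on output.
#'
#' @param path File path.
#' @return For `read_footprints_tsv`, a [footprint_read_set()].
#' @export
read_footprints_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  validate_reads(df, where = paste0("'", path, "'"))
  footprint_read_set(df$gene_id, df$five_prime_pos, df$length_nt, df$count)
}

#' @rdname read_footprints_tsv
#' @param reads A [footprint_read_set()].
#' @param meta Optional named list written as `# key=value` header lines.
#' @export
write_footprints_tsv <- function(reads, path, meta = NULL) {
  validate_reads(reads)
  write_tsv_with_header(as.data.frame(reads), path, meta)
}

#' Read footprint reads from a SAM file aligned against the CDS FASTA
#'
#' Converts a SAM alignment (reads mapped directly to the coding sequences,
#' not the genome) into a [footprint_read_set()]. Only forward-strand,
#' pure-match alignments are kept: records whose CIGAR contains anything but
#' `M` (soft clips, indels, skips) are rejected and tallied, as are unmapped
#' and reverse-strand records.
#'
#' @param path Path to a SAM file whose reference sequences are CDS ids.
#' @return A [footprint_read_set()] with attribute `rejections`, a named
#'   integer vector of discarded alignment counts by reason.
#' @export
read_footprints_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM input requires the Rsamtools package", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "cigar", "qwidth"))
  a <- Rsamtools::scanBam(bam, param = p)[[1]]
  rej <- c(unmapped = 0L, reverse_strand = 0L, clipped_or_gapped = 0L)
  keep <- !is.na(a$pos)
  rej["unmapped"] <- sum(!keep)
  fwd <- keep & a$strand == "+"
  rej["reverse_strand"] <- sum(keep & !fwd)
  pure <- fwd & grepl("^[0-9]+M$", a$cigar)
  rej["clipped_or_gapped"] <- sum(fwd & !pure)
  if (!any(pure)) stop("no usable alignments in '", path, "'", call. = FALSE)
  key <- data.frame(gene_id = as.character(a$rname[pure]),
                    five_prime_pos = a$pos[pure] - 1L,   # SAM is 1-based
                    length_nt = a$qwidth[pure],
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(key))), key, FUN = sum)
  out <- footprint_read_set(agg$gene_id, agg$five_prime_pos, agg$length_nt, agg$count)
  attr(out, "rejections") <- rej
  out
}

# Shared TSV writer: provenance header ("# key=value") then tab-separated body.
write_tsv_with_header <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (k in names(meta)) {
      writeLines(paste0("# ", k, "=", format(meta[[k]], scientific = FALSE)), con)
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
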