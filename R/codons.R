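#' Sense and stop codons of the standard genetic code
#'
#' `sense_codons()` returns the 61 non-stop codons (DNA alphabet, alphabetical
#' order); `stop_codons()` returns the three stop codons. These define the row
#' space of occupancy tables, dwell-time schemes and offset profiles throughout
#' the package.
#'
#' @return Character vector of codon triplets.
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

#' @rdname sense_codons
#' @export
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == "*"])
}

# Run expr with a temporary RNG state seeded by `seed`; restores the caller's
# RNG so seeded generators never perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a master seed and a stream label.
derive_seed <- function(seed, stream) {
  h <- fnv1a32(paste0(format(seed, scientific = FALSE), "/", stream))
  as.integer(h %% 2147483646) + 1L
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, in double arithmetic
# (exact below 2^53). Used for child-seed derivation and output header hashes.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor for doubles holding 32-bit values (bitwXor() overflows to NA on > 2^31)
bitwXor_dbl <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

fnv1a32_hex <- function(x) {
  h <- fnv1a32(x)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
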