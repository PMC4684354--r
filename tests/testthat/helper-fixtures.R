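# Shared fixtures and oracles, all built in code.

# uniform dwell table with named overrides, e.g. toy_dwells(GCT = 2)
toy_dwells <- function(...) {
  dw <- stats::setNames(rep(1, 61), sense_codons())
  mods <- list(...)
  for (nm in names(mods)) dw[nm] <- mods[[nm]]
  elongation_rates(dw)
}

# single-gene CDS from an explicit codon vector
toy_cds <- function(codons, stop = "TAA", gene_id = "g1") {
  coding_sequence_set(gene_id, list(codons), stop)
}

# synthetic tAI table: log-uniform on [0.1, 1] (spread comparable to real
# genomes, where rare wobble-decoded codons sit an order of magnitude below
# the best-adapted codon)
synthetic_tai <- function(seed = 12) {
  ribowaves:::with_seed(seed, {
    stats::setNames(exp(stats::runif(61, log(0.1), 0)), sense_codons())
  })
}

# brute-force offset profile: literal double loop over genes, positions and
# offsets; the independent oracle for offset_profile()
brute_force_profile <- function(enrichment, cds, offsets) {
  sense <- sense_codons()
  E <- matrix(NA_real_, 61, length(offsets),
              dimnames = list(sense, as.character(offsets)))
  n <- matrix(0L, 61, length(offsets), dimnames = dimnames(E))
  for (j in seq_along(offsets)) {
    d <- offsets[j]
    for (X in sense) {
      vals <- c()
      for (g in names(enrichment$e)) {
        cod <- cds$codons[[g]]
        m <- enrichment$mask[[g]]
        for (p in seq_along(cod)) {          # p is 1-based
          q <- p - d
          if (q >= 1 && q <= length(cod) && m[p] && m[q] && cod[q] == X) {
            vals <- c(vals, enrichment$e[[g]][p])
          }
        }
      }
      if (length(vals)) {
        E[X, j] <- mean(vals)
        n[X, j] <- length(vals)
      }
    }
  }
  list(E = E, n = n)
}

# enrichment/profile pipeline used all over the tests
profile_from_snapshot <- function(snap, cds, edge_exclusion, offsets = 0:65) {
  reads <- snapshot_to_reads(snap, cds, 28L)
  enr <- relative_enrichment(counts_from_reads(reads, cds), edge_exclusion)
  offset_profile(enr, cds, offsets)
}

# The desk-scale study conditions for the matched-pair analyses: a 200-gene
# transcriptome (450-550 sense codons), tAI-anchored pre dwells with
# anticorrelated post dwells, a 15-mean-dwell continued-elongation window
# and 1e6 footprints per sample. Built once and memoized across test files.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_conditions <- function() {
  if (!is.null(.acceptance_cache$cond)) return(.acceptance_cache$cond)
  cds <- generate_transcriptome(200L, c(450L, 550L), seed = 11)
  tai <- synthetic_tai(12)
  scheme <- generate_rate_scheme(tai, anticorrelation = -1, noise_sd = 0.25,
                                 seed = 13)
  .acceptance_cache$cond <- list(cds = cds, tai = tai, scheme = scheme)
  .acceptance_cache$cond
}

acceptance_pair <- function() {
  if (!is.null(.acceptance_cache$pair)) return(.acceptance_cache$pair)
  cond <- acceptance_conditions()
  pair <- generate_experiment_pair(cond$cds, cond$scheme, n_footprints = 1e6,
                                   chx_duration = 15, seed = 14)
  enr_ref <- relative_enrichment(counts_from_reads(pair$no_chx_reads, cond$cds), 200L)
  enr_chx <- relative_enrichment(counts_from_reads(pair$chx_reads, cond$cds), 200L)
  prof_ref <- offset_profile(enr_ref, cond$cds, 0:90)
  prof_chx <- offset_profile(enr_chx, cond$cds, 0:90)
  .acceptance_cache$pair <- list(pair = pair, prof_ref = prof_ref,
                                 prof_chx = prof_chx)
  .acceptance_cache$pair
}
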