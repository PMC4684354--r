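#' Generate a synthetic transcriptome
#'
#' Draws `n_genes` coding sequences with sense lengths uniform on
#' `length_range` and codons sampled i.i.d. from `codon_frequencies`, each
#' terminated by a stop codon. The defaults (450-550 sense codons) leave a
#' usable interior after the 90- and 200-codon edge exclusions used by the
#' enrichment statistics.
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_range Integer vector `c(min, max)` of sense lengths in
#'   codons; `min >= 1`, `max >= min`.
#' @param codon_frequencies Named probability vector over the 61 sense
#'   codons summing to 1 (within 1e-9). Default: uniform.
#' @param seed Integer seed; output is bit-identical for identical inputs.
#' @return A [coding_sequence_set()].
#' @export
generate_transcriptome <- function(n_genes, length_range = c(450L, 550L),
                                   codon_frequencies = NULL, seed = 1L) {
  if (!is_count(n_genes)) stop("`n_genes` must be a positive integer", call. = FALSE)
  length_range <- as.integer(round(length_range))
  if (length(length_range) != 2L || anyNA(length_range) ||
      length_range[1] < 1L || length_range[2] < length_range[1]) {
    stop("`length_range` must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  sense <- sense_codons()
  if (is.null(codon_frequencies)) {
    codon_frequencies <- stats::setNames(rep(1 / 61, 61), sense)
  }
  if (is.null(names(codon_frequencies)) ||
      !setequal(names(codon_frequencies), sense)) {
    stop("`codon_frequencies` must be named over the 61 sense codons", call. = FALSE)
  }
  codon_frequencies <- codon_frequencies[sense]
  if (any(codon_frequencies < 0) || anyNA(codon_frequencies) ||
      abs(sum(codon_frequencies) - 1) > 1e-9) {
    stop("`codon_frequencies` must be non-negative and sum to 1 (tol 1e-9)",
         call. = FALSE)
  }
  stopc <- stop_codons()
  with_seed(seed, {
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_genes, replace = TRUE)
    ids <- sprintf("gene_%04d", seq_len(n_genes))
    codons <- lapply(lens, function(L) {
      sample(sense, L, replace = TRUE, prob = codon_frequencies)
    })
    stops <- sample(stopc, n_genes, replace = TRUE)
    coding_sequence_set(ids, codons, stops)
  })
}

#' Generate a pre/post dwell-time scheme
#'
#' Builds two dwell-time tables emulating the two regimes seen in footprint
#' data: `pre` (undisrupted elongation) is a positive monotone transform of
#' 1/tAI with multiplicative lognormal noise, so that slow codons are those
#' decoded by scarce or wobble-paired tRNAs; `post` (elongation in the
#' presence of the inhibitor) is built by scaling the centred log-dwells of
#' `pre` by `anticorrelation` and adding fresh lognormal noise, so that the
#' rank correlation between `post` and `pre` has the sign (and roughly the
#' strength) of `anticorrelation`. Both tables are normalized to mean dwell 1.
#'
#' @param tai_table Named positive numeric vector of tAI values over the 61
#'   sense codons.
#' @param anticorrelation Number in `[-1, 1]`; -1 mirrors the ranking
#'   (strongly anticorrelated regimes, as observed with CHX), +1 preserves it.
#' @param noise_sd Standard deviation of the lognormal noise (log scale),
#'   >= 0.
#' @param seed Integer seed.
#' @param label Free-text label stored on the scheme.
#' @return A list of class `RateScheme` with elements `pre`, `post`
#'   (both [elongation_rates()]) and `label`.
#' @export
generate_rate_scheme <- function(tai_table, anticorrelation = -1,
                                 noise_sd = 0, seed = 1L, label = "synthetic") {
  sense <- sense_codons()
  if (is.null(names(tai_table)) || !setequal(names(tai_table), sense)) {
    stop("`tai_table` must be named over the 61 sense codons", call. = FALSE)
  }
  tai_table <- tai_table[sense]
  if (any(!is.finite(tai_table)) || any(tai_table <= 0)) {
    stop("tAI values must be strictly positive", call. = FALSE)
  }
  if (!is_number(anticorrelation) || abs(anticorrelation) > 1) {
    stop("`anticorrelation` must be in [-1, 1]", call. = FALSE)
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  with_seed(seed, {
    log_pre <- log(1 / tai_table) + stats::rnorm(61, 0, noise_sd)
    centred <- log_pre - mean(log_pre)
    log_post <- anticorrelation * centred + stats::rnorm(61, 0, noise_sd)
    pre <- exp(log_pre)
    post <- exp(log_post)
    structure(list(pre = elongation_rates(pre / mean(pre)),
                   post = elongation_rates(post / mean(post)),
                   label = label),
              class = "RateScheme")
  })
}

#' @export
print.RateScheme <- function(x, ...) {
  cat("RateScheme '", x$label, "': Spearman(post, pre) = ",
      round(stats::cor(x$pre, x$post, method = "spearman"), 3), "\n", sep = "")
  invisible(x)
}

#' Generate a matched pair of synthetic footprint experiments
#'
#' Produces the study design the wave analysis expects: a reference sample
#' drawn from steady state under `scheme$pre`, and a perturbed sample in
#' which every codon's dwell time is switched to `scheme$post` at time zero
#' and elongation continues for `chx_duration` mean-dwell units before the
#' snapshot (the continued-elongation model of CHX pretreatment). Both
#' snapshots are rendered as 28-nt footprint reads whose 5' ends sit exactly
#' 15 nt upstream of the A-site codon start, so assignment recovers the
#' simulated positions exactly on interior positions.
#'
#' @param cds A [coding_sequence_set()].
#' @param scheme A `RateScheme` from [generate_rate_scheme()].
#' @param n_footprints Ribosomes sampled per experiment (reads can be
#'   slightly fewer: occupancies too close to a CDS edge for a full 28-nt
#'   read are dropped and counted).
#' @param chx_duration Continued-elongation time in mean-dwell units (>= 0;
#'   0 makes the two samples draws from the same distribution).
#' @param seed Integer seed.
#' @param config Optional [sim_config()] (exclusion, engine overrides); its
#'   seed is replaced by `seed`.
#' @return List with elements `no_chx_reads` and `chx_reads`
#'   ([footprint_read_set()]s) plus the `snapshots` used.
#' @export
generate_experiment_pair <- function(cds, scheme, n_footprints,
                                     chx_duration, seed = 1L,
                                     config = sim_config()) {
  stopifnot(inherits(scheme, "RateScheme"))
  if (!is_count(n_footprints)) stop("`n_footprints` must be >= 1", call. = FALSE)
  if (!is_number(chx_duration) || chx_duration < 0) {
    stop("`chx_duration` must be >= 0", call. = FALSE)
  }
  cfg_ref <- config; cfg_ref$seed <- derive_seed(seed, "no-chx")
  cfg_chx <- config; cfg_chx$seed <- derive_seed(seed, "chx")
  snap_ref <- simulate_steady_state(cds, scheme$pre, cfg_ref,
                                    n_ribosomes = n_footprints)
  snap_chx <- simulate_rate_switch(cds, scheme$pre, scheme$post, cfg_chx,
                                   switch_duration = chx_duration,
                                   n_ribosomes = n_footprints)
  list(no_chx_reads = snapshot_to_reads(snap_ref, cds, 28L),
       chx_reads = snapshot_to_reads(snap_chx, cds, 28L),
       snapshots = list(no_chx = snap_ref, chx = snap_chx))
}
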