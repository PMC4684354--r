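#' Codon-specific elongation dwell times
#'
#' An `ElongationRates` object maps each of the 61 sense codons to its mean
#' relative dwell time (the mean of the exponential waiting time a ribosome
#' spends with that codon in its A-site). Rates are the reciprocals of
#' dwells. Relative units with mean dwell 1 over codon usage are
#' recommended, so that simulation time is measured in mean-dwell units.
#'
#' @param dwell Named numeric vector of strictly positive, finite mean dwell
#'   times covering all 61 sense codons.
#' @param normalize If `TRUE`, rescale so the (unweighted) mean dwell is 1.
#' @return Named numeric vector of class `ElongationRates`.
#' @export
elongation_rates <- function(dwell, normalize = FALSE) {
  sense <- sense_codons()
  if (is.null(names(dwell)) || !all(sense %in% names(dwell))) {
    stop("`dwell` must be named and cover all 61 sense codons", call. = FALSE)
  }
  dwell <- dwell[sense]
  if (any(!is.finite(dwell)) || any(dwell <= 0)) {
    stop("dwell times must be strictly positive and finite", call. = FALSE)
  }
  if (normalize) dwell <- dwell / mean(dwell)
  structure(as.numeric(dwell), names = sense, class = "ElongationRates")
}

#' Simulation configuration
#'
#' @param initiation_rate Initiation events per unit time per gene (used to
#'   size steady-state populations and to inject ribosomes during transient
#'   evolution). Must be positive.
#' @param exclusion_footprint Steric exclusion width in codons; 0 (default)
#'   disables exclusion, matching the independent-particle regime in which
#'   steady-state density is exactly proportional to dwell time. When
#'   exclusion is enabled the event-driven engine is used.
#' @param n_cells Number of independent replicate systems for the
#'   event-driven engine; snapshots are pooled.
#' @param burn_in Equilibration time before sampling (event-driven engine).
#' @param seed Integer master seed; all randomness derives from it.
#' @param engine `"auto"` (event-driven iff exclusion > 0), `"stationary"`
#'   (direct draw from the exact stationary law; exclusion must be 0) or
#'   `"event"` (always event-driven).
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(initiation_rate = 0.05, exclusion_footprint = 0L,
                       n_cells = 1L, burn_in = 0, seed = 1L,
                       engine = c("auto", "stationary", "event")) {
  engine <- match.arg(engine)
  if (!is_number(initiation_rate) || initiation_rate <= 0) {
    stop("`initiation_rate` must be > 0", call. = FALSE)
  }
  if (!is_count(exclusion_footprint, min = 0)) {
    stop("`exclusion_footprint` must be a non-negative integer", call. = FALSE)
  }
  if (!is_count(n_cells)) stop("`n_cells` must be a positive integer", call. = FALSE)
  if (!is_number(burn_in) || burn_in < 0) stop("`burn_in` must be >= 0", call. = FALSE)
  structure(list(initiation_rate = initiation_rate,
                 exclusion_footprint = as.integer(exclusion_footprint),
                 n_cells = as.integer(n_cells), burn_in = burn_in,
                 seed = as.integer(seed), engine = engine),
            class = "SimulationConfig")
}

# Flatten a CDS set against a dwell table: per-position dwell vector over the
# concatenation of all genes, plus indexing helpers.
flatten_dwells <- function(cds, rates) {
  stopifnot(inherits(cds, "CodingSequenceSet"))
  rates <- elongation_rates(rates)
  lens <- sense_lengths(cds)
  all_codons <- unlist(cds$codons, use.names = FALSE)
  idx <- match(all_codons, names(rates))
  if (anyNA(idx)) {
    stop("rates table is missing codon(s) present in the CDS set", call. = FALSE)
  }
  list(tau = as.numeric(rates)[idx],
       lens = as.integer(lens),
       starts = c(0L, cumsum(as.integer(lens))),
       gene_ids = cds$gene_ids)
}

new_snapshot <- function(gene_ids, a_site, n_hops = 0, n_terminated = 0) {
  structure(data.frame(gene_id = gene_ids, a_site = as.integer(a_site),
                       stringsAsFactors = FALSE),
            class = c("RibosomeSnapshot", "data.frame"),
            n_hops = n_hops, n_terminated = n_terminated)
}

# Draw `n` A-site positions from the exact stationary law of the open-boundary
# independent-particle model: P(gene g, position i) proportional to dwell.
sample_stationary <- function(fl, n) {
  flat <- sample.int(length(fl$tau), size = n, replace = TRUE, prob = fl$tau)
  gene <- findInterval(flat - 1L, fl$starts, left.open = FALSE)
  list(gene = gene, pos = flat - 1L - fl$starts[gene])
}

# Advance independent ribosomes for per-ribosome remaining times `t_rem`
# under the flattened dwell vector `fl$tau`. Exact jump-process simulation:
# each waiting time is exponential with the current codon's mean dwell
# (memorylessness makes residual waits at t = 0 exponential as well).
# Returns updated local positions, an alive mask (FALSE = terminated) and the
# number of elongation events executed.
advance_ribosomes <- function(gene, pos, t_rem, fl) {
  alive <- rep(TRUE, length(gene))
  n_hops <- 0
  repeat {
    idx <- which(alive & t_rem > 0)
    if (!length(idx)) break
    tau_cur <- fl$tau[fl$starts[gene[idx]] + pos[idx] + 1L]
    w <- stats::rexp(length(idx)) * tau_cur
    move <- w < t_rem[idx]
    stay <- idx[!move]
    t_rem[stay] <- 0
    mv <- idx[move]
    n_hops <- n_hops + length(mv)
    t_rem[mv] <- t_rem[mv] - w[move]
    pos[mv] <- pos[mv] + 1L
    done <- mv[pos[mv] >= fl$lens[gene[mv]]]
    alive[done] <- FALSE
  }
  list(gene = gene, pos = pos, alive = alive, n_hops = n_hops)
}

#' Sample ribosome positions at steady state
#'
#' Draws a snapshot of A-site positions of ribosomes translating `cds` under
#' codon-specific exponential dwell times. With steric exclusion disabled
#' (the default) the open-boundary independent-particle model is exactly
#' solvable -- expected density at a position is proportional to the dwell
#' time of its codon -- and the snapshot is drawn directly from that
#' stationary law. With `exclusion_footprint > 0` (or `engine = "event"`) an
#' exact event-driven (Gillespie) simulation is run per gene and cell,
#' equilibrated for `burn_in`, and sampled at `sample_time`.
#'
#' @param cds A [coding_sequence_set()].
#' @param rates An [elongation_rates()] table.
#' @param config A [sim_config()].
#' @param sample_time Snapshot time for the event-driven engine (default
#'   `config$burn_in`; must be >= it).
#' @param n_ribosomes For the stationary engine: draw exactly this many
#'   ribosomes (default: Poisson with mean `initiation_rate` times the total
#'   expected transit time, the stationary occupancy of the open system).
#' @return A `RibosomeSnapshot`: data.frame with columns `gene_id` and
#'   `a_site` (0-based codon index).
#' @export
simulate_steady_state <- function(cds, rates, config = sim_config(),
                                  sample_time = NULL, n_ribosomes = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  use_event <- config$engine == "event" ||
    (config$engine == "auto" && config$exclusion_footprint > 0L)
  if (config$engine == "stationary" && config$exclusion_footprint > 0L) {
    stop("the stationary engine requires exclusion_footprint = 0", call. = FALSE)
  }
  if (use_event) {
    if (is.null(sample_time)) sample_time <- config$burn_in
    if (!is_number(sample_time) || sample_time < config$burn_in || sample_time < 0) {
      stop("`sample_time` must be >= burn_in and >= 0", call. = FALSE)
    }
    return(sim_event_snapshot(cds, rates, config, t_end = sample_time))
  }
  fl <- flatten_dwells(cds, rates)
  with_seed(derive_seed(config$seed, "steady"), {
    n <- if (is.null(n_ribosomes)) {
      stats::rpois(1, config$initiation_rate * sum(fl$tau))
    } else {
      if (!is_count(n_ribosomes, min = 0)) {
        stop("`n_ribosomes` must be a non-negative integer", call. = FALSE)
      }
      as.integer(n_ribosomes)
    }
    if (n == 0L) {
      new_snapshot(character(), integer())
    } else {
      s <- sample_stationary(fl, n)
      new_snapshot(fl$gene_ids[s$gene], s$pos)
    }
  })
}

#' Simulate a global switch of elongation rates
#'
#' Equilibrates the system under `rates_pre`, switches every codon's dwell
#' time to `rates_post` at time zero, lets elongation continue for
#' `switch_duration` (mean-dwell units), and snapshots all ribosome
#' positions. This is the continued-elongation model of cycloheximide
#' pretreatment: the transient relaxation from the old to the new steady
#' state appears as downstream waves of enrichment or depletion. Ribosomes
#' reaching the stop codon terminate and leave; new ribosomes initiate at
#' codon 0 throughout the window at the stationary flux.
#'
#' `switch_duration = 0` reduces exactly to [simulate_steady_state()] under
#' `rates_pre`.
#'
#' @inheritParams simulate_steady_state
#' @param rates_pre,rates_post [elongation_rates()] before and after the
#'   switch.
#' @param switch_duration Elongation time under `rates_post` before the
#'   snapshot (>= 0, mean-dwell units).
#' @return A `RibosomeSnapshot` (attribute `n_hops` counts elongation events
#'   during the switch window).
#' @export
simulate_rate_switch <- function(cds, rates_pre, rates_post,
                                 config = sim_config(), switch_duration,
                                 n_ribosomes = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is_number(switch_duration) || switch_duration < 0) {
    stop("`switch_duration` must be >= 0", call. = FALSE)
  }
  use_event <- config$engine == "event" ||
    (config$engine == "auto" && config$exclusion_footprint > 0L)
  if (use_event) {
    return(sim_event_snapshot(cds, rates_pre, config,
                              t_end = config$burn_in + switch_duration,
                              t_switch = config$burn_in, rates_post = rates_post))
  }
  fl_pre <- flatten_dwells(cds, rates_pre)
  fl_post <- flatten_dwells(cds, rates_post)
  with_seed(derive_seed(config$seed, "switch"), {
    n <- if (is.null(n_ribosomes)) {
      stats::rpois(1, config$initiation_rate * sum(fl_pre$tau))
    } else {
      as.integer(n_ribosomes)
    }
    if (n == 0L) {
      new_snapshot(character(), integer())
    } else {
      s <- sample_stationary(fl_pre, n)
      gene <- s$gene; pos <- s$pos
      t_rem <- rep(switch_duration, n)
      # per-gene initiation rate implied by the sampled stationary population:
      # E[N] = J * total expected transit time, so J = N / sum(tau)
      J <- n / sum(fl_pre$tau)
      k_new <- if (switch_duration > 0) {
        stats::rpois(1, J * switch_duration * length(fl_pre$lens))
      } else 0L
      if (k_new > 0L) {
        gene_new <- sample.int(length(fl_pre$lens), k_new, replace = TRUE)
        gene <- c(gene, gene_new)
        pos <- c(pos, integer(k_new))
        t_rem <- c(t_rem, stats::runif(k_new, 0, switch_duration))
      }
      adv <- advance_ribosomes(gene, pos, t_rem, fl_post)
      keep <- adv$alive
      new_snapshot(fl_post$gene_ids[adv$gene[keep]], adv$pos[keep],
                   n_hops = adv$n_hops, n_terminated = sum(!keep))
    }
  })
}

#' Simulate the instantaneous-arrest null model
#'
#' Each ribosome elongates under unchanged rates until its own exponentially
#' distributed arrest time (rate `arrest_rate`), then freezes; the snapshot
#' is taken after every ribosome has arrested. Because the position of a
#' ribosome at an exponential random time samples the same stationary
#' distribution it occupied before the drug arrived, this null model
#' produces neither downstream peaks nor substantial changes in A-site
#' occupancies -- the signature that distinguishes it from the
#' continued-elongation model of [simulate_rate_switch()]. Ribosomes that
#' reach the stop codon before arresting terminate and are absent from the
#' snapshot; initiation after drug arrival is not modelled (with ongoing
#' initiation "all ribosomes arrested" never happens).
#'
#' @inheritParams simulate_steady_state
#' @param arrest_rate Arrest events per unit time per ribosome (> 0).
#' @return A `RibosomeSnapshot`.
#' @export
simulate_exponential_arrest <- function(cds, rates, arrest_rate,
                                        config = sim_config(),
                                        n_ribosomes = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.numeric(arrest_rate) || length(arrest_rate) != 1L ||
      is.na(arrest_rate) || arrest_rate <= 0) {
    stop("`arrest_rate` must be > 0", call. = FALSE)
  }
  fl <- flatten_dwells(cds, rates)
  with_seed(derive_seed(config$seed, "arrest"), {
    n <- if (is.null(n_ribosomes)) {
      stats::rpois(1, config$initiation_rate * sum(fl$tau))
    } else {
      as.integer(n_ribosomes)
    }
    if (n == 0L) {
      new_snapshot(character(), integer())
    } else {
      s <- sample_stationary(fl, n)
      t_rem <- if (is.finite(arrest_rate)) stats::rexp(n, arrest_rate) else numeric(n)
      adv <- advance_ribosomes(s$gene, s$pos, t_rem, fl)
      keep <- adv$alive
      new_snapshot(fl$gene_ids[adv$gene[keep]], adv$pos[keep],
                   n_hops = adv$n_hops, n_terminated = sum(!keep))
    }
  })
}

#' Render a ribosome snapshot as footprint reads
#'
#' Each ribosome occupancy emits one read of `read_length` nucleotides whose
#' 5' end is placed 15 nt upstream of the A-site codon start, so that the
#' standard assignment rule ([assign_a_site()]: offset +15 for lengths 28/29,
#' +16 for length 30) recovers the simulated position exactly. Occupancies
#' too close to a CDS edge for a full read are dropped and counted.
#'
#' @param snapshot A `RibosomeSnapshot`.
#' @param cds The [coding_sequence_set()] that was simulated.
#' @param read_length Footprint length in nt; one of 28, 29, 30.
#' @return A [footprint_read_set()] with attribute `n_dropped`.
#' @export
snapshot_to_reads <- function(snapshot, cds, read_length = 28L) {
  stopifnot(inherits(snapshot, "RibosomeSnapshot"),
            inherits(cds, "CodingSequenceSet"))
  if (!read_length %in% c(28L, 29L, 30L)) {
    stop("`read_length` must be 28, 29 or 30", call. = FALSE)
  }
  lens <- sense_lengths(cds)
  gi <- match(snapshot$gene_id, cds$gene_ids)
  if (anyNA(gi)) stop("snapshot refers to genes absent from `cds`", call. = FALSE)
  five_prime <- 3L * snapshot$a_site - 15L
  cds_nt <- 3L * (lens[gi] + 1L)   # sense + stop
  ok <- five_prime >= 0L & (five_prime + read_length) <= cds_nt
  n_dropped <- sum(!ok)
  if (!any(ok)) {
    out <- footprint_read_set(character(), integer(), integer(), integer())
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  key <- paste(snapshot$gene_id[ok], five_prime[ok], sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- footprint_read_set(vapply(parts, `[`, character(1), 1L),
                            as.integer(vapply(parts, `[`, character(1), 2L)),
                            read_length,
                            as.integer(tab))
  attr(out, "n_dropped") <- n_dropped
  out
}

# ---- event-driven (Gillespie) engine -------------------------------------

# Exact simulation of one gene in one cell. Positions are 0-based A-site
# codon indices, kept in increasing order. With exclusion ef > 0, a ribosome
# may hop only if the next ribosome ahead is more than ef codons away, and
# initiation requires the first ef codons to be free; ef = 0 disables both
# constraints (independent particles). Rates may switch once at t_switch.
sim_gillespie_gene <- function(tau, J, ef, t_end, t_switch = Inf,
                               tau_post = NULL) {
  L <- length(tau)
  cur_tau <- tau
  switched <- !is.finite(t_switch)
  pos <- integer(0)
  t <- 0
  repeat {
    n <- length(pos)
    can_init <- ef == 0L || n == 0L || pos[1] >= ef
    if (n > 0L) {
      gap_ok <- if (ef == 0L) rep(TRUE, n) else c(diff(pos) > ef, TRUE)
      r <- ifelse(gap_ok, 1 / cur_tau[pos + 1L], 0)
    } else r <- numeric(0)
    rates <- c(r, if (can_init) J else 0)
    R <- sum(rates)
    if (R <= 0) {
      t <- t_end
    } else {
      dt <- stats::rexp(1, R)
      if (!switched && t + dt >= t_switch) {
        # exponential clocks are memoryless: jump to the boundary and redraw
        t <- t_switch
        cur_tau <- tau_post
        switched <- TRUE
        next
      }
      t <- t + dt
    }
    if (t >= t_end) break
    ev <- sample.int(length(rates), 1L, prob = rates)
    if (ev > n) {
      pos <- c(0L, pos)
    } else {
      pos[ev] <- pos[ev] + 1L
      if (pos[ev] >= L) pos <- pos[-ev]
    }
  }
  pos
}

sim_event_snapshot <- function(cds, rates, config, t_end, t_switch = Inf,
                               rates_post = NULL) {
  fl <- flatten_dwells(cds, rates)
  fl_post <- if (!is.null(rates_post)) flatten_dwells(cds, rates_post)
  genes <- seq_along(fl$gene_ids)
  out_gene <- list(); out_pos <- list(); out_cell <- list(); k <- 0L
  for (cell in seq_len(config$n_cells)) {
    cell_seed <- derive_seed(config$seed, paste0("cell", cell))
    with_seed(cell_seed, {
      for (g in genes) {
        rng <- (fl$starts[g] + 1L):fl$starts[g + 1L]
        pos <- sim_gillespie_gene(fl$tau[rng], config$initiation_rate,
                                  config$exclusion_footprint, t_end, t_switch,
                                  if (!is.null(fl_post)) fl_post$tau[rng])
        if (length(pos)) {
          k <- k + 1L
          out_gene[[k]] <- rep(fl$gene_ids[g], length(pos))
          out_pos[[k]] <- pos
          out_cell[[k]] <- rep(cell, length(pos))
        }
      }
    })
  }
  snap <- new_snapshot(unlist(out_gene) %||% character(),
                       unlist(out_pos) %||% integer())
  snap$cell <- unlist(out_cell) %||% integer()
  snap
}

`%||%` <- function(a, b) if (is.null(a)) b else a
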