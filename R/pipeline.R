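#' Read or write a codon dwell-time table as TSV
#'
#' Two columns: `codon`, `dwell`.
#'
#' @param path File path.
#' @return For the reader, an [elongation_rates()] vector.
#' @export
read_rates_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("codon", "dwell") %in% names(df))) {
    stop("'", path, "': expected columns codon, dwell", call. = FALSE)
  }
  elongation_rates(stats::setNames(df$dwell, df$codon))
}

#' @rdname read_rates_tsv
#' @param rates An [elongation_rates()] vector.
#' @param meta Optional named list of header fields.
#' @export
write_rates_tsv <- function(rates, path, meta = NULL) {
  rates <- elongation_rates(rates)
  write_tsv_with_header(data.frame(codon = names(rates), dwell = as.numeric(rates)),
                        path, meta)
}

#' Export an offset profile as a long-format TSV
#'
#' @param profile An `OffsetProfile`.
#' @param path File path.
#' @param meta Optional named list of header fields.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, meta = NULL) {
  stopifnot(inherits(profile, "OffsetProfile"))
  long <- data.frame(codon = rep(rownames(profile$E), times = ncol(profile$E)),
                     offset = rep(profile$offsets, each = nrow(profile$E)),
                     enrichment = as.vector(profile$E),
                     n = as.vector(profile$n),
                     se = as.vector(profile$se))
  write_tsv_with_header(long, path, meta)
}

pipeline_meta <- function(params) {
  flat <- paste(names(params), vapply(params, function(p)
    paste(format(p, scientific = FALSE), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  list(tool = paste0("ribowaves ", as.character(utils::packageVersion("ribowaves"))),
       seed = params$seed %||% NA,
       params_hash = fnv1a32_hex(flat))
}

#' Run an end-to-end analysis stage
#'
#' Thin orchestration over the package's functions, writing deterministic,
#' provenance-stamped TSV outputs (every file carries tool version, seed and
#' a parameter hash in `#`-comment headers).
#'
#' Modes:
#' \describe{
#'   \item{`synthetic-pair`}{Generate a transcriptome, a pre/post dwell
#'     scheme and a matched no-CHX/CHX experiment pair, then run the full
#'     wave analysis. Parameters: `n_genes`, `length_range`, `n_footprints`,
#'     `chx_duration`, `anticorrelation`, `noise_sd`, `edge_exclusion`,
#'     `window`, `seed`.}
#'   \item{`analyze`}{Analyze existing data: `cds_fasta`, `reads_tsv`
#'     (optionally `ref_reads_tsv` for a matched reference),
#'     `edge_exclusion`, `window`.}
#'   \item{`simulate`}{Simulate footprints from `cds_fasta` and
#'     `rates_pre_tsv` (optionally `rates_post_tsv` + `duration` for a rate
#'     switch, or `arrest_rate` for the arrest null), `n_footprints`, `seed`.}
#'   \item{`analytic`}{Integrate the master-equation wave model:
#'     `dwell_old`, `dwell_new` (vectors), `flux`, `times`.}
#' }
#'
#' @param config Named list of parameters (see modes above), or the path to
#'   a YAML file holding one.
#' @param mode One of `"synthetic-pair"`, `"analyze"`, `"simulate"`,
#'   `"analytic"`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of result objects; output file paths in
#'   `$files`.
#' @export
run_pipeline <- function(config, mode = c("synthetic-pair", "analyze",
                                          "simulate", "analytic"),
                         out_dir = ".") {
  mode <- match.arg(mode)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a config file requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  cfg <- function(key, default = NULL) config[[key]] %||% default
  meta <- pipeline_meta(c(config, list(mode = mode)))
  files <- character(0)
  res <- switch(
    mode,
    "synthetic-pair" = {
      seed <- cfg("seed", 1L)
      cds <- generate_transcriptome(cfg("n_genes", 200L),
                                    cfg("length_range", c(450L, 550L)),
                                    cfg("codon_frequencies"),
                                    seed = derive_seed(seed, "transcriptome"))
      tai <- cfg("tai")
      if (is.null(tai)) {
        tai <- with_seed(derive_seed(seed, "tai"), {
          stats::setNames(exp(stats::runif(61, log(0.1), 0)), sense_codons())
        })
      }
      scheme <- generate_rate_scheme(tai, cfg("anticorrelation", -1),
                                     cfg("noise_sd", 0.25),
                                     seed = derive_seed(seed, "scheme"))
      pair <- generate_experiment_pair(cds, scheme,
                                       cfg("n_footprints", 1e6),
                                       cfg("chx_duration", 15),
                                       seed = derive_seed(seed, "pair"))
      ee <- cfg("edge_exclusion", 200L)
      win <- cfg("window", c(6L, 65L))
      offsets <- 0:max(90L, win[2])
      enr_ref <- relative_enrichment(counts_from_reads(pair$no_chx_reads, cds), ee)
      enr_chx <- relative_enrichment(counts_from_reads(pair$chx_reads, cds), ee)
      prof_ref <- offset_profile(enr_ref, cds, offsets)
      prof_chx <- offset_profile(enr_chx, cds, offsets)
      wa <- wave_analysis(prof_chx, prof_ref, window = win)
      write_cds_fasta(cds, pth("cds.fasta"))
      write_footprints_tsv(pair$no_chx_reads, pth("no_chx_reads.tsv"), meta)
      write_footprints_tsv(pair$chx_reads, pth("chx_reads.tsv"), meta)
      write_rates_tsv(scheme$pre, pth("rates_pre.tsv"), meta)
      write_rates_tsv(scheme$post, pth("rates_post.tsv"), meta)
      write_profile_tsv(prof_chx, pth("profile_chx.tsv"), meta)
      write_tsv_with_header(wa$table, pth("wave_analysis.tsv"), meta)
      files <- pth(c("cds.fasta", "no_chx_reads.tsv", "chx_reads.tsv",
                     "rates_pre.tsv", "rates_post.tsv", "profile_chx.tsv",
                     "wave_analysis.tsv"))
      list(cds = cds, scheme = scheme, tai = tai, pair = pair,
           profiles = list(no_chx = prof_ref, chx = prof_chx), wave = wa)
    },
    "analyze" = {
      cds <- read_cds_fasta(cfg("cds_fasta") %||% stop("analyze mode needs `cds_fasta`", call. = FALSE))
      reads <- read_footprints_tsv(cfg("reads_tsv") %||% stop("analyze mode needs `reads_tsv`", call. = FALSE))
      ee <- cfg("edge_exclusion", 90L)
      win <- cfg("window", c(7L, 90L))
      counts <- counts_from_reads(reads, cds)
      enr <- relative_enrichment(counts, ee)
      prof <- offset_profile(enr, cds, cfg("offsets", -90:90))
      occ <- site_occupancies(prof)
      ref <- NULL
      if (!is.null(cfg("ref_reads_tsv"))) {
        enr_ref <- relative_enrichment(
          counts_from_reads(read_footprints_tsv(cfg("ref_reads_tsv")), cds), ee)
        ref <- offset_profile(enr_ref, cds, cfg("offsets", -90:90))
      }
      wa <- wave_analysis(prof, ref, window = win)
      write_profile_tsv(prof, pth("profile.tsv"), meta)
      write_tsv_with_header(occ, pth("occupancy.tsv"), meta)
      write_tsv_with_header(wa$table, pth("wave_analysis.tsv"), meta)
      write_tsv_with_header(
        data.frame(gene_id = names(counts), rpkm = gene_rpkm(counts)),
        pth("rpkm.tsv"), meta)
      files <- pth(c("profile.tsv", "occupancy.tsv", "wave_analysis.tsv", "rpkm.tsv"))
      list(counts = counts, enrichment = enr, profile = prof,
           occupancy = occ, wave = wa)
    },
    "simulate" = {
      cds <- read_cds_fasta(cfg("cds_fasta") %||% stop("simulate mode needs `cds_fasta`", call. = FALSE))
      pre <- read_rates_tsv(cfg("rates_pre_tsv") %||% stop("simulate mode needs `rates_pre_tsv`", call. = FALSE))
      config_sim <- sim_config(seed = cfg("seed", 1L))
      nfp <- cfg("n_footprints", 1e5)
      snap <- if (!is.null(cfg("arrest_rate"))) {
        simulate_exponential_arrest(cds, pre, cfg("arrest_rate"), config_sim,
                                    n_ribosomes = nfp)
      } else if (!is.null(cfg("rates_post_tsv"))) {
        simulate_rate_switch(cds, pre, read_rates_tsv(cfg("rates_post_tsv")),
                             config_sim, cfg("duration", 15), n_ribosomes = nfp)
      } else {
        simulate_steady_state(cds, pre, config_sim, n_ribosomes = nfp)
      }
      reads <- snapshot_to_reads(snap, cds, cfg("read_length", 28L))
      write_footprints_tsv(reads, pth("simulated_reads.tsv"), meta)
      files <- pth("simulated_reads.tsv")
      list(snapshot = snap, reads = reads)
    },
    "analytic" = {
      traj <- evolve_density(cfg("dwell_old") %||% stop("analytic mode needs `dwell_old`", call. = FALSE),
                             cfg("dwell_new") %||% stop("analytic mode needs `dwell_new`", call. = FALSE),
                             cfg("flux", 1),
                             cfg("times") %||% stop("analytic mode needs `times`", call. = FALSE))
      ws <- wave_summary(traj)
      dens <- data.frame(time = rep(traj$times, each = length(traj$positions)),
                         position = rep(traj$positions, times = length(traj$times)),
                         density = as.vector(t(traj$density)))
      write_tsv_with_header(dens, pth("density.tsv"), meta)
      write_tsv_with_header(ws, pth("wave_summary.tsv"), meta)
      files <- pth(c("density.tsv", "wave_summary.tsv"))
      list(trajectory = traj, summary = ws)
    })
  c(res, list(files = files, meta = meta))
}
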