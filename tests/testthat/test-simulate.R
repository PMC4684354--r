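test_that("stationary snapshots reproduce the closed-form steady state", {
  # 3-position toy gene with dwells 1, 2, 4: occupancy 1/7 : 2/7 : 4/7
  cds <- toy_cds(c("AAA", "GCT", "CGA"))
  rates <- toy_dwells(GCT = 2, CGA = 4)
  snap <- simulate_steady_state(cds, rates, sim_config(seed = 1),
                                n_ribosomes = 1e5)
  prop <- tabulate(snap$a_site + 1L, 3) / 1e5
  expected <- c(1, 2, 4) / 7
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_true(all(abs(prop - expected) <= 3 * se))
  # near-zero initiation rate: empty snapshot, no error
  tiny <- simulate_steady_state(cds, rates, sim_config(initiation_rate = 1e-9,
                                                       seed = 2))
  expect_equal(nrow(tiny), 0)
})

test_that("the event-driven engine relaxes to density proportional to dwell time", {
  # non-circular check of the stationary law: a genuine Gillespie run on an
  # alternating gene must give slow:fast occupancy ratio = 2
  cod <- rep(c("AAA", "GCT"), length.out = 21)
  cds <- toy_cds(cod)
  rates <- toy_dwells(GCT = 2)
  cfg <- sim_config(initiation_rate = 0.3, n_cells = 150, burn_in = 100,
                    seed = 5, engine = "event")
  snap <- simulate_steady_state(cds, rates, cfg)
  tab <- tabulate(snap$a_site + 1L, 21)
  n_slow <- sum(tab[cod == "GCT"]); n_fast <- sum(tab[cod == "AAA"])
  ratio <- (n_slow / sum(cod == "GCT")) / (n_fast / sum(cod == "AAA"))
  # binomial SE on the slow fraction propagated to the ratio
  p <- n_slow / (n_slow + n_fast)
  se_p <- sqrt(p * (1 - p) / (n_slow + n_fast))
  expect_true(abs(p - 2 * 10 / (2 * 10 + 11)) <= 3 * se_p)
  expect_gt(ratio, 1.6); expect_lt(ratio, 2.5)
})

test_that("steric exclusion keeps same-gene ribosomes separated", {
  cds <- toy_cds(rep("GCT", 40))
  cfg <- sim_config(initiation_rate = 0.5, exclusion_footprint = 5L,
                    n_cells = 30, burn_in = 60, seed = 6)
  snap <- simulate_steady_state(cds, toy_dwells(), cfg)
  expect_gt(nrow(snap), 0)
  for (cell in unique(snap$cell)) {
    pos <- sort(snap$a_site[snap$cell == cell])
    if (length(pos) > 1) expect_true(all(diff(pos) >= 5L))
  }
})

test_that("a zero-duration switch reduces to the pre-switch steady state", {
  cds <- toy_cds(rep(c("AAA", "GCT", "CGA"), 20))
  pre <- toy_dwells(GCT = 2, CGA = 4)
  post <- toy_dwells(GCT = 0.5)
  s0 <- simulate_rate_switch(cds, pre, post, sim_config(seed = 7),
                             switch_duration = 0, n_ribosomes = 5e4)
  ss <- simulate_steady_state(cds, pre, sim_config(seed = 8), n_ribosomes = 5e4)
  t0 <- tabulate(s0$a_site + 1L, 60) / nrow(s0)
  t1 <- tabulate(ss$a_site + 1L, 60) / nrow(ss)
  se <- sqrt(t1 * (1 - t1) / 5e4)
  expect_true(all(abs(t0 - t1) <= 4 * pmax(se, 1e-4) * sqrt(2)))
})

test_that("a long switch converges to the post-switch steady state", {
  cds <- toy_cds(rep(c("AAA", "GCT"), 15))
  pre <- toy_dwells(GCT = 4)
  post <- toy_dwells(GCT = 0.5)
  snap <- simulate_rate_switch(cds, pre, post, sim_config(seed = 9),
                               switch_duration = 200, n_ribosomes = 4e4)
  tab <- tabulate(snap$a_site + 1L, 30)
  p_slow <- sum(tab[seq(2, 30, 2)]) / sum(tab)
  expected <- 0.5 / (1 + 0.5)   # post dwells: 1 vs 0.5
  se <- sqrt(expected * (1 - expected) / sum(tab))
  expect_true(abs(p_slow - expected) <= 4 * se)
})

test_that("elongation event counts match duration over mean dwell", {
  cds <- generate_transcriptome(20, c(300L, 350L), seed = 10)
  rates <- toy_dwells()   # all dwells 1
  snap <- simulate_rate_switch(cds, rates, rates, sim_config(seed = 11),
                               switch_duration = 12, n_ribosomes = 2e4)
  hops_per_ribosome <- attr(snap, "n_hops") / 2e4
  expect_equal(hops_per_ribosome, 12, tolerance = 0.05)
})

test_that("exponential arrest leaves the steady-state occupancies unchanged", {
  cds <- generate_transcriptome(30, c(200L, 250L), seed = 12)
  sch <- generate_rate_scheme(synthetic_tai(13), -1, 0.2, seed = 14)
  ss <- simulate_steady_state(cds, sch$pre, sim_config(seed = 15),
                              n_ribosomes = 2e5)
  ar <- simulate_exponential_arrest(cds, sch$pre, arrest_rate = 0.1,
                                    sim_config(seed = 16), n_ribosomes = 2e5)
  p1 <- profile_from_snapshot(ss, cds, 60L, 0:65)
  p2 <- profile_from_snapshot(ar, cds, 60L, 0:65)
  z <- (p2$E[, "0"] - p1$E[, "0"]) / sqrt(p2$se[, "0"]^2 + p1$se[, "0"]^2)
  expect_true(all(abs(z) <= 4))
  # no downstream structure either: window-mean flatness per codon
  win <- as.character(6:65)
  wmean <- rowMeans(p2$E[, win]) - rowMeans(p1$E[, win])
  wse <- sqrt(rowSums(p2$se[, win]^2) + rowSums(p1$se[, win]^2)) / length(win)
  expect_true(all(abs(wmean / wse) <= 4, na.rm = TRUE))
  # instant arrest is exactly a stationary draw
  inst <- simulate_exponential_arrest(cds, sch$pre, arrest_rate = Inf,
                                      sim_config(seed = 17), n_ribosomes = 1e4)
  expect_equal(attr(inst, "n_hops"), 0)
  expect_error(simulate_exponential_arrest(cds, sch$pre, 0, sim_config()),
               "> 0")
})

test_that("wave mass is conserved over a window covering the traveled distance", {
  # single perturbed codon: total excess downstream must offset the
  # binding-site loss once the window extends past the wave
  cod <- rep("CCA", 301); cod[151] <- "GCG"
  cds <- coding_sequence_set(paste0("g", 1:40), rep(list(cod), 40),
                             rep("TAA", 40))
  pre <- toy_dwells(GCG = 4); post <- toy_dwells(GCG = 0.5)
  ref <- simulate_steady_state(cds, pre, sim_config(seed = 18), n_ribosomes = 3e5)
  sw <- simulate_rate_switch(cds, pre, post, sim_config(seed = 19),
                             switch_duration = 10, n_ribosomes = 3e5)
  pr <- profile_from_snapshot(ref, cds, 90L, 0:60)
  pc <- profile_from_snapshot(sw, cds, 90L, 0:60)
  d_all <- as.character(0:60)
  total <- sum(pc$E["GCG", d_all] - pr$E["GCG", d_all])
  se_tot <- sqrt(sum(pc$se["GCG", d_all]^2 + pr$se["GCG", d_all]^2))
  expect_lt(abs(total), 4 * se_tot)
  # and the wave itself is real: binding-site change is strongly negative
  delta_bind <- sum(pc$E["GCG", as.character(0:2)] - pr$E["GCG", as.character(0:2)])
  expect_lt(delta_bind, -1)
})

test_that("snapshots render to reads that invert the assignment rule", {
  cds <- toy_cds(rep("GCT", 30))
  snap <- structure(data.frame(gene_id = rep("g1", 3), a_site = c(5L, 10L, 0L)),
                    class = c("RibosomeSnapshot", "data.frame"))
  r28 <- snapshot_to_reads(snap, cds, 28L)
  # a_site 5 -> five_prime 0; a_site 0 would start upstream -> dropped
  expect_equal(attr(r28, "n_dropped"), 1L)
  expect_setequal(r28$five_prime_pos, c(0L, 15L))
  expect_equal(assign_a_site(0, 28)$a_site, 5L)
  # length 30: 5' end placed so the +16 rule recovers the position
  r30 <- snapshot_to_reads(snap, cds, 30L)
  fp5 <- r30$five_prime_pos[r30$five_prime_pos == 0L]
  expect_length(fp5, 1)
  expect_equal(assign_a_site(0, 30)$a_site, 5L)
  expect_error(snapshot_to_reads(snap, cds, 31L), "28, 29 or 30")
})

test_that("simulations are bit-identical under a fixed seed", {
  cds <- generate_transcriptome(5, c(80L, 100L), seed = 20)
  sch <- generate_rate_scheme(synthetic_tai(21), -1, 0.1, seed = 22)
  a <- simulate_rate_switch(cds, sch$pre, sch$post, sim_config(seed = 23), 7,
                            n_ribosomes = 5e3)
  b <- simulate_rate_switch(cds, sch$pre, sch$post, sim_config(seed = 23), 7,
                            n_ribosomes = 5e3)
  expect_identical(a, b)
  c1 <- simulate_exponential_arrest(cds, sch$pre, 0.2, sim_config(seed = 24),
                                    n_ribosomes = 5e3)
  c2 <- simulate_exponential_arrest(cds, sch$pre, 0.2, sim_config(seed = 24),
                                    n_ribosomes = 5e3)
  expect_identical(c1, c2)
  ev1 <- simulate_steady_state(toy_cds(rep("GCT", 15)), toy_dwells(),
                               sim_config(n_cells = 5, burn_in = 30, seed = 25,
                                          engine = "event"))
  ev2 <- simulate_steady_state(toy_cds(rep("GCT", 15)), toy_dwells(),
                               sim_config(n_cells = 5, burn_in = 30, seed = 25,
                                          engine = "event"))
  expect_identical(ev1, ev2)
})
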