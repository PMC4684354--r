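test_that("tAI weights follow the penalized sum over decoding anticodons", {
  # one perfectly decoded codon: GCT is read by AGC (Watson-Crick wobble A:T)
  tgcn <- c(AGC = 10)
  tai <- compute_tai(tgcn, data.frame(codon_base = "T", anticodon_base = "A",
                                      s = 0), partial = TRUE)
  expect_equal(tai$tai[tai$codon == "GCT"], 1)
  # incomplete anticodon complements are an error unless partial results
  # are requested explicitly
  expect_error(compute_tai(c(AGC = 10)), "no decoding anticodon")
  expect_error(compute_tai(c(bad = 1)), "anticodon triplets")
})

test_that("toy genetic code with wobble pairs matches hand-computed sums", {
  # anticodons AGC (reads GCT via A:T and GCC via I:C) and CGC (reads GCG)
  tgcn <- c(AGC = 8, CGC = 4)
  s <- data.frame(codon_base     = c("T", "C", "G"),
                  anticodon_base = c("A", "A", "C"),
                  s              = c(0, 0.5, 0))
  tai <- compute_tai(tgcn, s, partial = TRUE)
  tt <- stats::setNames(tai$W, tai$codon)
  expect_equal(tt[["GCT"]], 8)          # (1-0) * 8
  expect_equal(tt[["GCC"]], 4)          # (1-0.5) * 8
  expect_equal(tt[["GCG"]], 4)          # (1-0) * 4
  expect_equal(tai$tai[tai$codon == "GCC"], 0.5)
  # default weights cover all 61 codons given a full anticodon complement
  full <- stats::setNames(rep(1, 64),
                          apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                            c("A","C","G","T")), 1, paste0,
                                collapse = ""))
  tai_full <- compute_tai(full)
  expect_true(all(tai_full$tai > 0 & tai_full$tai <= 1))
  expect_equal(max(tai_full$tai), 1)
})

test_that("Spearman against 1/tAI behaves as a rank correlation should", {
  tai <- synthetic_tai(5)
  r1 <- spearman_vs_inverse_tai(1 / tai, tai)
  expect_equal(r1$rho, 1)
  r2 <- spearman_vs_inverse_tai(tai, tai)
  expect_equal(r2$rho, -1)
  # two swapped ranks against the exact rank formula: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  v <- stats::setNames(1:10, names(tai)[1:10])
  sw <- v; sw[c(3, 7)] <- v[c(7, 3)]
  tai10 <- stats::setNames(1 / (1:10), names(tai)[1:10])  # 1/tai10 = 1..10
  got <- spearman_vs_inverse_tai(sw, tai10)
  d2 <- sum((rank(sw) - rank(1:10))^2)
  expect_equal(got$rho, 1 - 6 * d2 / (10 * 99))
  expect_error(spearman_vs_inverse_tai(stats::setNames(rep(1, 10), names(tai)[1:10]),
                                       tai), "constant")
  expect_error(spearman_vs_inverse_tai(v[1:3], tai), "at least 4")
})

test_that("experiment correlation matrices follow the textbook Pearson formula", {
  set.seed(6)
  a <- stats::setNames(rnorm(61, 1, 0.3), sense_codons())
  ident <- experiment_correlation_matrix(list(x = a, y = a))
  expect_equal(unname(ident), matrix(c(1, 1, 1, 1), 2))
  flipped <- experiment_correlation_matrix(list(x = a, y = 2 * mean(a) - a))
  expect_equal(flipped["x", "y"], -1)
  b <- stats::setNames(rnorm(61, 1, 0.3), sense_codons())
  c3 <- stats::setNames(rnorm(61, 1, 0.3), sense_codons())
  m <- experiment_correlation_matrix(list(e1 = a, e2 = b, e3 = c3))
  hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(m["e1", "e2"], hand(a, b))
  expect_equal(m["e2", "e3"], hand(b, c3))
  expect_true(isSymmetric(m))
  expect_error(experiment_correlation_matrix(list(a)), "at least 2")
})

test_that("UPGMA recovers planted block structure and merges duplicates first", {
  m <- rbind(A1 = c(1.0, 0.9, 0.1, 0.1),
             A2 = c(0.9, 1.0, 0.1, 0.1),
             B1 = c(0.1, 0.1, 1.0, 0.9),
             B2 = c(0.1, 0.1, 0.9, 1.0))
  colnames(m) <- rownames(m)
  tr <- upgma_cluster(m)
  expect_true(ape::is.monophyletic(tr, c("A1", "A2")))
  expect_true(ape::is.monophyletic(tr, c("B1", "B2")))
  nwk <- ape::write.tree(tr)
  expect_match(nwk, "A1")
  # identical rows merge at distance zero
  m2 <- rbind(x = c(1, 0.5, 0.2), y = c(1, 0.5, 0.2), z = c(0.2, 0.2, 1))
  colnames(m2) <- c("c1", "c2", "c3"); rownames(m2) <- c("x", "y", "z")
  hc <- attr(upgma_cluster(m2), "hclust")
  expect_equal(hc$height[1], 0)
  expect_error(upgma_cluster(matrix(1, 2, 3)), "square")
})

test_that("clustering separates simulated perturbed from unperturbed samples", {
  cds <- generate_transcriptome(30, c(200L, 250L), seed = 61)
  sch <- generate_rate_scheme(synthetic_tai(62), -1, 0.2, seed = 63)
  occ_of <- function(snap) {
    prof <- profile_from_snapshot(snap, cds, 60L, 0:2)
    site_occupancies(prof)
  }
  tables <- list()
  for (i in 1:3) {
    ss <- simulate_steady_state(cds, sch$pre, sim_config(seed = 100 + i),
                                n_ribosomes = 5e4)
    tables[[paste0("noCHX_", i)]] <- occ_of(ss)
  }
  for (i in 1:3) {
    sw <- simulate_rate_switch(cds, sch$pre, sch$post,
                               sim_config(seed = 200 + i), 15,
                               n_ribosomes = 5e4)
    tables[[paste0("CHX_", i)]] <- occ_of(sw)
  }
  m <- experiment_correlation_matrix(tables, site = "A")
  tr <- upgma_cluster(m)
  expect_true(ape::is.monophyletic(tr, paste0("CHX_", 1:3)))
  expect_true(ape::is.monophyletic(tr, paste0("noCHX_", 1:3)))
})

test_that("wave analysis recovers exact conservation built into synthetic profiles", {
  # construct profiles where each codon's downstream differences sum to
  # exactly -delta_binding: regression must return slope -1, r^2 = 1
  offsets <- 0:70
  E_ref <- matrix(1, 61, length(offsets),
                  dimnames = list(sense_codons(), as.character(offsets)))
  E_test <- E_ref
  set.seed(8)
  delta <- rnorm(61, 0, 0.5)
  E_test[, "0"] <- 1 + delta
  # spread the compensating area uniformly over offsets 6..65
  E_test[, as.character(6:65)] <- 1 - delta / 60
  mk <- function(E) structure(list(E = E, n = E * 0 + 10L, se = E * 0,
                                   offsets = offsets), class = "OffsetProfile")
  wa <- wave_analysis(mk(E_test), mk(E_ref), window = c(6, 65))
  expect_equal(wa$regression$slope, -1, tolerance = 1e-12)
  expect_equal(wa$regression$r_squared, 1, tolerance = 1e-12)
  expect_equal(wa$table$wave_area, -wa$table$delta_binding, tolerance = 1e-12)
  # corrected aggregate restores the pre-perturbation binding signal
  expect_equal(wa$table$corrected_aggregate,
               unname(rowSums(E_test[, c("0", "1", "2")])) + wa$table$wave_area,
               tolerance = 1e-12)
  # identical profiles: all zero, regression flagged undefined
  wa0 <- wave_analysis(mk(E_ref), mk(E_ref), window = c(6, 65))
  expect_null(wa0$regression)
  expect_true(all(wa0$table$wave_area == 0))
  # windows may not touch the binding sites
  expect_error(wave_analysis(mk(E_test), mk(E_ref), window = c(2, 65)),
               "binding sites")
})

test_that("peak localization finds symmetric synthetic peaks and flags flat profiles", {
  offsets <- 0:60
  E <- matrix(1, 61, length(offsets),
              dimnames = list(sense_codons(), as.character(offsets)))
  tri <- pmax(0, 5 - abs((0:60) - 20)) / 5   # triangle centered at 20
  E["CGA", ] <- 1 + tri
  prof <- structure(list(E = E, n = E * 0 + 5L, se = E * 0, offsets = offsets),
                    class = "OffsetProfile")
  pk <- peak_center(prof, "CGA", c(5, 40))
  expect_true(pk$defined)
  expect_equal(pk$center, 20, tolerance = 0.5 / 20)
  expect_equal(pk$height, 1)
  flat <- peak_center(prof, "AAA", c(5, 40))
  expect_false(flat$defined)
  expect_true(is.na(flat$center))
  expect_error(peak_center(prof, "CGA", c(50, 80)), "offset range")
})
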