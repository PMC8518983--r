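test_that("simulated dosages are valid, deterministic, and honour missingness", {
  cfg <- SimulationConfig(n_genotypes = 4, n_markers = 3, missing_rate = 0,
                          n_chromosomes = 2, seed = 1)
  g <- simulateGenotypes(cfg)
  d <- dosages(g)
  expect_equal(dim(d), c(4L, 3L))
  expect_true(all(d %in% c(0, 1, 2)))
  expect_identical(d, dosages(simulateGenotypes(cfg)))

  cfg2 <- SimulationConfig(n_genotypes = 40, n_markers = 1000,
                           missing_rate = 0.5, seed = 2)
  g2 <- simulateGenotypes(cfg2)
  expect_lt(abs(mean(is.na(dosages(g2))) - 0.5), 0.05)

  map <- markerMap(g2)
  expect_false(is.unsorted(map$position_bp[map$chromosome ==
                                             map$chromosome[1]]))
})

test_that("invalid simulation configs are rejected", {
  expect_error(SimulationConfig(missing_rate = 1), "missing_rate")
  expect_error(SimulationConfig(maf_range = c(0.1, 0.7)), "maf_range")
  expect_error(SimulationConfig(maf_range = c(0.3, 0.1)), "maf_range")
  expect_error(SimulationConfig(n_genotypes = 0), "n_genotypes")
})

test_that("Balding-Nichols structure separates subpopulations in kinship", {
  g <- simulateGenotypes(SimulationConfig(n_genotypes = 60, n_markers = 400,
                                          missing_rate = 0, fst = 0.2,
                                          seed = 3))
  K <- relatednessMatrix(g)
  pop <- S4Vectors::metadata(g)$population
  within <- mean(K[outer(pop, pop, "==") & upper.tri(K)])
  between <- mean(K[outer(pop, pop, "!=") & upper.tri(K)])
  expect_gt(within, between)
})

test_that("trait simulation matches its variance-component bookkeeping", {
  g <- simulateGenotypes(SimulationConfig(n_genotypes = 300, n_markers = 20,
                                          missing_rate = 0, seed = 4))
  # no genetic signal: variance of genotype means is sigma_e2 / n_blocks
  st0 <- simulateTraits(g, sigma_g2 = 0, sigma_e2 = 1,
                        block_effects = numeric(4), seed = 5)
  gm <- genotypeMeans(st0$plants)
  expect_lt(abs(var(gm$trait_01) - 0.25), 0.06)
  expect_equal(st0$truth$h2_true, 0)

  st <- simulateTraits(g, sigma_g2 = 1, sigma_e2 = 3,
                       block_effects = numeric(4), seed = 6)
  expect_equal(st$truth$h2_true, 1 / (1 + 3 / 4))

  expect_error(
    simulateTraits(g, n_traits = 2,
                   genetic_corr = matrix(c(1, 2, 2, 1), 2), seed = 7),
    "positive semi-definite")
})

test_that("a planted QTL contributes the standard additive variance", {
  g <- simulateGenotypes(SimulationConfig(n_genotypes = 2000, n_markers = 10,
                                          missing_rate = 0, seed = 8))
  mk <- colnames(dosages(g))[1]
  st <- simulateTraits(g, sigma_g2 = 0.2, sigma_e2 = 1,
                       block_effects = numeric(4),
                       qtl = list(list(marker = mk, effect = 0.5)),
                       seed = 9)
  gm <- genotypeMeans(st$plants)
  x <- dosages(g)[gm$genotype_id, mk]
  fit <- lm(gm$trait_01 ~ x)
  expect_lt(abs(coef(fit)[["x"]] - 0.5), 0.05)
  p <- mean(x) / 2
  expected_var <- 2 * p * (1 - p) * 0.5^2
  expect_lt(abs(var(x * 0.5) - expected_var) / expected_var, 0.1)
})

test_that("simulated gas traces invert the flux relation", {
  ch <- ChamberConfig()
  tr <- simulateGasTrace(0.3845, ch, corrected_volume_ml = 19,
                         noise_sd = 0, transient_amplitude = 0)
  expect_length(tr@time_s, 91L)
  sl <- estimateSlope(tr)
  # 0.3845 nmol/s in 19 ml at 301.15 K / 101.325 kPa <-> 0.5 umol/mol/s
  expect_lt(abs(sl$slope - 0.5), 1e-4)

  tr0 <- simulateGasTrace(0, ch, noise_sd = 0, transient_amplitude = 0)
  expect_equal(estimateSlope(tr0)$slope, 0, tolerance = 1e-12)

  # Monte-Carlo recovery under noise
  fl <- vapply(seq_len(100), function(s) {
    tri <- simulateGasTrace(0.5, ch, noise_sd = 0.2, seed = s)
    computeFlux(estimateSlope(tri)$slope, ch, 19)
  }, numeric(1))
  se <- sd(fl) / sqrt(length(fl))
  expect_lt(abs(mean(fl) - 0.5), 2 * se + 1e-6)
})

test_that("the transient is confined to the dead band", {
  ch <- ChamberConfig()
  tr <- simulateGasTrace(0.3845, ch, noise_sd = 0,
                         transient_amplitude = 10, transient_halflife = 4)
  sl <- estimateSlope(tr, 20, 90)
  expect_lt(abs(sl$slope - 0.5), 0.01)
  sl_all <- estimateSlope(tr, 0, 90)
  expect_gt(abs(sl_all$slope - 0.5), abs(sl$slope - 0.5))
})

test_that("simulated root systems carry an exact linear respiration truth", {
  rs <- simulateRootSystems(10, 0.001, 0.003, 0.03, seed = 1)
  pv <- partitionVolumes(rs$features)
  pm <- suppressWarnings(fitPartitionModel(pv, rs$respiration))
  expect_equal(pm$r_squared, 1, tolerance = 1e-10)
  expect_equal(pm$coefficients$estimate[-1], c(0.001, 0.003, 0.03),
               tolerance = 1e-8)
  expect_true(all(rs$features$lateral_root_volume_mm3 >= 0))
})
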