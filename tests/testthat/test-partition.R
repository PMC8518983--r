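test_that("tip and lateral-axis volumes follow the stated conventions", {
  f <- data.frame(sample_id = c("a", "b", "c"),
                  tips = c(404, 399.61, 2),
                  axial_root_volume_mm3 = c(244, 243.9, 10),
                  lateral_root_volume_mm3 = c(85, 85.59, 5))
  pv <- partitionVolumes(f)
  expect_equal(pv$n_lateral_tips, c(400, 395.61, 0))
  expect_equal(pv$tip_volume_mm3, c(4.00, 3.9561, 0))
  expect_equal(pv$lateral_axis_volume_mm3[2], 81.6339)
  expect_true(pv$clamped[3])
  expect_false(any(pv$clamped[1:2]))
})

test_that("the partition model recovers planted rates and degrades under permutation", {
  rs <- simulateRootSystems(200, 0.001, 0.003, 0.03, seed = 21,
                            respiration_noise_sd = 0.02)
  pv <- partitionVolumes(rs$features)
  pm <- fitPartitionModel(pv, rs$respiration)
  expect_equal(pm$coefficients$estimate[-1], c(0.001, 0.003, 0.03),
               tolerance = 0.3)
  expect_gt(pm$r_squared, 0.8)
  expect_equal(pm$n_clamped, 0)

  set.seed(1)
  perm <- rs$respiration
  perm$flux_nmol_s <- sample(perm$flux_nmol_s)
  pmp <- fitPartitionModel(pv, perm)
  expect_lt(pmp$r_squared, 0.1)
})

test_that("slope ratios recover the 30.5 : 8.1 tip activity structure", {
  a <- 8e-4
  rs <- simulateRootSystems(1000, a, a * 30.5 / 8.1, a * 30.5, seed = 22,
                            allometric_sd = 0.2,
                            respiration_noise_sd = 0.03)
  pm <- fitPartitionModel(partitionVolumes(rs$features), rs$respiration)
  expect_lt(abs(pm$ratio_tip_axial - 30.5) / 30.5, 0.15)
  expect_lt(abs(pm$ratio_tip_lateral - 8.1) / 8.1, 0.15)
})

test_that("equal rates give statistically indistinguishable slopes", {
  rs <- simulateRootSystems(800, 0.002, 0.002, 0.002, seed = 23,
                            allometric_sd = 0.2,
                            respiration_noise_sd = 0.02)
  pm <- fitPartitionModel(partitionVolumes(rs$features), rs$respiration)
  est <- pm$coefficients$estimate[-1]
  se <- pm$coefficients$se[-1]
  for (i in 2:3)
    expect_lt(abs(est[i] - est[1]) / sqrt(se[i]^2 + se[1]^2), 3.5)
})

test_that("stepwise AIC keeps real terms and tends to drop null terms", {
  rs <- simulateRootSystems(500, 0.001, 0.003, 0.03, seed = 24,
                            respiration_noise_sd = 0.01)
  sel <- stepwiseAIC(partitionVolumes(rs$features), rs$respiration)
  expect_setequal(sel$terms, c("axial_volume_mm3",
                               "lateral_axis_volume_mm3",
                               "tip_volume_mm3"))
  # tip rate truly zero: the tip term should usually be dropped
  drops <- vapply(1:20, function(s) {
    rs0 <- simulateRootSystems(400, 0.001, 0.003, 0, seed = 100 + s,
                               allometric_sd = 0.25,
                               respiration_noise_sd = 0.05)
    sel0 <- stepwiseAIC(partitionVolumes(rs0$features), rs0$respiration)
    !"tip_volume_mm3" %in% sel0$terms
  }, logical(1))
  expect_gt(mean(drops), 0.5)
})

test_that("SRR_R has the OLS residual properties", {
  rs <- simulateRootSystems(300, 8e-4, 3e-3, 2.4e-2, seed = 25,
                            respiration_noise_sd = 0.05)
  pv <- partitionVolumes(rs$features)
  pm <- fitPartitionModel(pv, rs$respiration)
  res <- residualTrait(pm, pv, rs$respiration)
  expect_lt(abs(mean(res$SRR_R)), 1e-10)
  for (v in c("axial_volume_mm3", "lateral_axis_volume_mm3",
              "tip_volume_mm3"))
    expect_lt(abs(cor(res$SRR_R, pv[[v]])), 1e-8)
  # a sample respiring exactly as predicted scores zero
  probe <- data.frame(sample_id = "probe",
                      tips = 400, axial_root_volume_mm3 = 250,
                      lateral_root_volume_mm3 = 90)
  pvp <- partitionVolumes(probe)
  pred <- predict(pm$fit, newdata = pvp)
  r0 <- residualTrait(pm, pvp, data.frame(sample_id = "probe",
                                          flux_nmol_s = unname(pred)))
  expect_equal(r0$SRR_R, 0, tolerance = 1e-12)
})

test_that("SRR_R heritability grows with planted metabolic offset variance", {
  h2_for <- function(offset_sd, seed) {
    ng <- 60; nb <- 4
    g_off <- rnorm(ng, sd = offset_sd)
    rs <- simulateRootSystems(ng * nb,
                              respiration_offset = rep(g_off, each = nb),
                              respiration_noise_sd = 0.03, seed = seed)
    pv <- partitionVolumes(rs$features)
    pm <- fitPartitionModel(pv, rs$respiration)
    res <- residualTrait(pm, pv, rs$respiration)
    pl <- data.frame(genotype_id = rep(sprintf("g%02d", seq_len(ng)),
                                       each = nb),
                     block_id = rep(seq_len(nb), ng),
                     value = res$SRR_R)
    broadSenseH2(fitRcbdReml(pl))
  }
  set.seed(31)
  h_small <- h2_for(0.01, 32)
  set.seed(33)
  h_large <- h2_for(0.15, 34)
  expect_gt(h_large, 0.5)
  expect_gt(h_large, h_small)
})
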