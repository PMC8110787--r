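# the seeded generators that stand in for the instrument

test_that("generated curves encode series compliance", {
  cu <- gen_force_curve(curve_gen_spec(k_true = 10, k_system = 40,
                                       noise_sd = 0, z0 = 3))
  fit <- fit_stiffness(cu, detect_contact_point(cu))
  expect_equal(fit$k_uncorrected, 8, tolerance = 1e-4) # 1/(1/10+1/40)
  expect_equal(correct_compliance(fit$k_uncorrected, calibration_record(40)),
               10, tolerance = 1e-3)
})

test_that("an infinitely stiff instrument leaves the slope unchanged", {
  cu <- gen_force_curve(curve_gen_spec(k_true = 7, k_system = 1e12,
                                       noise_sd = 0, z0 = 2))
  fit <- fit_stiffness(cu, detect_contact_point(cu))
  expect_equal(fit$k_uncorrected, 7, tolerance = 1e-6)
})

test_that("curve generation is deterministic per seed", {
  s <- curve_gen_spec(k_true = 5, noise_sd = 0.05, seed = 99)
  c1 <- gen_force_curve(s)
  c2 <- gen_force_curve(s)
  expect_identical(c1$F, c2$F)
  s2 <- curve_gen_spec(k_true = 5, noise_sd = 0.05, seed = 100)
  expect_false(identical(gen_force_curve(s2)$F, c1$F))
})

test_that("generator leaves the global RNG stream unchanged", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_force_curve(curve_gen_spec(3, seed = 77)))
  expect_identical(runif(1), before)
})

test_that("population generator returns coupled ground truth", {
  spec <- population_spec(n_grains = 12, m_per_grain = 6, seed = 4)
  pop <- gen_pollen_population(spec)
  expect_equal(nrow(pop$truth), 12)
  expect_equal(nrow(pop$measurements), 72)
  expect_equal(pop$truth$k_i_true,
               pop$truth$ratio_true * pop$truth$k_e_true, tolerance = 1e-12)
  # per-grain coupling: higher exine goes with higher intine
  expect_gt(cor(pop$truth$k_e_true, pop$truth$k_i_true), 0.5)
})

test_that("degenerate population settings give exact ratios", {
  spec <- population_spec(n_grains = 8, m_per_grain = 4, ratio_sd = 0,
                          cv = 0, seed = 5)
  pop <- gen_pollen_population(spec)
  rt <- ratio_table(pop$measurements |>
                      transform(k = k_true))
  expect_equal(rt$ratio, rep(spec$ratio_mean, 8), tolerance = 1e-12)
})

test_that("the exine mixture reproduces its target mean and SD", {
  spec <- population_spec(n_grains = 4000, seed = 8)
  pop <- gen_pollen_population(spec)
  expect_equal(mean(pop$truth$k_e_true), 16.5, tolerance = 0.02)
  expect_equal(sd(pop$truth$k_e_true), 6.6, tolerance = 0.05)
})

test_that("pooled marginals from the bimodal mixture fail normality", {
  spec <- population_spec(n_grains = 500, m_per_grain = 2, seed = 6)
  pop <- gen_pollen_population(spec)
  expect_lt(normality_test(pop$truth$k_e_true)$p, 0.001)
  # the intine marginal inherits the bimodality through the ratio
  expect_lt(normality_test(pop$truth$k_i_true)$p, 0.01)
})

test_that("worm map generator labels bands by angle", {
  spec <- worm_gen_spec(band_centers = c(90, 270), band_width = 40, seed = 2,
                        rotation_angles = c(0, 80, 100, 260, 280),
                        n_lines = 5)
  m <- gen_worm_map(spec)
  lab <- unique(m$truth[, c("theta_true", "band")])
  expect_identical(lab$band[lab$theta_true == 0], "soft")
  expect_identical(lab$band[lab$theta_true == 80], "stiff")
  expect_identical(lab$band[lab$theta_true == 260], "stiff")
  # all four lines near the band centers are stiff, the one at 0 soft
  expect_identical(unname(table(m$truth$band)["stiff"]), 40L)
})

test_that("zero-width bands give an all-soft map", {
  spec <- worm_gen_spec(band_width = 0, seed = 3)
  m <- gen_worm_map(spec)
  expect_true(all(m$truth$band == "soft"))
})

test_that("full-circumference bands are rejected", {
  expect_error(worm_gen_spec(band_centers = c(0, 90, 180, 270),
                             band_width = 90), "full circumference")
})

test_that("default worm layout matches the printed group sizes", {
  m <- gen_worm_map(worm_gen_spec(seed = 10))
  expect_identical(as.vector(table(m$truth$band)), c(20L, 30L))
  sites <- do.call(rbind, m$lines)
  expect_equal(nrow(sites), 50)
})
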