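# contact detection, slope fitting and compliance correction

test_that("force_curve validates its invariants", {
  expect_error(force_curve(1:5, 1:5), "at least 10")
  expect_error(force_curve(1:10, 1:9), "same length")
  expect_error(force_curve(c(1:9, 9), 1:10), "strictly increasing")
  expect_error(force_curve(1:10, c(1:9, NA)), "finite")
  cu <- force_curve(1:10, rep(0, 10), region = "exine")
  expect_s3_class(cu, "force_curve")
  expect_identical(cu$region, "exine")
})

test_that("contact point of a noiseless kink curve is exact", {
  cu <- kink_curve(k = 2, z0 = 5)
  expect_equal(detect_contact_point(cu), 5, tolerance = 1e-8)
})

test_that("contact detection fails cleanly without contact", {
  z <- seq(0, 10, by = 0.05)
  cu <- force_curve(z, rep(0, length(z)))
  expect_error(detect_contact_point(cu), "no contact detected")
})

test_that("noisy contact detection stays within the expected window", {
  # Monte-Carlo calibration: slope 2 N/m, sigma = 0.01 uN, 5x threshold
  hits <- vapply(seq_len(1000), function(s) {
    cu <- kink_curve(k = 2, z0 = 5, noise = 0.01, seed = s)
    z0 <- detect_contact_point(cu, noise_mult = 5)
    z0 >= 4.8 && z0 <= 5.3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("stiffness fit recovers a linear slope exactly", {
  cu <- kink_curve(k = 2, z0 = 1, z_max = 6)
  fit <- fit_stiffness(cu, z0 = 1)
  expect_equal(fit$k_uncorrected, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  fit2 <- fit_stiffness(cu, z0 = 1, window = c(0.2, 0.7))
  expect_equal(fit2$k_uncorrected, 2, tolerance = 1e-10)
})

test_that("windowed fit of a quadratic matches the closed-form slope", {
  # F = a (z - z0)^2, window (0.5, 1] of F_max = 10 uN, a = 1
  a <- 1; z0 <- 2
  z <- seq(0, z0 + sqrt(10), by = 1e-3)
  cu <- force_curve(z, a * pmax(z - z0, 0)^2)
  fit <- fit_stiffness(cu, z0 = z0, window = c(0.5, 1.0))
  # continuous-limit least-squares slope of a*u^2 on u in [sqrt(5), sqrt(10)]
  u1 <- sqrt(5); u2 <- sqrt(10)
  m <- function(p) (u2^(p + 1) - u1^(p + 1)) / ((p + 1) * (u2 - u1))
  slope_cf <- a * (m(3) - m(1) * m(2)) / (m(2) - m(1)^2)
  expect_equal(fit$k_uncorrected, slope_cf, tolerance = 1e-4)
  expect_lt(fit$r_squared, 1)
})

test_that("too narrow a window raises an error", {
  z <- seq(0, 10, by = 1)
  cu <- force_curve(z, pmax(z - 5, 0) * 2)
  expect_error(fit_stiffness(cu, 5, window = c(0.95, 1.0)), "window too narrow")
})

test_that("compliance correction matches the series-spring formula", {
  expect_equal(correct_compliance(8, calibration_record(40)), 10)
  # rigid-system limit
  expect_equal(correct_compliance(5, calibration_record(1e9)), 5,
               tolerance = 1e-7)
  # series-spring identity: measured at half the system stiffness
  ks <- 123.4
  expect_equal(correct_compliance(ks / 2, calibration_record(ks)), ks,
               tolerance = 1e-12)
  expect_error(correct_compliance(50, calibration_record(40)),
               "exceeds system stiffness")
  expect_error(correct_compliance(40, calibration_record(40)),
               "exceeds system stiffness")
})

test_that("compliance correction is monotone in both arguments", {
  ks <- 100
  km <- seq(1, 80, by = 1)
  kc <- correct_compliance(km, calibration_record(ks))
  expect_true(all(diff(kc) > 0))
  expect_true(all(kc > km))
  # decreasing system stiffness increases the corrected value
  kc2 <- correct_compliance(50, calibration_record(80))
  kc1 <- correct_compliance(50, calibration_record(120))
  expect_gt(kc2, kc1)
})

test_that("process_curve recovers the generating stiffness", {
  # round-trip with the instrument emulator: series compliance built in
  spec <- curve_gen_spec(k_true = 9.3, k_system = 300, noise_sd = 0)
  cu <- gen_force_curve(spec)
  m <- process_curve(cu, calibration_record(300))
  expect_s3_class(m, "stiffness_measurement")
  expect_equal(m$k, 9.3, tolerance = 0.005)
  expect_gt(m$k, m$k_uncorrected) # correction can only increase the slope
  expect_true(m$r_squared > 0.999)
})

test_that("round-trip recovery is better than 0.1% without noise", {
  for (kt in c(0.5, 5, 50, 140)) {
    cu <- gen_force_curve(curve_gen_spec(k_true = kt, k_system = 300,
                                         noise_sd = 0))
    m <- process_curve(cu, calibration_record(300))
    expect_equal(m$k, kt, tolerance = 1e-3)
  }
})

test_that("a rigid calibration curve processed as a sample errors", {
  # slope equals the system stiffness when indenting glass
  cu <- kink_curve(k = 300, z0 = 2, z_max = 4, dz = 0.005)
  expect_error(process_curve(cu, calibration_record(300)),
               "exceeds system stiffness")
})

test_that("batch processing is order-independent", {
  curves <- lapply(1:10, function(i)
    gen_force_curve(curve_gen_spec(k_true = 5 + i, k_system = 300,
                                   noise_sd = 0.02, seed = i),
                    curve_id = sprintf("c%02d", i)))
  cal <- calibration_record(300)
  t1 <- process_batch(curves, cal)
  t2 <- process_batch(rev(curves), cal)
  t2 <- t2[match(t1$curve_id, t2$curve_id), ]
  rownames(t2) <- NULL
  expect_equal(t1, t2)
})

test_that("stiffness is unit-coherent between (uN, um) and (N, m)", {
  cu <- kink_curve(k = 3, z0 = 2, z_max = 6)
  fit_um <- fit_stiffness(cu, 2)
  # same curve expressed in metres and newtons: slope in N/m is identical
  cu_m <- force_curve(cu$z * 1e-6, cu$F * 1e-6)
  post <- cu_m$z >= 2e-6
  Fm <- max(cu_m$F[post])
  sel <- post & cu_m$F >= 0.5 * Fm
  k_si <- coef(lm(cu_m$F[sel] ~ cu_m$z[sel]))[2]
  expect_equal(fit_um$k_uncorrected, unname(k_si), tolerance = 1e-9)
})

test_that("curves written to disk read back identically", {
  cu <- gen_force_curve(curve_gen_spec(k_true = 7, seed = 3,
                                       noise_sd = 0.01),
                        specimen_id = "g1", region = "exine")
  path <- file.path(tempdir(), "curve1.csv")
  write_force_curve(cu, path)
  cu2 <- read_force_curve(path)
  expect_equal(cu2$z, cu$z, tolerance = 1e-8)
  expect_equal(cu2$F, cu$F, tolerance = 1e-8)
  expect_identical(cu2$region, "exine")
  expect_identical(cu2$specimen_id, "g1")
  unlink(c(path, sub("csv$", "json", path)))
})
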