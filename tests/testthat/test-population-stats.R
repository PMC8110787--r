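# per-grain ratios, repeatability, and group statistics

test_that("per-grain ratio follows the printed single-grain example", {
  sp <- specimen("g1", data.frame(region = c("intine", "exine"),
                                  k = c(8.1, 14.3)))
  r <- per_grain_ratio(sp)
  expect_equal(r$ratio, 8.1 / 14.3, tolerance = 1e-12)
  expect_equal(round(r$ratio, 3), 0.566)
})

test_that("ratio arithmetic on small fixtures", {
  sp <- specimen("g", data.frame(region = c("intine", "intine", "exine",
                                            "exine"),
                                 k = c(2, 4, 6, 6)))
  expect_equal(per_grain_ratio(sp)$ratio, 0.5)
  sp2 <- specimen("h", data.frame(region = c("intine", "exine"),
                                  k = c(3.3, 3.3)))
  expect_equal(per_grain_ratio(sp2)$ratio, 1)
})

test_that("incomplete specimens are rejected", {
  sp <- specimen("g1", data.frame(region = "intine", k = 5))
  expect_error(per_grain_ratio(sp), "incomplete specimen")
})

test_that("ratio is invariant under uniform scaling of a grain", {
  set.seed(42)
  meas <- data.frame(region = rep(c("intine", "exine"), each = 5),
                     k = c(runif(5, 5, 12), runif(5, 10, 25)))
  r1 <- per_grain_ratio(specimen("g", meas))$ratio
  meas$k <- meas$k * 3.7
  r2 <- per_grain_ratio(specimen("g", meas))$ratio
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("per-grain aggregation differs from pooled aggregation", {
  # grains with different ratios and very different overall stiffness
  meas <- data.frame(
    specimen_id = rep(c("g1", "g2"), each = 2),
    region = rep(c("intine", "exine"), 2),
    k = c(1, 2, 30, 100)) # ratios 0.5 and 0.3
  rt <- ratio_table(meas)
  per_grain <- mean(rt$ratio)
  pooled <- mean(meas$k[meas$region == "intine"]) /
    mean(meas$k[meas$region == "exine"])
  expect_equal(per_grain, 0.4)
  expect_equal(pooled, 31 / 102)
  expect_false(isTRUE(all.equal(per_grain, pooled)))
})

test_that("coefficient of variation matches hand calculations", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_equal(coefficient_of_variation(rep(7, 5)), 0)
  expect_error(coefficient_of_variation(c(5)), "at least two")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("repeatability design reproduces the generator CV", {
  # n = 5 specimens x m = 10 repeats with 4.8% multiplicative noise
  mean_cvs <- vapply(seq_len(500), function(s) {
    set.seed(s)
    cvs <- vapply(seq_len(5), function(i) {
      k_true <- runif(1, 5, 25)
      coefficient_of_variation(k_true * rnorm(10, 1, 0.048))
    }, numeric(1))
    mean(cvs)
  }, numeric(1))
  expect_gte(mean(mean_cvs), 0.035)
  expect_lte(mean(mean_cvs), 0.06)
})

test_that("normality test is calibrated under the null", {
  ps <- vapply(seq_len(200), function(s) {
    set.seed(s)
    normality_test(rnorm(500))$p
  }, numeric(1))
  # p-values approximately uniform on [0, 1]
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("normality test rejects a bimodal mixture", {
  set.seed(7)
  x <- c(rnorm(150, 9, 1), rnorm(150, 20, 1))
  expect_lt(normality_test(x)$p, 0.001)
})

test_that("normality test guards its domain", {
  expect_error(normality_test(rnorm(5)), "at least 8")
  expect_error(normality_test(rep(1, 20)), "constant")
})

test_that("group comparison handles identical groups", {
  x <- c(1.1, 2.2, 3.3, 4.4)
  cmp <- compare_groups(x, x)
  expect_equal(cmp$t, 0, tolerance = 1e-12)
  expect_equal(cmp$p, 1, tolerance = 1e-12)
})

test_that("pooled t statistic matches the textbook formula", {
  a <- c(4.1, 5.2, 6.3, 5.8)
  b <- c(6.9, 7.4, 8.1, 7.7)
  cmp <- compare_groups(a, b, variance_rule = "pooled")
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), df = 6)
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$df, 6)
  expect_equal(cmp$p, p_hand, tolerance = 1e-12)
})

test_that("comparison is symmetric up to the sign of t", {
  set.seed(11)
  a <- rnorm(10, 1); b <- rnorm(12, 2)
  c1 <- compare_groups(a, b)
  c2 <- compare_groups(b, a)
  expect_equal(c1$t, -c2$t, tolerance = 1e-12)
  expect_equal(c1$p, c2$p, tolerance = 1e-12)
  expect_gte(c1$p, 0); expect_lte(c1$p, 1)
})

test_that("water vs CaCl2 ratio settings are reliably distinguished", {
  # power Monte-Carlo at the printed group parameters (0.56 vs 0.66,
  # sd 0.10, n = 30 each)
  rej <- vapply(seq_len(1000), function(s) {
    set.seed(s)
    a <- rnorm(30, 0.56, 0.10)
    b <- rnorm(30, 0.66, 0.10)
    compare_groups(a, b)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.90)
})

test_that("degenerate variances are rejected", {
  expect_error(compare_groups(rep(1, 5), rep(2, 5)), "degenerate variance")
})

test_that("population summary uses linear-interpolation quantiles", {
  s <- summarize_population(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q05, 5.95)
  expect_equal(s$q95, 95.05)
  s1 <- summarize_population(42)
  expect_equal(s1$mean, 42)
  expect_equal(s1$median, 42)
  expect_equal(s1$min, 42)
  expect_equal(s1$max, 42)
})
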