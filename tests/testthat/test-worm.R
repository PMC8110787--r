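# cylindrical coordinate assignment, unfolding and band analysis

make_lines <- function(ks) lapply(ks, function(k)
  data.frame(s_um = seq(0, 180, by = 20), k_Npm = k))

test_that("declared angles map through without drift", {
  m <- assign_coordinates(make_lines(c(0.5, 0.7)), c(0, 90),
                          drift_offsets = c(0, 0))
  expect_setequal(unique(m$sites$theta_deg), c(0, 90))
  expect_equal(nrow(m$sites), 20)
})

test_that("angles wrap modulo 360", {
  m <- assign_coordinates(make_lines(c(0.5)), c(350), drift_offsets = c(20))
  expect_equal(unique(m$sites$theta_deg), 10)
})

test_that("missing drift information is an error for multiple lines", {
  expect_error(assign_coordinates(make_lines(c(0.5, 0.7)), c(0, 90)),
               "drift")
})

test_that("fiducial overlap recovers an injected drift", {
  spec <- worm_gen_spec(n_lines = 3, rotation_angles = c(0, 90, 180),
                        drift = c(0, 10, 0), fiducial_noise_sd = 0.5,
                        seed = 21)
  g <- gen_worm_map(spec)
  m <- assign_coordinates(g$lines, g$rotation_angles,
                          fiducials = g$fiducials)
  expect_equal(m$drift_offsets[2], 10, tolerance = 2)
  expect_equal(m$drift_offsets[3], 0, tolerance = 2)
  # recovered angles close to the true ones
  th <- unique(m$sites$theta_deg)
  expect_equal(sort(th), sort(unique(g$truth$theta_true)), tolerance = 2)
})

test_that("unfold preserves every site and refolds exactly", {
  spec <- worm_gen_spec(seed = 31)
  g <- gen_worm_map(spec)
  m <- assign_coordinates(g$lines, g$rotation_angles, fiducials = g$fiducials)
  grid <- unfold(m)
  expect_lte(sum(!is.na(grid)), nrow(m$sites))
  back <- refold(grid)
  ord1 <- with(m$sites, order(s_um, theta_deg))
  ord2 <- with(back, order(s_um, theta_deg))
  expect_equal(back$k_Npm[ord2], m$sites$k_Npm[ord1], tolerance = 1e-12)
})

test_that("holes in the grid are preserved, not interpolated", {
  lines <- list(data.frame(s_um = c(0, 20), k_Npm = c(0.5, 0.6)),
                data.frame(s_um = c(0, 40), k_Npm = c(0.7, 0.8)))
  m <- assign_coordinates(lines, c(0, 90), drift_offsets = c(0, 0))
  grid <- unfold(m)
  expect_equal(dim(grid), c(3, 2))
  expect_equal(sum(is.na(grid)), 2)
})

test_that("band comparison reports the printed group structure", {
  g <- gen_worm_map(worm_gen_spec(seed = 41))
  m <- assign_coordinates(g$lines, g$rotation_angles, fiducials = g$fiducials)
  bc <- band_comparison(m, g$truth$band)
  expect_equal(bc$soft$n, 20)
  expect_equal(bc$stiff$n, 30)
  expect_lt(bc$test$p, 1e-4)
  expect_lt(bc$soft$mean, bc$stiff$mean)
})

test_that("identical groups give a unit p-value", {
  set.seed(5)
  k <- 0.6 + rnorm(10, 0, 0.05)
  lines <- lapply(1:4, function(l)
    data.frame(s_um = seq(0, 180, by = 20), k_Npm = k))
  m <- assign_coordinates(lines, c(0, 90, 180, 270),
                          drift_offsets = rep(0, 4))
  labels <- rep(c("soft", "stiff"), each = 20) # group values identical
  bc <- band_comparison(m, labels)
  expect_equal(bc$test$t, 0, tolerance = 1e-12)
  expect_equal(bc$test$p, 1, tolerance = 1e-12)
})

test_that("randomly permuted labels are calibrated under the null", {
  g <- gen_worm_map(worm_gen_spec(seed = 51, band_width = 0))
  m <- assign_coordinates(g$lines, g$rotation_angles, fiducials = g$fiducials)
  ps <- vapply(seq_len(200), function(s) {
    set.seed(s)
    lab <- sample(rep(c("soft", "stiff"), c(20, 30)))
    band_comparison(m, lab)$test$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-group labels are rejected", {
  g <- gen_worm_map(worm_gen_spec(seed = 61))
  m <- assign_coordinates(g$lines, g$rotation_angles, fiducials = g$fiducials)
  expect_error(band_comparison(m, rep("soft", nrow(m$sites))),
               "two nonempty groups")
})

test_that("coordinate assignment is rotation-equivariant", {
  g <- gen_worm_map(worm_gen_spec(seed = 71))
  m1 <- assign_coordinates(g$lines, g$rotation_angles,
                           drift_offsets = rep(0, 5))
  m2 <- assign_coordinates(g$lines, g$rotation_angles + 40,
                           drift_offsets = rep(0, 5))
  expect_equal(sort(unique((m2$sites$theta_deg - m1$sites$theta_deg) %% 360)),
               40)
  b1 <- band_comparison(m1, g$truth$band)
  b2 <- band_comparison(m2, g$truth$band)
  expect_equal(b1$test$p, b2$test$p, tolerance = 1e-12)
})

test_that("band spacing of the default 90-degree layout is recovered", {
  g <- gen_worm_map(worm_gen_spec(seed = 81))
  m <- assign_coordinates(g$lines, g$rotation_angles, fiducials = g$fiducials)
  bc <- band_comparison(m, g$truth$band)
  expect_equal(bc$band_spacing_deg, 90, tolerance = 15)
})

test_that("automatic 2-means labeling is available but flagged", {
  g <- gen_worm_map(worm_gen_spec(seed = 91))
  m <- assign_coordinates(g$lines, g$rotation_angles, fiducials = g$fiducials)
  set.seed(1)
  bc <- band_comparison(m, "kmeans")
  expect_identical(bc$labels_source, "kmeans")
  expect_lt(bc$soft$mean, bc$stiff$mean)
})
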