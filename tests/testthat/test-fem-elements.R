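# element-level checks: patch tests, pressure consistency, and the
# closed-form thin-shell oracle

test_that("a single wedge under uniaxial stretch matches St V-K", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
  el <- matrix(1:6, nrow = 1)
  eps <- 1e-6
  U <- X * 0; U[, 1] <- eps * X[, 1]
  out <- turgorcfm:::fem_wedge_assemble(X, U, el, 100, 0.3, 1L, FALSE)
  f <- matrix(out$f, ncol = 3, byrow = TRUE)
  lam <- 100 * 0.3 / (1.3 * 0.4); mu <- 100 / 2.6
  sxx <- (lam + 2 * mu) * eps
  # reaction on the x = 1 face (area 1/2... the triangle leg face) equals
  # sigma_xx times the face area
  expect_equal(sum(f[c(2, 5), 1]), sxx * 0.5, tolerance = 1e-5)
  # equilibrium: nodal forces sum to zero
  expect_lt(max(abs(colSums(f))), 1e-12 * sxx)
})

test_that("wedge internal forces vanish in the reference state", {
  X <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
             c(0.1, 0, 1), c(2, 0.1, 1.2), c(0, 2, 0.9))
  el <- matrix(1:6, nrow = 1)
  out <- turgorcfm:::fem_wedge_assemble(X, X * 0, el, 50, 0.3, 0L, FALSE)
  expect_equal(max(abs(out$f)), 0)
})

test_that("membrane triangle reproduces plane-stress uniaxial response", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  el <- matrix(1:3, nrow = 1)
  eps <- 1e-6; E <- 80; nu <- 0.3; h <- 0.2
  U <- X * 0; U[, 1] <- eps * X[, 1]
  out <- turgorcfm:::fem_membrane_assemble(X, U, el, h, E, nu)
  f <- matrix(out$f, ncol = 3, byrow = TRUE)
  sxx <- E / (1 - nu^2) * eps
  expect_equal(f[2, 1], sxx * h * 0.5, tolerance = 1e-5)
  expect_lt(max(abs(colSums(f))), 1e-12 * sxx * h)
})

test_that("pressure on a closed surface is self-equilibrated", {
  sp <- sphere_shell_model(thickness = 1.5)
  mesh <- build_sphere_model(sp, resolution = 800)
  U <- matrix(0, nrow(mesh$nodes), 3)
  p <- turgorcfm:::fem_pressure_assemble(mesh$nodes, U, mesh$pressure_tris,
                                         0.2)
  f <- matrix(p$f, ncol = 3, byrow = TRUE)
  # resultant vanishes although individual nodal forces are large
  expect_lt(max(abs(colSums(f))), 1e-8 * max(abs(f)) * nrow(f))
  # total magnitude is close to P times the surface area (nodal
  # averaging of adjacent facet normals loses a few percent on coarse
  # curved meshes)
  nrm <- sqrt(rowSums(f^2))
  expect_equal(sum(nrm), 0.2 * surface_area(mesh), tolerance = 0.15)
})

test_that("enclosed volume of the sphere mesh is near-analytic", {
  sp <- sphere_shell_model(thickness = 0.2, element_kind = "membrane")
  mesh <- build_sphere_model(sp, resolution = 3000, refine_amp = 0)
  V <- turgorcfm:::fem_enclosed_volume(mesh$nodes,
                                       matrix(0, nrow(mesh$nodes), 3),
                                       mesh$pressure_tris)
  expect_equal(V, 4 / 3 * pi * 50^3, tolerance = 0.05)
})

test_that("the thin-shell point-load formula behaves as expected", {
  expect_equal(reissner_stiffness(10, 1, 50, 0.3), 0.484, tolerance = 1e-3)
  # quadratic in thickness
  expect_equal(reissner_stiffness(10, 2, 100, 0.3) /
                 reissner_stiffness(10, 1, 100, 0.3), 4, tolerance = 1e-12)
  # inverse in radius
  expect_equal(reissner_stiffness(10, 1, 100, 0.3) /
                 reissner_stiffness(10, 1, 50, 0.3), 0.5, tolerance = 1e-12)
  expect_error(reissner_stiffness(10, 5, 50), "t/R")
})

test_that("apparent stiffness evaluation matches analytic derivatives", {
  d <- seq(0, 2, by = 0.05)
  lin <- list(depth = d, force = 3 * d)
  expect_equal(apparent_stiffness_at(lin, 1.0), 3, tolerance = 1e-9)
  expect_equal(apparent_stiffness_at(lin, 0.5, mode = "secant"), 3,
               tolerance = 1e-9)
  quad <- list(depth = d, force = d^2)
  expect_equal(apparent_stiffness_at(quad, 1.0), 2, tolerance = 1e-3)
  expect_error(apparent_stiffness_at(quad, 1.95), "outside sampled range")
})

test_that("linearity classification matches power-law prototypes", {
  d <- seq(0, 1.2, by = 0.02)
  expect_identical(classify_linearity(list(depth = d, force = d^1.5)),
                   "superlinear")
  expect_identical(classify_linearity(list(depth = d, force = d^0.7)),
                   "sublinear")
  expect_identical(classify_linearity(list(depth = d, force = 2 * d)),
                   "linear")
  expect_error(classify_linearity(list(depth = d / 10, force = d)),
               "outside sampled")
})

test_that("zero pressure gives a zero inflation state", {
  ts <- tiny_sphere(P = 0)
  st <- inflate(ts$mesh, ts$model)
  expect_true(st$converged)
  expect_equal(max(abs(st$U)), 0)
  expect_equal(st$volume, st$volume0, tolerance = 1e-12)
})

test_that("zero-depth indentation carries zero force", {
  ts <- tiny_sphere(P = 0)
  st <- inflate(ts$mesh, ts$model)
  r <- indent(ts$mesh, st, ts$model, site = "colpus_center", max_depth = 0)
  expect_equal(r$depth, 0)
  expect_equal(r$force, 0)
})
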