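# shared fixtures, all generated in code

# noiseless kink curve: F = 0 below z0, slope k beyond
kink_curve <- function(k = 2, z0 = 5, z_max = 10, dz = 0.02, noise = 0,
                       seed = NULL, region = "intine") {
  z <- seq(0, z_max, by = dz)
  F <- pmax(z - z0, 0) * k
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    F <- F + rnorm(length(z), 0, noise)
  }
  force_curve(z = z, F = F, region = region, specimen_id = "fix",
              curve_id = sprintf("kink-k%g", k))
}

# tiny sphere model + mesh reused by several FEM tests
tiny_sphere <- local({
  cache <- new.env()
  function(thickness = 1.5, E = 10, P = 0.2, resolution = 800) {
    key <- paste(thickness, E, P, resolution, sep = "_")
    if (is.null(cache[[key]])) {
      sp <- sphere_shell_model(diameter = 100, thickness = thickness,
                               E = E, nu = 0.3, P = P)
      cache[[key]] <- list(model = sp,
                           mesh = build_sphere_model(sp,
                                                     resolution = resolution))
    }
    cache[[key]]
  }
})
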