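# Seeded generators emulating the instrument and the study populations,
# so every pipeline stage can be exercised without instrument data.

#' Specification of a synthetic force curve
#'
#' Describes one linear-contact indentation as the instrument records
#' it: flat baseline before contact, then a rising flank whose slope is
#' the series combination of the true sample stiffness and the
#' instrument-chain stiffness, with additive Gaussian force noise.
#'
#' @param k_true true sample stiffness (N/m).
#' @param z0 contact displacement (um).
#' @param k_system instrument-chain stiffness (N/m).
#' @param noise_sd force noise standard deviation (uN).
#' @param max_force force at which the approach stops (uN).
#' @param dz sampling step (um).
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @return an object of class `curve_gen_spec`.
#' @export
curve_gen_spec <- function(k_true, z0 = 5, k_system = 300, noise_sd = 0.02,
                           max_force = 20, dz = 0.02, seed = NULL) {
  stopifnot(k_true > 0, k_system > 0, noise_sd >= 0, z0 >= 0,
            max_force > 0, dz > 0)
  structure(list(k_true = k_true, z0 = z0, k_system = k_system,
                 noise_sd = noise_sd, max_force = max_force, dz = dz,
                 seed = seed), class = "curve_gen_spec")
}

#' Generate a synthetic force curve
#'
#' Produces the stage-displacement/force record implied by a
#' [curve_gen_spec()]: zero-mean baseline noise up to the contact point,
#' then force rising at the effective slope
#' \eqn{k_{eff} = (1/k_{true} + 1/k_{system})^{-1}} (sample and
#' instrument springs in series), so that the analysis pipeline's
#' compliance correction recovers `k_true`.
#'
#' @param spec a [curve_gen_spec()].
#' @param specimen_id,region,curve_id metadata for the generated curve.
#' @return a [force_curve()].
#' @export
gen_force_curve <- function(spec, specimen_id = "synthetic",
                            region = "intine", curve_id = NULL) {
  stopifnot(inherits(spec, "curve_gen_spec"))
  k_eff <- 1 / (1 / spec$k_true + 1 / spec$k_system)
  z_end <- spec$z0 + spec$max_force / k_eff
  z <- seq(0, z_end, by = spec$dz)
  if (max(z) <= spec$z0)
    stop("displacement range does not cover the contact point")
  with_seed(spec$seed, {
    F <- ifelse(z < spec$z0, 0, k_eff * (z - spec$z0))
    if (spec$noise_sd > 0) F <- F + stats::rnorm(length(z), 0, spec$noise_sd)
    force_curve(z = z, F = F, specimen_id = specimen_id, region = region,
                curve_id = curve_id %||%
                  sprintf("%s/%s/k%.3g", specimen_id, region, spec$k_true))
  })
}

#' Specification of a synthetic pollen population
#'
#' Emulates the measured stiffness populations of hydrated pollen
#' grains: a bimodal (two-component normal mixture) exine marginal, a
#' per-grain intine/exine stiffness ratio drawn around `ratio_mean`, and
#' measurement-level multiplicative repeatability noise.  The default
#' parameters are the printed population values for grains in deionized
#' water (exine 16.5 +/- 6.6 N/m, ratio 0.56 +/- 0.10, repeatability
#' CV 4.8%); `medium = "cacl2_5mM"` switches the ratio mean to 0.66.
#'
#' The mixture components sit at 0.7x and 1.4x a base stiffness chosen
#' so that the mixture reproduces `exine_mean`, with component spreads
#' chosen to reproduce `exine_sd`.
#'
#' @param n_grains number of grains.
#' @param m_per_grain indentations per grain (split evenly between the
#'   colpus and exine regions).
#' @param ratio_mean,ratio_sd per-grain intine/exine ratio distribution
#'   (truncated positive).
#' @param exine_mean,exine_sd marginal mean and SD of the exine
#'   stiffness (N/m).
#' @param cv multiplicative repeatability noise (fraction).
#' @param medium `"water"`, `"cacl2_5mM"` or `"dry"` label; switching to
#'   CaCl2 sets `ratio_mean = 0.66` unless given explicitly.
#' @param k_system instrument stiffness used for synthetic acquisition.
#' @param noise_sd force noise of generated curves (uN).
#' @param seed integer seed.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_grains = 30, m_per_grain = 10,
                            ratio_mean = NULL, ratio_sd = 0.10,
                            exine_mean = 16.5, exine_sd = 6.6,
                            cv = 0.048,
                            medium = c("water", "cacl2_5mM", "dry"),
                            k_system = 300, noise_sd = 0.02, seed = 1) {
  medium <- match.arg(medium)
  if (is.null(ratio_mean))
    ratio_mean <- switch(medium, water = 0.56, cacl2_5mM = 0.66, dry = 1)
  stopifnot(n_grains >= 1, m_per_grain >= 2, ratio_mean > 0, ratio_sd >= 0,
            exine_mean > 0, exine_sd >= 0, cv >= 0, k_system > 0)
  # equal-weight components at 0.7x and 1.4x the base value
  base <- exine_mean / 1.05
  mu <- c(0.7, 1.4) * base
  between <- 0.25 * (mu[2] - mu[1])^2
  if (exine_sd^2 <= between)
    stop("exine_sd too small for the bimodal separation of the mixture")
  comp_sd <- sqrt(exine_sd^2 - between)
  structure(list(n_grains = n_grains, m_per_grain = m_per_grain,
                 ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                 exine_mean = exine_mean, exine_sd = exine_sd,
                 mixture = list(means = mu, sds = rep(comp_sd, 2),
                                weights = c(0.5, 0.5)),
                 cv = cv, medium = medium, k_system = k_system,
                 noise_sd = noise_sd, seed = seed),
            class = "population_spec")
}

rtrunc_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

rmixture <- function(n, mix) {
  comp <- 1L + (stats::runif(n) > mix$weights[1])
  x <- stats::rnorm(n, mix$means[comp], mix$sds[comp])
  while (any(bad <- x <= 0))
    x[bad] <- stats::rnorm(sum(bad), mix$means[comp[bad]], mix$sds[comp[bad]])
  x
}

#' Generate a synthetic pollen population
#'
#' Draws per-grain true stiffness pairs (exine from the bimodal
#' mixture, intine as ratio times exine), adds measurement-level
#' multiplicative repeatability noise, and either returns the stiffness
#' values directly or renders every measurement as a synthetic force
#' curve for the full pipeline.
#'
#' @param spec a [population_spec()].
#' @param curves if `TRUE`, also generate a [force_curve()] per
#'   measurement (slower; exercises contact detection and compliance
#'   correction).
#' @return list with `truth` (per-grain true values), `measurements`
#'   (data.frame of per-indentation stiffness, before instrument
#'   effects) and, if requested, `curves` (list of force curves).
#' @export
gen_pollen_population <- function(spec, curves = FALSE) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    n <- spec$n_grains
    k_e <- rmixture(n, spec$mixture)
    r <- rtrunc_pos(n, spec$ratio_mean, spec$ratio_sd)
    k_i <- r * k_e
    truth <- data.frame(specimen_id = sprintf("grain%03d", seq_len(n)),
                        k_e_true = k_e, k_i_true = k_i, ratio_true = r,
                        medium = spec$medium, stringsAsFactors = FALSE)
    m_i <- ceiling(spec$m_per_grain / 2)
    m_e <- spec$m_per_grain - m_i
    rows <- list(); cvs <- list()
    for (g in seq_len(n)) {
      kk <- c(rep(k_i[g], m_i), rep(k_e[g], m_e))
      reg <- c(rep("intine", m_i), rep("exine", m_e))
      noise <- rtrunc_pos(length(kk), 1, spec$cv)
      kobs <- kk * noise
      rows[[g]] <- data.frame(specimen_id = truth$specimen_id[g],
                              region = reg, k_true = kobs,
                              stringsAsFactors = FALSE)
      if (curves) {
        cvs[[g]] <- lapply(seq_along(kobs), function(j) {
          gen_force_curve(
            curve_gen_spec(k_true = kobs[j],
                           z0 = stats::runif(1, 4, 6),
                           k_system = spec$k_system,
                           noise_sd = spec$noise_sd),
            specimen_id = truth$specimen_id[g], region = reg[j],
            curve_id = sprintf("%s/%s/%02d", truth$specimen_id[g], reg[j], j))
        })
      }
    }
    out <- list(truth = truth, measurements = do.call(rbind, rows),
                spec = spec)
    if (curves) out$curves <- do.call(c, cvs)
    out
  })
}

#' Specification of a synthetic worm stiffness map
#'
#' Emulates the cylindrical indentation survey of a single nematode:
#' lines of sites along the longitudinal axis at successive rotation
#' angles, with stiff bands (e.g. body-wall muscle regions) at given
#' angular positions and soft regions elsewhere.  Defaults reproduce
#' the printed group parameters: soft 0.53 +/- 0.07 N/m, stiff
#' 0.75 +/- 0.11 N/m, with two stiff bands so that adjacent soft/stiff
#' band centers sit about 90 degrees apart and the default 5 x 10
#' layout yields 20 soft and 30 stiff sites.
#'
#' @param n_lines number of indentation lines (rotations).
#' @param sites_per_line sites per line (up to 11).
#' @param spacing axial spacing between sites (um).
#' @param rotation_angles declared rotation per line (degrees); the
#'   five-line default surveys the circumference in quarter turns plus
#'   one intermediate orientation, which with the default bands yields
#'   the 20 soft / 30 stiff split.
#' @param band_centers,band_width stiff-band centers and full width
#'   (degrees).
#' @param k_soft,k_stiff `c(mean, sd)` of the two groups (N/m).
#' @param drift true (unknown to the analyst) extra rotation per line
#'   (degrees).
#' @param fiducial_noise_sd angular noise of the per-line fiducial
#'   observation (degrees).
#' @param seed integer seed.
#' @return an object of class `worm_gen_spec`.
#' @export
worm_gen_spec <- function(n_lines = 5, sites_per_line = 10, spacing = 20,
                          rotation_angles = if (n_lines == 5)
                            c(0, 90, 180, 270, 315)
                          else seq(0, by = 360 / n_lines,
                                   length.out = n_lines),
                          band_centers = c(90, 270), band_width = 90,
                          k_soft = c(0.53, 0.07), k_stiff = c(0.75, 0.11),
                          drift = rep(0, n_lines), fiducial_noise_sd = 0.5,
                          seed = 1) {
  stopifnot(n_lines >= 1, sites_per_line >= 1, sites_per_line <= 11,
            spacing > 0, length(rotation_angles) == n_lines,
            length(drift) == n_lines, band_width >= 0,
            all(band_centers >= 0), all(band_centers < 360))
  if (band_width > 0 && length(band_centers) * band_width >= 360)
    stop("stiff bands cover the full circumference")
  structure(list(n_lines = n_lines, sites_per_line = sites_per_line,
                 spacing = spacing, rotation_angles = rotation_angles,
                 band_centers = band_centers, band_width = band_width,
                 k_soft = k_soft, k_stiff = k_stiff, drift = drift,
                 fiducial_noise_sd = fiducial_noise_sd, seed = seed),
            class = "worm_gen_spec")
}

ang_dist <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Generate a synthetic worm stiffness map
#'
#' Places sites on the (axial position, angle) grid, drawing stiffness
#' from the stiff-group distribution inside the stiff bands and from
#' the soft group elsewhere; per-line drift is added to the true angles
#' and a noisy fiducial observation (apparent angle of a fixed body
#' landmark) is emitted per line so the analysis stage can recover the
#' drift.
#'
#' @param spec a [worm_gen_spec()].
#' @return list with `lines` (per-line data.frames of `s_um` and
#'   `k_Npm`), `rotation_angles`, `fiducials`, and `truth` (data.frame
#'   with true angles and band labels).
#' @export
gen_worm_map <- function(spec) {
  stopifnot(inherits(spec, "worm_gen_spec"))
  with_seed(spec$seed, {
    theta_landmark <- 0 # body frame reference
    lines <- list(); truth <- list(); fid <- numeric(spec$n_lines)
    for (l in seq_len(spec$n_lines)) {
      th_true <- (spec$rotation_angles[l] + spec$drift[l]) %% 360
      stiff <- spec$band_width > 0 &
        any(ang_dist(th_true, spec$band_centers) <= spec$band_width / 2)
      par <- if (stiff) spec$k_stiff else spec$k_soft
      k <- rtrunc_pos(spec$sites_per_line, par[1], par[2])
      s <- spec$spacing * (seq_len(spec$sites_per_line) - 1)
      lines[[l]] <- data.frame(s_um = s, k_Npm = k)
      truth[[l]] <- data.frame(line = l, s_um = s, theta_true = th_true,
                               band = if (stiff) "stiff" else "soft",
                               drift = spec$drift[l])
      fid[l] <- (theta_landmark - th_true +
                   stats::rnorm(1, 0, spec$fiducial_noise_sd)) %% 360
    }
    list(lines = lines, rotation_angles = spec$rotation_angles,
         fiducials = fid, truth = do.call(rbind, truth), spec = spec)
  })
}
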