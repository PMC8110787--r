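# Curve processing: contact detection, slope fitting, compliance
# correction, and their composition into a stiffness measurement.

#' Detect the contact point of a force curve
#'
#' The pre-contact baseline is estimated from the first quarter of the
#' samples (mean and standard deviation); the raw contact index is the
#' first sample exceeding baseline + `noise_mult` standard deviations.
#' The estimate is then refined by fitting a line to the early rising
#' part of the curve and back-extrapolating it to the baseline force,
#' which reduces the bias the threshold crossing has on noisy curves
#' and reduces to the exact kink position for noiseless ones.
#'
#' @param curve a [force_curve()].
#' @param noise_mult threshold in baseline standard deviations.
#' @return contact displacement z0 (um).
#' @export
detect_contact_point <- function(curve, noise_mult = 5) {
  z <- curve$z; F <- curve$F
  nb <- max(10L, floor(length(z) * 0.25))
  if (length(z) < nb) stop("curve too short for baseline estimation")
  base <- mean(F[seq_len(nb)])
  s <- stats::sd(F[seq_len(nb)])
  thr <- base + noise_mult * max(s, 1e-12)
  above <- F > thr
  # demand two consecutive samples above threshold to reject spikes
  ic <- which(above & c(above[-1], FALSE))[1]
  if (is.na(ic))
    stop("no contact detected in curve '", curve$curve_id, "'")
  if (ic == 1L)
    warning("no baseline: contact at the first sample of curve '",
            curve$curve_id, "'")
  # refine on the rising flank: samples between the crossing and 60% of
  # the maximum force excess
  top <- base + 0.6 * (max(F) - base)
  ir <- which(F >= top)[1]
  if (is.na(ir) || ir - ic < 4L) ir <- min(ic + 9L, length(z))
  idx <- ic:ir
  fit <- stats::lm(F[idx] ~ z[idx])
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope <= 0) return(z[max(ic - 1L, 1L)])
  z0 <- as.numeric((base - coef(fit)[1]) / slope)
  # keep the refinement inside the sampled range and near the crossing
  min(max(z0, z[1]), z[ic])
}

#' Fit the apparent stiffness of a force curve
#'
#' Least-squares slope of force against displacement restricted to a
#' force-fraction window of the post-contact curve; the default window
#' is the upper half of the force range, where the response of turgid
#' samples is close to linear.
#'
#' @param curve a [force_curve()].
#' @param z0 contact displacement (um), e.g. from
#'   [detect_contact_point()].
#' @param window force-fraction interval within (0, 1].
#' @return list with `k_uncorrected` (N/m), `r_squared`, `n_points`,
#'   and the displacement `fit_window` actually used.
#' @export
fit_stiffness <- function(curve, z0, window = c(0.5, 1.0)) {
  stopifnot(length(window) == 2, window[1] < window[2],
            window[1] >= 0, window[2] <= 1)
  post <- curve$z >= z0
  Fmax <- max(curve$F[post])
  sel <- post & curve$F >= window[1] * Fmax & curve$F <= window[2] * Fmax
  if (sum(sel) < 5)
    stop("window too narrow: ", sum(sel), " samples in the fit window of '",
         curve$curve_id, "'")
  zf <- curve$z[sel]; Ff <- curve$F[sel]
  zm <- mean(zf); Fm <- mean(Ff)
  k <- sum((zf - zm) * (Ff - Fm)) / sum((zf - zm)^2)
  ss_res <- sum((Ff - Fm - k * (zf - zm))^2)
  ss_tot <- sum((Ff - Fm)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(k_uncorrected = k, r_squared = r2, n_points = sum(sel),
       fit_window = range(zf))
}

#' Correct a measured stiffness for instrument compliance
#'
#' The sample and the measuring system deform in series, so the sample
#' stiffness follows from the measured slope as
#' \deqn{k_{sample} = \left(\frac{1}{k_{measured}} -
#'   \frac{1}{k_{system}}\right)^{-1}.}
#' The correction always increases the stiffness and diverges as the
#' measured slope approaches the system stiffness.
#'
#' @param k_measured measured slope (N/m).
#' @param cal a [calibration_record()] (or a bare positive number).
#' @return corrected sample stiffness (N/m).
#' @export
correct_compliance <- function(k_measured, cal) {
  k_system <- if (inherits(cal, "calibration_record")) cal$k_system
              else as.numeric(cal)
  stopifnot(k_system > 0)
  if (any(k_measured <= 0))
    stop("measured stiffness must be positive")
  if (any(k_measured >= k_system))
    stop("measured stiffness exceeds system stiffness")
  1 / (1 / k_measured - 1 / k_system)
}

#' Process a force curve into a stiffness measurement
#'
#' Composition of the three analysis steps: contact-point detection,
#' windowed slope fit, and series-compliance correction.  All
#' intermediate quantities are kept on the result for audit.
#'
#' @param curve a [force_curve()].
#' @param cal a [calibration_record()].
#' @param noise_mult,window passed to [detect_contact_point()] and
#'   [fit_stiffness()].
#' @return an object of class `stiffness_measurement`.
#' @export
process_curve <- function(curve, cal, noise_mult = 5, window = c(0.5, 1.0)) {
  stopifnot(inherits(curve, "force_curve"))
  z0 <- tryCatch(detect_contact_point(curve, noise_mult),
                 error = function(e)
                   stop("curve '", curve$curve_id, "': ",
                        conditionMessage(e), call. = FALSE))
  fit <- tryCatch(fit_stiffness(curve, z0, window),
                  error = function(e)
                    stop("curve '", curve$curve_id, "': ",
                         conditionMessage(e), call. = FALSE))
  k <- tryCatch(correct_compliance(fit$k_uncorrected, cal),
                error = function(e)
                  stop("curve '", curve$curve_id, "': ",
                       conditionMessage(e), call. = FALSE))
  structure(list(k = k, k_uncorrected = fit$k_uncorrected,
                 contact_point = z0, fit_window = fit$fit_window,
                 r_squared = fit$r_squared, n_points = fit$n_points,
                 region = curve$region, specimen_id = curve$specimen_id,
                 curve_id = curve$curve_id,
                 k_system = if (inherits(cal, "calibration_record"))
                   cal$k_system else as.numeric(cal)),
            class = "stiffness_measurement")
}

#' @export
print.stiffness_measurement <- function(x, ...) {
  cat(sprintf("stiffness_measurement '%s' (%s/%s)\n", x$curve_id,
              x$specimen_id, x$region))
  cat(sprintf("  k = %.4g N/m (raw slope %.4g, k_system %g, r2 = %.4f)\n",
              x$k, x$k_uncorrected, x$k_system, x$r_squared))
  cat(sprintf("  contact at z0 = %.3f um, fit window %.3f-%.3f um (%d pts)\n",
              x$contact_point, x$fit_window[1], x$fit_window[2], x$n_points))
  invisible(x)
}

#' Process a batch of force curves
#'
#' @param curves list of [force_curve()] objects.
#' @param cal a [calibration_record()].
#' @param ... passed to [process_curve()].
#' @return data.frame with one row per curve (all
#'   `stiffness_measurement` fields).
#' @export
process_batch <- function(curves, cal, ...) {
  rows <- lapply(curves, function(cu) {
    m <- process_curve(cu, cal, ...)
    data.frame(curve_id = m$curve_id, specimen_id = m$specimen_id,
               region = m$region, k = m$k, k_uncorrected = m$k_uncorrected,
               contact_point = m$contact_point,
               fit_lo = m$fit_window[1], fit_hi = m$fit_window[2],
               r_squared = m$r_squared, n_points = m$n_points,
               k_system = m$k_system, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
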