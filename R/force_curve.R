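#' Force-displacement curve from a single indentation
#'
#' Container for one micro-indentation record: stage displacement and
#' measured force sampled along the approach, plus acquisition
#' metadata.  Displacement is in micrometres, force in micronewtons, so
#' slopes are in uN/um = N/m.
#'
#' @param z displacement samples (um), strictly increasing.
#' @param F force samples (uN), same length as `z`.
#' @param velocity indentation speed (um/s).
#' @param approach_distance pre-contact travel (um).
#' @param sensor_id,specimen_id labels.
#' @param region one of `"intine"`, `"exine"`, `"dry_exine"`, `"worm"`,
#'   `"calibration"`.
#' @param curve_id optional identifier used in error messages and audit
#'   output.
#' @return an object of class `force_curve`.
#' @export
force_curve <- function(z, F, velocity = 4, approach_distance = 20,
                        sensor_id = "FT-S100", specimen_id = "unknown",
                        region = c("intine", "exine", "dry_exine", "worm",
                                   "calibration"),
                        curve_id = NULL) {
  region <- match.arg(region)
  z <- as.numeric(z); F <- as.numeric(F)
  if (length(z) != length(F))
    stop("z and F must have the same length")
  if (length(z) < 10)
    stop("a force curve needs at least 10 samples")
  if (any(!is.finite(z)) || any(!is.finite(F)))
    stop("displacement and force samples must be finite")
  if (any(diff(z) <= 0))
    stop("displacement must be strictly increasing along the approach")
  stopifnot(velocity > 0, approach_distance >= 0)
  structure(list(z = z, F = F, velocity = velocity,
                 approach_distance = approach_distance,
                 sensor_id = sensor_id, specimen_id = specimen_id,
                 region = region,
                 curve_id = curve_id %||% paste0(specimen_id, "/", region)),
            class = "force_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force_curve '%s': %d samples, z %.2f-%.2f um, F max %.3f uN\n",
              x$curve_id, length(x$z), min(x$z), max(x$z), max(x$F)))
  cat(sprintf("  specimen %s, region %s, sensor %s, v = %g um/s\n",
              x$specimen_id, x$region, x$sensor_id, x$velocity))
  invisible(x)
}

#' @export
plot.force_curve <- function(x, ...) {
  graphics::plot(x$z, x$F, type = "l",
                 xlab = "stage displacement (um)", ylab = "force (uN)",
                 main = x$curve_id, ...)
  invisible(x)
}

#' Instrument-chain calibration record
#'
#' Stiffness of the measuring system itself (sensor, probe, mounting),
#' obtained by indenting a rigid surface such as a glass slide.  Sample
#' stiffness is recovered from the measured slope by the series-spring
#' correction in [correct_compliance()].
#'
#' @param k_system system stiffness (N/m), positive.
#' @param source_curve_id label of the calibration curve.
#' @return an object of class `calibration_record`.
#' @export
calibration_record <- function(k_system, source_curve_id = "calibration") {
  stopifnot(is.numeric(k_system), length(k_system) == 1, k_system > 0)
  structure(list(k_system = k_system, source_curve_id = source_curve_id),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("calibration_record: k_system = %g N/m (from %s)\n",
              x$k_system, x$source_curve_id))
  invisible(x)
}

#' Read a force curve from a delimited text file
#'
#' Expects columns `z_um` and `F_uN`; metadata (velocity, approach
#' distance, sensor, specimen, region) is read from a sidecar JSON file
#' if present (same path with extension `.json`), otherwise defaults
#' apply.
#'
#' @param path CSV/TSV file path.
#' @param meta optional named list overriding sidecar metadata.
#' @return a [force_curve()].
#' @export
read_force_curve <- function(path, meta = list()) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.csv(path, sep = sep)
  if (!all(c("z_um", "F_uN") %in% names(d)))
    stop("expected columns z_um and F_uN in ", path)
  side <- sub("\\.[ct]sv$", ".json", path, ignore.case = TRUE)
  sm <- if (file.exists(side) && side != path)
    jsonlite::read_json(side, simplifyVector = TRUE) else list()
  sm[names(meta)] <- meta
  force_curve(z = d$z_um, F = d$F_uN,
              velocity = sm$velocity %||% 4,
              approach_distance = sm$approach_distance %||% 20,
              sensor_id = sm$sensor_id %||% "FT-S100",
              specimen_id = sm$specimen_id %||% "unknown",
              region = sm$region %||% "intine",
              curve_id = sm$curve_id %||% basename(path))
}

#' Write a force curve (and sidecar metadata) to disk
#'
#' @param curve a [force_curve()].
#' @param path output CSV path; metadata goes to the matching `.json`.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  utils::write.csv(data.frame(z_um = curve$z, F_uN = curve$F), path,
                   row.names = FALSE)
  side <- sub("\\.csv$", ".json", path, ignore.case = TRUE)
  meta <- curve[c("velocity", "approach_distance", "sensor_id",
                  "specimen_id", "region", "curve_id")]
  jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
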