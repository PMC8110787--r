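# End-to-end workflows tying the stages together, with reproducible
# configuration, seeds and provenance stamps.

config_hash <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(x, tf, ascii = TRUE) # ascii form is stable for equal configs
  unname(tools::md5sum(tf))
}

stamp <- function(config, seed) {
  list(config_hash = config_hash(config), seed = seed,
       package_version = as.character(utils::packageVersion("turgorcfm")))
}

#' Run the pollen characterization workflow
#'
#' From force curves (or the synthetic population generator) to
#' per-grain intine/exine ratios and the water-vs-CaCl2 style group
#' comparison.  With `fem = TRUE` a matched parameter sweep of the
#' two-layer shell model is run and the best-fitting parameter
#' combination is selected jointly on the apparent stiffness at the
#' colpus and the reaction force at 1.8 um depth.
#'
#' @param config list with entries:
#'   \describe{
#'     \item{curves}{list of [force_curve()]s, or NULL to use `synth`.}
#'     \item{synth}{list of one or two [population_spec()]s (named,
#'       e.g. `water` and `cacl2`) rendered through the full pipeline.}
#'     \item{calibration}{a [calibration_record()]; defaults to the
#'       synthetic spec's `k_system`.}
#'     \item{window,noise_mult}{curve-processing options.}
#'     \item{fem}{optional list(model, P_values, E_i_values, E_e_values,
#'       resolution) enabling the simulation sweep.}
#'     \item{seed}{integer seed stamped into every output.}
#'   }
#' @param out_dir optional directory to write `ratios.csv`,
#'   `stats.json` (and `sweep.csv`).
#' @return list with `measurements`, `ratios` (per population),
#'   `comparison`, optional `sweep`/`best_fit`, and the provenance
#'   `stamp`.
#' @export
run_pollen_workflow <- function(config, out_dir = NULL) {
  seed <- config$seed %||% 1
  if (is.null(config$curves) && is.null(config$synth))
    stop("validation error: config must provide curves or a synthetic spec")
  pops <- list()
  if (!is.null(config$curves)) {
    if (!length(config$curves)) stop("validation error: empty curve set")
    cal <- config$calibration %||% stop("calibration required for curves")
    meas <- process_batch(config$curves, cal,
                          noise_mult = config$noise_mult %||% 5,
                          window = config$window %||% c(0.5, 1.0))
    pops$measured <- meas
  }
  if (!is.null(config$synth)) {
    specs <- config$synth
    if (inherits(specs, "population_spec")) specs <- list(pop = specs)
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      gen <- gen_pollen_population(sp, curves = TRUE)
      cal <- config$calibration %||% calibration_record(sp$k_system)
      pops[[nm]] <- process_batch(gen$curves, cal,
                                  noise_mult = config$noise_mult %||% 5,
                                  window = config$window %||% c(0.5, 1.0))
    }
  }
  ratios <- lapply(pops, ratio_table)
  summaries <- lapply(ratios, summarize_population)
  normality <- lapply(ratios, function(r)
    if (nrow(r) >= 8) normality_test(r$ratio) else NULL)
  comparison <- NULL
  if (length(ratios) >= 2) {
    nm <- names(ratios)[1:2]
    comparison <- c(list(groups = nm),
                    compare_groups(ratios[[nm[1]]]$ratio,
                                   ratios[[nm[2]]]$ratio))
  }
  sweep <- best_fit <- NULL
  if (!is.null(config$fem)) {
    f <- config$fem
    sweep <- run_parameter_sweep(f$model %||% pollen_model(),
                                 P_values = f$P_values %||% c(0.1, 0.2, 0.3),
                                 E_i_values = f$E_i_values %||% c(5, 10, 20),
                                 E_e_values = f$E_e_values %||% c(20, 100),
                                 resolution = f$resolution %||% 3000)
    target_k <- f$target_k %||% 8.1
    ok <- sweep$site == "colpus_center" & !is.na(sweep$k_apparent)
    if (any(ok)) {
      cand <- sweep[ok, ]
      best_fit <- cand[which.min(abs(cand$k_apparent - target_k)), ]
    }
  }
  res <- list(measurements = pops, ratios = ratios, summaries = summaries,
              normality = normality, comparison = comparison, sweep = sweep,
              best_fit = best_fit,
              stamp = stamp(config[setdiff(names(config), "curves")], seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(ratios))
      utils::write.csv(ratios[[nm]],
                       file.path(out_dir, paste0("ratios_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(summaries = summaries, normality = normality,
           comparison = comparison, stamp = res$stamp),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, force = TRUE)
    if (!is.null(sweep))
      utils::write.csv(sweep, file.path(out_dir, "sweep.csv"),
                       row.names = FALSE)
  }
  res
}

#' Run the worm mapping workflow
#'
#' From per-line indentation records (or the synthetic map generator)
#' to the unfolded stiffness map and the soft/stiff band comparison.
#'
#' @param config list with entries: `lines`, `rotation_angles`,
#'   `drift_offsets`/`fiducials` (as in [assign_coordinates()]) or
#'   `synth` (a [worm_gen_spec()]); `labels` (`"truth"` for synthetic
#'   maps, `"kmeans"`, or an explicit vector); `seed`.
#' @param out_dir optional directory to write `map.csv` and
#'   `bands.json`.
#' @return list with the `map`, `grid`, `bands` and provenance `stamp`.
#' @export
run_worm_workflow <- function(config, out_dir = NULL) {
  seed <- config$seed %||% 1
  truth <- NULL
  if (!is.null(config$synth)) {
    gen <- gen_worm_map(config$synth)
    map <- assign_coordinates(gen$lines, gen$rotation_angles,
                              fiducials = gen$fiducials)
    truth <- gen$truth
  } else {
    if (is.null(config$lines) || !length(config$lines))
      stop("validation error: no indentation lines provided")
    map <- assign_coordinates(config$lines, config$rotation_angles,
                              drift_offsets = config$drift_offsets,
                              fiducials = config$fiducials)
  }
  labels <- config$labels %||% "kmeans"
  if (identical(labels, "truth")) {
    if (is.null(truth)) stop("truth labels only exist for synthetic maps")
    labels <- truth$band
  }
  bands <- band_comparison(map, labels)
  res <- list(map = map, grid = unfold(map), bands = bands, truth = truth,
              stamp = stamp(config[setdiff(names(config), "lines")], seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(map$sites, file.path(out_dir, "map.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(bands = bands, stamp = res$stamp),
                         file.path(out_dir, "bands.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  res
}
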