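# Per-specimen aggregation and the group-comparison statistics used for
# the pollen populations.

#' Bundle measurements of one specimen
#'
#' @param specimen_id label shared by all measurements.
#' @param measurements data.frame with columns `region` and `k` (N/m),
#'   or a list of `stiffness_measurement` objects.
#' @param medium `"water"`, `"cacl2_5mM"` or `"dry"`.
#' @return an object of class `specimen`.
#' @export
specimen <- function(specimen_id, measurements,
                     medium = c("water", "cacl2_5mM", "dry")) {
  medium <- match.arg(medium)
  if (is.list(measurements) && !is.data.frame(measurements))
    measurements <- do.call(rbind, lapply(measurements, function(m)
      data.frame(region = m$region, k = m$k, stringsAsFactors = FALSE)))
  stopifnot(all(c("region", "k") %in% names(measurements)),
            all(measurements$k > 0))
  structure(list(specimen_id = specimen_id, medium = medium,
                 measurements = measurements), class = "specimen")
}

#' Per-grain intine/exine stiffness ratio
#'
#' One ratio per specimen: the mean colpus (intine) apparent stiffness
#' divided by the mean exine apparent stiffness of the same grain.
#' Working per grain removes most of the between-grain biological
#' scatter that dominates the raw stiffness populations.
#'
#' @param spec a [specimen()] (or a data.frame with `region` and `k`).
#' @return an object of class `ratio_record`: `specimen_id`,
#'   `k_i_mean`, `k_e_mean`, `ratio`, and per-region counts.
#' @export
per_grain_ratio <- function(spec) {
  meas <- if (inherits(spec, "specimen")) spec$measurements else spec
  id <- if (inherits(spec, "specimen")) spec$specimen_id else "specimen"
  ki <- meas$k[meas$region == "intine"]
  ke <- meas$k[meas$region == "exine"]
  if (!length(ki) || !length(ke))
    stop("incomplete specimen '", id,
         "': need at least one intine and one exine measurement")
  structure(list(specimen_id = id, k_i_mean = mean(ki), k_e_mean = mean(ke),
                 ratio = mean(ki) / mean(ke), n_intine = length(ki),
                 n_exine = length(ke)), class = "ratio_record")
}

#' @export
print.ratio_record <- function(x, ...) {
  cat(sprintf("ratio_record '%s': k_i = %.3g, k_e = %.3g, k_i/k_e = %.4g\n",
              x$specimen_id, x$k_i_mean, x$k_e_mean, x$ratio))
  invisible(x)
}

#' Ratios for a table of measurements
#'
#' @param measurements data.frame with `specimen_id`, `region`, `k`.
#' @return data.frame with one row per specimen.
#' @export
ratio_table <- function(measurements) {
  ids <- unique(measurements$specimen_id)
  rows <- lapply(ids, function(id) {
    r <- per_grain_ratio(measurements[measurements$specimen_id == id, ])
    data.frame(specimen_id = id, k_i_mean = r$k_i_mean,
               k_e_mean = r$k_e_mean, ratio = r$ratio,
               n_intine = r$n_intine, n_exine = r$n_exine,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Coefficient of variation
#'
#' Sample standard deviation over the mean, as used for the
#' repeatability assessment of repeated indentations.
#'
#' @param values numeric vector (>= 2 values, nonzero mean).
#' @return CV as a fraction.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("zero mean: coefficient of variation undefined")
  stats::sd(values) / m
}

#' Omnibus normality test
#'
#' Shapiro-Wilk test of the null hypothesis that the values are drawn
#' from a normal distribution; the method name is recorded so reports
#' state which omnibus test produced the p-value.
#'
#' @param values numeric vector (n >= 8).
#' @return list with `statistic`, `p`, `method`, `n`.
#' @export
normality_test <- function(values) {
  if (length(values) < 8) stop("need at least 8 values for a normality test")
  if (stats::sd(values) == 0) stop("constant values: normality test undefined")
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = "Shapiro-Wilk", n = length(values))
}

#' Two-group comparison with variance-based test selection
#'
#' An F-test on the group variances decides between the pooled-variance
#' and the Welch form of the double-sided two-sample t-test (pooled
#' when the F-test does not reject equal variances at `alpha_var`).
#' Both forms can also be forced.
#'
#' @param a,b numeric vectors (each n >= 3).
#' @param variance_rule `"auto"` (F-test), `"pooled"` or `"welch"`.
#' @param alpha_var significance level of the variance F-test.
#' @return list with `t`, `df`, `p`, `method`, the F-test result, and
#'   group summaries.
#' @export
compare_groups <- function(a, b, variance_rule = c("auto", "pooled", "welch"),
                           alpha_var = 0.05) {
  variance_rule <- match.arg(variance_rule)
  stopifnot(length(a) >= 3, length(b) >= 3)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate variance in both groups")
  ft <- stats::var.test(a, b)
  pooled <- switch(variance_rule,
                   auto = ft$p.value >= alpha_var,
                   pooled = TRUE, welch = FALSE)
  ht <- stats::t.test(a, b, var.equal = pooled, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       method = if (pooled) "pooled two-sided t-test"
                else "Welch two-sided t-test",
       f_test = list(F = unname(ft$statistic), p = ft$p.value),
       mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
       mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b))
}

#' Summary statistics of a population
#'
#' Location and spread summaries with the quantile convention fixed to
#' linear interpolation between order statistics (R type 7), matching
#' whisker conventions that report 5th/95th percentiles.
#'
#' @param values numeric vector (nonempty), or a data.frame whose
#'   `ratio` column is summarized.
#' @return one-row data.frame: n, mean, sd, median, q25, q75, q05, q95,
#'   min, max.
#' @export
summarize_population <- function(values) {
  if (is.data.frame(values)) values <- values$ratio
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                       names = FALSE)
  data.frame(n = length(values), mean = mean(values),
             sd = if (length(values) > 1) stats::sd(values) else 0,
             median = q[3], q25 = q[2], q75 = q[4], q05 = q[1], q95 = q[5],
             min = min(values), max = max(values))
}
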