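# Closed-form ordinary least squares with the flat-y R^2 = 0 convention.
.ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) pegs_error("all x values identical: degenerate fit",
                           "pegs_degenerate_fit")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r_squared = r2)
}

#' Ordinary least-squares line fit
#'
#' Fits `y = intercept + slope * x` by least squares and reports the
#' coefficient of determination `R^2 = 1 - SS_res/SS_tot`.  A flat response
#' (`SS_tot = 0`) is reported as `R^2 = 0` by convention.
#'
#' @param x,y Numeric vectors of equal length with at least two distinct `x`.
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @examples
#' linear_fit(c(0, 1, 2), c(0, 2, 3))  # slope 1.5, intercept 1/6, R^2 27/28
#' @export
linear_fit <- function(x, y) {
  stop_if_not(is.numeric(x) && is.numeric(y) && length(x) == length(y),
              "x and y must be numeric vectors of equal length")
  stop_if_not(length(x) >= 2, "need at least two points")
  .ols(x, y)
}

#' Build a calibration curve from replicate slope measurements
#'
#' Aggregates replicate slopes per concentration (mean, SD, n) and fits the
#' least-squares line of mean slope against concentration, mirroring the
#' slope-versus-NH3 calibration plots.
#'
#' @param runs A data frame with columns `conc` (ppm) and `slope` (min^-1),
#'   one row per replicate run.
#' @return An object of class `pegs_calibration`: `points` (data frame with
#'   `conc`, `mean_slope`, `sd_slope`, `n`), `fit_slope`, `fit_intercept`,
#'   `r_squared`.
#' @export
build_calibration <- function(runs) {
  stop_if_not(is.data.frame(runs) && all(c("conc", "slope") %in% names(runs)),
              "runs must be a data frame with columns conc and slope")
  stop_if_not(nrow(runs) >= 2, "need at least two runs")
  concs <- sort(unique(runs$conc))
  if (length(concs) < 2) pegs_error("need at least two distinct concentrations",
                                    "pegs_degenerate_fit")
  pts <- do.call(rbind, lapply(concs, function(cc) {
    s <- runs$slope[runs$conc == cc]
    data.frame(conc = cc, mean_slope = mean(s),
               sd_slope = if (length(s) > 1) stats::sd(s) else 0,
               n = length(s))
  }))
  fit <- .ols(pts$conc, pts$mean_slope)
  structure(list(points = pts, fit_slope = fit$slope,
                 fit_intercept = fit$intercept, r_squared = fit$r_squared),
            class = "pegs_calibration")
}

#' @export
print.pegs_calibration <- function(x, ...) {
  cat(sprintf("<pegs_calibration> slope = %.5g * conc + %.5g (R^2 %.4f)\n",
              x$fit_slope, x$fit_intercept, x$r_squared))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Invert a calibration curve
#'
#' Maps a measured slope back to a concentration through the fitted line,
#' clipping negative estimates at zero.
#'
#' @param curve A `pegs_calibration`.
#' @param slope Measured slope, min^-1 (same sign convention as the curve).
#' @return Estimated concentration in ppm.
#' @export
invert_calibration <- function(curve, slope) {
  stop_if_not(inherits(curve, "pegs_calibration"),
              "curve must be a pegs_calibration")
  if (curve$fit_slope == 0) pegs_error("calibration has zero slope",
                                       "pegs_degenerate_fit")
  max(0, (slope - curve$fit_intercept) / curve$fit_slope)
}

#' Estimate the limit of detection from blanks and a calibration
#'
#' Three-sigma criterion at the tested concentrations: the LOD is the
#' smallest tested concentration whose mean absolute slope exceeds the blank
#' mean plus three blank standard deviations (both computed on absolute
#' blank slopes).  Ties are broken toward the lower concentration; if no
#' tested concentration clears the threshold the LOD is reported as `Inf`.
#'
#' @param curve A `pegs_calibration` whose points are the tested
#'   concentrations.
#' @param blank_slopes Numeric vector of replicate blank (0 ppm) slopes,
#'   length >= 3.
#' @return A list with `lod` (ppm, possibly `Inf`), `threshold` (min^-1) and
#'   `blank_mean`, `blank_sd`.
#' @export
estimate_lod <- function(curve, blank_slopes) {
  stop_if_not(inherits(curve, "pegs_calibration"),
              "curve must be a pegs_calibration")
  if (!(is.numeric(blank_slopes) && length(blank_slopes) >= 3)) {
    pegs_error("need at least three blank replicate slopes",
               "pegs_insufficient_blanks")
  }
  b <- abs(blank_slopes)
  threshold <- mean(b) + 3 * stats::sd(b)
  pts <- curve$points[order(curve$points$conc), ]
  hit <- which(abs(pts$mean_slope) > threshold)
  lod <- if (length(hit) == 0) Inf else pts$conc[hit[1]]
  list(lod = lod, threshold = threshold, blank_mean = mean(b),
       blank_sd = stats::sd(b))
}

#' One-tailed (right) paired-samples t test
#'
#' Tests whether condition `b` exceeds condition `a` on paired, per-subject
#' measurements: `d = b - a`, `t = mean(d) / (SD(d)/sqrt(n))`, p-value from
#' the upper tail of Student's t with `n - 1` degrees of freedom.  A zero
#' difference SD yields `t = 0, p = 0.5` for identical samples and `p = 0`
#' (or 1) when the mean difference is nonzero.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`, paired by index
#'   (e.g. per-subject control and treatment slopes).
#' @return An object of class `pegs_ttest` with the per-condition summaries,
#'   `t_statistic`, `degrees_of_freedom` and one-tailed `p_value`.
#' @examples
#' paired_t_one_tailed(c(1, 2, 3), c(2, 4, 6))
#' @export
paired_t_one_tailed <- function(a, b) {
  stop_if_not(is.numeric(a) && is.numeric(b) && length(a) == length(b),
              "a and b must be numeric vectors of equal length")
  n <- length(a)
  stop_if_not(n >= 2, "need at least two pairs")
  d <- b - a
  sd_d <- stats::sd(d)
  t_stat <- if (sd_d == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    mean(d) / (sd_d / sqrt(n))
  }
  p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  structure(list(
    pairs = data.frame(a = a, b = b, diff = d),
    mean_a = mean(a), sd_a = stats::sd(a),
    mean_b = mean(b), sd_b = stats::sd(b),
    mean_diff = mean(d), sd_diff = sd_d,
    t_statistic = t_stat, degrees_of_freedom = n - 1, p_value = p
  ), class = "pegs_ttest")
}

#' @export
print.pegs_ttest <- function(x, ...) {
  cat(sprintf("<pegs_ttest> one-tailed (right) paired t test, n = %d\n",
              nrow(x$pairs)))
  cat(sprintf("  a: %.4g +/- %.4g, b: %.4g +/- %.4g\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  cat(sprintf("  t = %.4f, df = %d, p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}
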