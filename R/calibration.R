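#' KO2 primary standard record
#'
#' Primary standards are quantified spectrophotometrically: the difference in
#' A240 before and after SOD addition, converted to molar units with the
#' molar absorptivity of superoxide at 240 nm and pH 12.5
#' (2,183 L mol^-1 cm^-1, already corrected for the absorbance of the
#' hydrogen peroxide formed during decay).
#'
#' @param A240_before absorbance at 240 nm before SOD.
#' @param A240_after_sod absorbance after SOD; must be below `A240_before`.
#' @param path_length_cm cuvette path length (cm).
#' @param epsilon molar absorptivity (L mol^-1 cm^-1); default 2183.
#' @return object of class `primary_standard`.
#' @export
primary_standard <- function(A240_before, A240_after_sod,
                             path_length_cm = 1, epsilon = 2183) {
  if (A240_before <= A240_after_sod)
    stop("A240 must decrease after SOD addition (delta A must be positive)")
  if (path_length_cm <= 0) stop("path_length_cm must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(A240_before = A240_before,
                 A240_after_sod = A240_after_sod,
                 path_length_cm = path_length_cm,
                 epsilon = epsilon),
            class = "primary_standard")
}

#' Quantify a primary standard (Beer-Lambert)
#'
#' @param std a [primary_standard()].
#' @return superoxide concentration in mol L^-1:
#'   `(A_before - A_after) / (epsilon * path_length)`.
#' @export
quantify_primary_standard <- function(std) {
  stopifnot(inherits(std, "primary_standard"))
  (std$A240_before - std$A240_after_sod) / (std$epsilon * std$path_length_cm)
}

#' Fit pseudo-first-order decay to a standard trace
#'
#' Ordinary least squares on `ln(luminescence - baseline)` versus time within
#' the decay window; decay data in practice are log-linear, which is what
#' justifies the first-order model. Points whose baseline-subtracted signal
#' is non-positive are dropped (and counted); at least 5 usable points are
#' required, and the fitted rate constant must be positive.
#'
#' @param trace a [chemilum_trace()].
#' @param start_s,end_s decay window in trace time.
#' @param baseline baseline counts to subtract before taking logs.
#' @return object of class `decay_fit`: `k` (s^-1), `log_intercept`
#'   (ln counts at t = 0 of the trace time axis), `r_squared`,
#'   `fit_window`, `baseline_used`, `n_used`, `n_dropped`. Half-life is
#'   `ln(2)/k`, see [half_life()].
#' @export
fit_decay <- function(trace, start_s, end_s, baseline) {
  stopifnot(inherits(trace, "chemilum_trace"))
  idx <- which(trace$times >= start_s - 1e-9 & trace$times <= end_s + 1e-9)
  tt <- trace$times[idx]
  yy <- trace$luminescence[idx] - baseline
  usable <- yy > 0
  n_dropped <- sum(!usable)
  if (sum(usable) < 5)
    stop("fit_decay needs >= 5 points above baseline in the window (got ",
         sum(usable), ")")
  tt <- tt[usable]; ly <- log(yy[usable])
  fit <- stats::lm(ly ~ tt)
  slope <- unname(stats::coef(fit)[2])
  # a flat segment fits slope ~ 0 up to rounding; anything with a half-life
  # beyond ~220 years is not a decay
  if (!is.finite(slope) || -slope <= 1e-10)
    stop("invalid decay fit: non-decaying input (fitted k <= 0)")
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  structure(list(k = -slope,
                 log_intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 fit_window = c(start_s = start_s, end_s = end_s),
                 baseline_used = baseline,
                 n_used = sum(usable),
                 n_dropped = n_dropped),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k = %.4g /s (t1/2 = %.3g s), R2 = %.4f, n = %d (%d dropped)\n",
              x$k, log(2) / x$k, x$r_squared, x$n_used, x$n_dropped))
  invisible(x)
}

#' Back-extrapolate standard luminescence to the quantification time
#'
#' Secondary standards decay between the moment the primary standard was
#' quantified and the moment the instrument reads them; under the fitted
#' first-order model the baseline-subtracted luminescence at the
#' quantification time is `exp(log_intercept - k * quant_time)`, equivalently
#' the observed level times `exp(k * (read_time - quant_time))`.
#'
#' @param fit a [decay_fit()] (its time axis defines `quant_time`).
#' @param quant_time_s time at which the primary standard was quantified.
#' @param read_time_s time at which the signal was read; must be >=
#'   `quant_time_s`.
#' @param max_span_s warn when the extrapolation span exceeds this cap
#'   (default 120 s); the result is still returned.
#' @return baseline-subtracted counts at `quant_time_s`.
#' @export
extrapolate_luminescence <- function(fit, quant_time_s, read_time_s,
                                     max_span_s = 120) {
  stopifnot(inherits(fit, "decay_fit"))
  if (read_time_s < quant_time_s)
    stop("read_time_s must be >= quant_time_s (backward extrapolation only)")
  span <- read_time_s - quant_time_s
  if (span > max_span_s)
    warning(sprintf("extrapolation span %.1f s exceeds the %.0f s cap; %s",
                    span, max_span_s,
                    "treat the extrapolated value with caution"))
  exp(fit$log_intercept - fit$k * quant_time_s)
}

#' Calibration point
#'
#' @param concentration_nM standard concentration (nM), > 0.
#' @param extrapolated_luminescence baseline-subtracted counts extrapolated
#'   back to the quantification time.
#' @param extrapolation_time_s span of the backward extrapolation (s), >= 0;
#'   typically a fraction of a second to about a minute.
#' @return one-row data.frame usable with [build_calibration()].
#' @export
calibration_point <- function(concentration_nM, extrapolated_luminescence,
                              extrapolation_time_s = 0) {
  if (concentration_nM <= 0) stop("concentration_nM must be > 0")
  if (extrapolation_time_s < 0) stop("extrapolation_time_s must be >= 0")
  data.frame(concentration_nM = concentration_nM,
             extrapolated_luminescence = extrapolated_luminescence,
             extrapolation_time_s = extrapolation_time_s)
}

#' Build a calibration curve
#'
#' Linear regression (free intercept) of extrapolated luminescence versus
#' standard concentration. Sensitivity is reported as pM per luminescence
#' count (= 1000/slope for slope in counts per nM); the detection limit is
#' three times the sample standard deviation (n-1 denominator) of a blank
#' series; the matrix half-life is `ln(2)/matrix_k`. Curves whose Pearson r
#' falls below `r_floor` are returned with `failed = TRUE` rather than
#' rejected, so the diagnostic is visible.
#'
#' @param points data.frame of calibration points (rbind of
#'   [calibration_point()] rows), at least 3, spanning at least a factor of
#'   2 in concentration.
#' @param blanks_nM numeric vector of replicate blank measurements (nM).
#' @param matrix_k decay constant of the calibration matrix (s^-1).
#' @param r_floor minimum acceptable Pearson correlation (default 0.93).
#' @return object of class `calibration_curve`: slope (counts per nM),
#'   intercept (counts), correlation_r, sensitivity_pM_per_count,
#'   detection_limit_nM, matrix_half_life_s, n_points, failed.
#' @export
build_calibration <- function(points, blanks_nM, matrix_k, r_floor = 0.93) {
  points <- as.data.frame(points)
  stopifnot(all(c("concentration_nM", "extrapolated_luminescence")
                %in% names(points)))
  if (nrow(points) < 3)
    stop("a calibration needs >= 3 standard points (got ", nrow(points), ")")
  cr <- range(points$concentration_nM)
  if (cr[2] < 2 * cr[1])
    stop("standard concentrations must span at least a factor of 2")
  if (length(blanks_nM) < 3) stop("blank series needs >= 3 measurements")
  if (matrix_k <= 0) stop("matrix_k must be > 0")
  fit <- stats::lm(extrapolated_luminescence ~ concentration_nM, data = points)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("calibration slope must be positive")
  r <- stats::cor(points$concentration_nM, points$extrapolated_luminescence)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 correlation_r = r,
                 sensitivity_pM_per_count = 1000 / slope,
                 detection_limit_nM = 3 * stats::sd(blanks_nM),
                 matrix_half_life_s = log(2) / matrix_k,
                 n_points = nrow(points),
                 failed = r < r_floor),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> slope %.4g counts/nM, intercept %.3g, r = %.4f%s\n",
              x$slope, x$intercept, x$correlation_r,
              if (x$failed) " [FAILED r floor]" else ""))
  cat(sprintf("  sensitivity %.3g pM/count, LOD %.3g nM, matrix t1/2 %.3g s, n = %d\n",
              x$sensitivity_pM_per_count, x$detection_limit_nM,
              x$matrix_half_life_s, x$n_points))
  invisible(x)
}

#' Serialize / load a calibration curve (JSON)
#'
#' @param curve a [calibration_curve][build_calibration] object.
#' @param path file path.
#' @return `path` (write) or the curve (read).
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "calibration_curve")
}

#' Pseudo-first-order half-life
#'
#' @param k decay constant (s^-1), > 0.
#' @return half-life `ln(2)/k` in the reciprocal units of `k`.
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("k must be > 0")
  log(2) / k
}
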