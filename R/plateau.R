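#' Plateau-detection settings
#'
#' Field protocol accepts a reading once the signal is "stable": the rolling
#' coefficient of variation (sd/mean over a trailing window) stays below a
#' threshold, by default 4%, for a minimum duration.
#'
#' @param window_length_s rolling-window length in seconds (default 30 s,
#'   about 15 points at the 0.5 Hz field acquisition rate).
#' @param cv_threshold maximum coefficient of variation (fraction, default
#'   0.04).
#' @param min_duration_s minimum plateau length in seconds (default 60 s for
#'   biological segments; use 120 s for reagent blanks).
#' @return object of class `plateau_config`.
#' @export
plateau_config <- function(window_length_s = 30, cv_threshold = 0.04,
                           min_duration_s = 60) {
  if (window_length_s <= 0) stop("window_length_s must be > 0")
  if (cv_threshold <= 0 || cv_threshold >= 1)
    stop("cv_threshold must be in (0, 1)")
  structure(list(window_length_s = window_length_s,
                 cv_threshold = cv_threshold,
                 min_duration_s = min_duration_s),
            class = "plateau_config")
}

#' Summary statistics of a trace segment
#'
#' @param trace a [chemilum_trace()].
#' @param start_s,end_s segment bounds (inclusive), in trace time.
#' @param label segment label.
#' @return object of class `segment_stats`: label, mean, sd, n_points,
#'   start_s, end_s.
#' @export
segment_stats <- function(trace, start_s, end_s, label = "coral_surface") {
  stopifnot(inherits(trace, "chemilum_trace"))
  if (start_s >= end_s) stop("start_s must be < end_s")
  idx <- which(trace$times >= start_s - 1e-9 & trace$times <= end_s + 1e-9)
  if (length(idx) < 2) stop("segment must contain at least 2 points")
  x <- trace$luminescence[idx]
  structure(list(label = label, mean = mean(x), sd = stats::sd(x),
                 n_points = length(idx),
                 start_s = trace$times[idx[1]],
                 end_s = trace$times[idx[length(idx)]]),
            class = "segment_stats")
}

#' @export
print.segment_stats <- function(x, ...) {
  cat(sprintf("<segment_stats> %s: %.2f +/- %.2f counts (n=%d, %.0f-%.0f s, CV %.2f%%)\n",
              x$label, x$mean, x$sd, x$n_points, x$start_s, x$end_s,
              100 * x$sd / x$mean))
  invisible(x)
}

#' Detect a stable plateau within an annotated window
#'
#' Scans the window with a trailing rolling window of `window_length_s`
#' seconds; a point qualifies when the CV (sd/mean) over its window is below
#' `cv_threshold` and the window mean is positive (CV is undefined otherwise,
#' so such windows are simply ineligible). The latest contiguous qualifying
#' run spanning at least `min_duration_s` is returned, with mean and sd
#' computed over the full run; the field protocol reads the final steady
#' state before the tubing is moved, hence latest rather than first.
#'
#' @param trace a [chemilum_trace()].
#' @param start_s,end_s evaluation window (e.g. from an annotation).
#' @param config a [plateau_config()].
#' @param label label to attach to the returned stats.
#' @return a [segment_stats()] for the plateau, or `NULL` if no qualifying
#'   run exists.
#' @export
detect_plateau <- function(trace, start_s, end_s,
                           config = plateau_config(),
                           label = "coral_surface") {
  stopifnot(inherits(trace, "chemilum_trace"),
            inherits(config, "plateau_config"))
  idx <- which(trace$times >= start_s - 1e-9 & trace$times <= end_s + 1e-9)
  if (length(idx) < 2) stop("window must contain at least 2 points")
  tt <- trace$times[idx]
  xx <- trace$luminescence[idx]
  wlen <- config$window_length_s
  n <- length(idx)
  ok <- logical(n)
  win_start <- numeric(n)
  for (i in seq_len(n)) {
    j <- which(tt >= tt[i] - wlen - 1e-9 & tt <= tt[i] + 1e-9)
    if (length(j) < 2) next
    m <- mean(xx[j]); s <- stats::sd(xx[j])
    if (m <= 0) next                      # CV undefined; window ineligible
    ok[i] <- (s / m) < config$cv_threshold
    win_start[i] <- tt[j[1]]
  }
  runs <- rle(ok)
  if (!any(runs$values)) return(NULL)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1
  cand <- which(runs$values)
  # latest qualifying run long enough once extended back to its first
  # window's start
  for (r in rev(cand)) {
    i0 <- run_start[r]; i1 <- run_end[r]
    seg_start <- win_start[i0]
    seg_end <- tt[i1]
    if (seg_end - seg_start >= config$min_duration_s - 1e-9)
      return(segment_stats(trace, seg_start, seg_end, label = label))
  }
  NULL
}

#' Verify an SOD quench check
#'
#' After superoxide dismutase addition the signal must collapse to (or
#' slightly below) the reagent-blank baseline: the check passes iff the
#' post-SOD mean is at most the reagent-blank mean plus twice the blank sd,
#' and below the pre-SOD surface mean.
#'
#' @param surface,post_sod,reagent_blank [segment_stats()] from one session.
#' @return logical.
#' @export
verify_sod_quench <- function(surface, post_sod, reagent_blank) {
  stopifnot(inherits(surface, "segment_stats"),
            inherits(post_sod, "segment_stats"),
            inherits(reagent_blank, "segment_stats"))
  post_sod$mean <= reagent_blank$mean + 2 * reagent_blank$sd &&
    post_sod$mean < surface$mean
}

#' Blank-correct a segment signal
#'
#' Two schemes mirror the field protocol:
#' `coral_minus_sw` subtracts the seawater background (5-15 cm away) from the
#' coral-surface signal, removing the seawater and reagent blanks at once;
#' `raw_minus_reagent_blank` subtracts only the reagent blank (used for the
#' seawater backgrounds themselves). Negative corrected values are
#' meaningful (surfaces can sit below background) and are never clipped.
#'
#' @param target [segment_stats()] to correct.
#' @param reference [segment_stats()] to subtract.
#' @param scheme `"coral_minus_sw"` or `"raw_minus_reagent_blank"`.
#' @return object of class `corrected_signal`: value (counts), temporal sd of
#'   the target (counts), scheme, provenance labels.
#' @export
correct_signal <- function(target, reference,
                           scheme = c("coral_minus_sw",
                                      "raw_minus_reagent_blank")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(target, "segment_stats"),
            inherits(reference, "segment_stats"))
  if (scheme == "coral_minus_sw") {
    if (!reference$label %in% c("background_sw_surface", "background_sw_depth"))
      stop("scheme 'coral_minus_sw' expects a reference labelled ",
           "'background_sw_surface' or 'background_sw_depth', got '",
           reference$label, "'")
  } else {
    if (reference$label != "reagent_blank")
      stop("scheme 'raw_minus_reagent_blank' expects a reference labelled ",
           "'reagent_blank', got '", reference$label, "'")
  }
  structure(list(value = target$mean - reference$mean,
                 temporal_sd = target$sd,
                 scheme = scheme,
                 provenance = c(target$label, reference$label)),
            class = "corrected_signal")
}

#' Peak corrected reading within a segment
#'
#' The maximum single blank-corrected reading within a segment (e.g. the
#' coral-surface phase). How "peak" levels should be selected from a trace
#' is a convention, not a protocol rule; this maximum-of-single-readings
#' convention is flagged as such on the result.
#'
#' @param trace a [chemilum_trace()].
#' @param start_s,end_s segment bounds.
#' @param reference [segment_stats()] of the blank to subtract.
#' @return list: `peak_value` (counts above the reference mean),
#'   `time_s` of the peak sample, `convention`.
#' @export
peak_corrected_signal <- function(trace, start_s, end_s, reference) {
  stopifnot(inherits(trace, "chemilum_trace"),
            inherits(reference, "segment_stats"))
  idx <- which(trace$times >= start_s - 1e-9 & trace$times <= end_s + 1e-9)
  if (length(idx) < 1) stop("empty segment")
  i <- idx[which.max(trace$luminescence[idx])]
  list(peak_value = trace$luminescence[i] - reference$mean,
       time_s = trace$times[i],
       convention = "max single corrected reading (convention-dependent)")
}

#' @export
print.corrected_signal <- function(x, ...) {
  cat(sprintf("<corrected_signal> %.2f counts [%s: %s - %s]\n",
              x$value, x$scheme, x$provenance[1], x$provenance[2]))
  invisible(x)
}
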