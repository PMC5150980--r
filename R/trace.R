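#' Chemiluminescence trace
#'
#' A uniformly sampled photomultiplier time series plus acquisition metadata.
#' This is the unit every processing stage consumes or produces.
#'
#' @param times time stamps in seconds; must be strictly increasing and
#'   uniform (to within 1e-9 s) and consistent with `sampling_rate_hz`.
#' @param luminescence photomultiplier counts; must be finite.
#' @param flow_rate_ml_min carrier flow rate (ml min^-1).
#' @param matrix matrix label (e.g. "AFRW+DTPA", "PBASW+DTPA", "seawater").
#' @param temperature_c temperature (degrees C).
#' @param sampling_rate_hz acquisition rate (Hz).
#' @param notes free-text notes.
#' @return object of class `chemilum_trace`: list with `times`,
#'   `luminescence`, `metadata`.
#' @export
chemilum_trace <- function(times, luminescence,
                           flow_rate_ml_min = NA_real_,
                           matrix = "seawater",
                           temperature_c = NA_real_,
                           sampling_rate_hz,
                           notes = "") {
  times <- as.numeric(times)
  luminescence <- as.numeric(luminescence)
  if (length(times) != length(luminescence))
    stop("times and luminescence must have equal length")
  if (length(times) < 2) stop("a trace needs at least 2 points")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (diff(range(dt)) > 1e-9)
    stop("times must form a uniform grid (within 1e-9 s)")
  if (!all(is.finite(luminescence)))
    stop("luminescence values must be finite")
  if (abs(dt[1] - 1 / sampling_rate_hz) > 1e-6)
    stop("sampling_rate_hz is inconsistent with the time grid")
  structure(list(
    times = times,
    luminescence = luminescence,
    metadata = list(flow_rate_ml_min = flow_rate_ml_min,
                    matrix = matrix,
                    temperature_c = temperature_c,
                    sampling_rate_hz = sampling_rate_hz,
                    notes = notes)
  ), class = "chemilum_trace")
}

#' @export
print.chemilum_trace <- function(x, ...) {
  cat(sprintf("<chemilum_trace> %d points, %.1f-%.1f s @ %g Hz, matrix '%s'\n",
              length(x$times), min(x$times), max(x$times),
              x$metadata$sampling_rate_hz, x$metadata$matrix))
  cat(sprintf("  counts: median %.1f, range %.1f-%.1f\n",
              stats::median(x$luminescence),
              min(x$luminescence), max(x$luminescence)))
  invisible(x)
}

#' @export
as.data.frame.chemilum_trace <- function(x, ...) {
  data.frame(time_s = x$times, luminescence_counts = x$luminescence)
}

segment_labels <- function() {
  c("reagent_blank", "background_sw_surface", "background_sw_depth",
    "coral_surface", "sod_check", "standard_decay")
}

#' Write a trace to CSV
#'
#' The dialect is `#key=value` header lines (at minimum `flow_rate_ml_min`,
#' `matrix`, `temperature_c`, `sampling_rate_hz`) followed by a
#' `time_s,luminescence_counts` table. The round trip through [read_trace()]
#' is lossless for times, counts and metadata.
#'
#' @param trace a [chemilum_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "chemilum_trace"))
  md <- trace$metadata
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(md)) {
    val <- md[[key]]
    if (is.numeric(val)) val <- format(val, digits = 17)
    writeLines(sprintf("#%s=%s", key, val), con)
  }
  writeLines("time_s,luminescence_counts", con)
  writeLines(sprintf("%s,%s",
                     format(trace$times, digits = 17, trim = TRUE),
                     format(trace$luminescence, digits = 17, trim = TRUE)),
             con)
  invisible(path)
}

#' Read a trace from CSV
#'
#' @param path file in the dialect written by [write_trace()].
#' @return a [chemilum_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0 || any(diff(hdr) != 1) || hdr[1] != 1)
    stop("malformed trace file: expected a leading '#key=value' header block")
  md <- list()
  for (i in hdr) {
    kv <- sub("^#", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 1) stop(sprintf("malformed header at line %d: '%s'", i, lines[i]))
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    num <- suppressWarnings(as.numeric(val))
    md[[key]] <- if (!is.na(num)) num else val
  }
  required <- c("flow_rate_ml_min", "matrix", "temperature_c",
                "sampling_rate_hz")
  missing <- setdiff(required, names(md))
  if (length(missing) > 0)
    stop("trace header missing required field(s): ",
         paste(missing, collapse = ", "))
  body <- utils::read.csv(textConnection(lines[-hdr]))
  if (!all(c("time_s", "luminescence_counts") %in% names(body)))
    stop("trace body must have columns time_s,luminescence_counts")
  if (!is.numeric(body$luminescence_counts) || anyNA(body$luminescence_counts)) {
    bad <- which(is.na(suppressWarnings(
      as.numeric(as.character(body$luminescence_counts)))))[1]
    stop(sprintf("non-numeric counts at data line %d", bad))
  }
  if (any(diff(body$time_s) <= 0)) {
    bad <- which(diff(body$time_s) <= 0)[1] + 1
    stop(sprintf("non-monotone times at data line %d", bad))
  }
  tr <- chemilum_trace(body$time_s, body$luminescence_counts,
                       flow_rate_ml_min = md$flow_rate_ml_min,
                       matrix = md$matrix,
                       temperature_c = md$temperature_c,
                       sampling_rate_hz = md$sampling_rate_hz,
                       notes = if (is.null(md$notes)) "" else md$notes)
  extra <- setdiff(names(md), c(required, "notes"))
  for (key in extra) tr$metadata[[key]] <- md[[key]]
  tr
}

#' Write / read segment annotations
#'
#' Annotations are a sidecar CSV `label,start_s,end_s` marking the phases of
#' a session (reagent blank, seawater backgrounds, coral surface, SOD check,
#' standard decay).
#'
#' @param annotations data.frame with columns `label`, `start_s`, `end_s`.
#' @param path file path.
#' @return `path` (write) or the annotation data.frame (read).
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("label", "start_s", "end_s") %in% names(annotations)))
  utils::write.csv(annotations[, c("label", "start_s", "end_s")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(ann)))
  bad <- setdiff(ann$label, segment_labels())
  if (length(bad) > 0)
    stop("unknown segment label(s): ", paste(bad, collapse = ", "))
  if (any(ann$start_s >= ann$end_s)) stop("annotation start must precede end")
  ann
}
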