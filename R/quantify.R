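#' Convert a corrected signal to a superoxide concentration
#'
#' Division by the calibration slope, with the curve intercept applied only
#' under the `raw_minus_reagent_blank` scheme: the `coral_minus_sw`
#' difference cancels any common intercept, so none is subtracted there.
#' Negative concentrations are passed through (a coral surface can sit below
#' its seawater background).
#'
#' @param corrected a [correct_signal()] result.
#' @param curve a [calibration_curve][build_calibration]; refused when
#'   failure-flagged unless `override = TRUE`.
#' @param override use a failure-flagged curve anyway.
#' @return concentration in nM.
#' @export
signal_to_concentration <- function(corrected, curve, override = FALSE) {
  stopifnot(inherits(corrected, "corrected_signal"),
            inherits(curve, "calibration_curve"))
  if (isTRUE(curve$failed) && !override)
    stop("calibration curve is failure-flagged (r below floor); ",
         "pass override = TRUE to use it anyway")
  if (curve$slope <= 0) stop("calibration slope must be positive")
  adj <- if (corrected$scheme == "raw_minus_reagent_blank")
    curve$intercept else 0
  (corrected$value - adj) / curve$slope
}

#' Superoxide measurement
#'
#' A blank-corrected steady-state concentration with the temporal standard
#' deviation of the plateau signal (converted to nM by the calibration
#' slope) and sample metadata.
#'
#' @param concentration_nM steady-state concentration (nM; may be negative
#'   after blank correction).
#' @param temporal_sd_nM standard deviation of the temporal signal (nM).
#' @param scheme blank scheme used (`coral_minus_sw` or
#'   `raw_minus_reagent_blank`).
#' @param curve_id identifier of the calibration curve used.
#' @param species,site,health,par_umol optional sample metadata.
#' @return object of class `superoxide_measurement`.
#' @export
superoxide_measurement <- function(concentration_nM, temporal_sd_nM,
                                   scheme = "coral_minus_sw",
                                   curve_id = "curve-1",
                                   species = NA_character_,
                                   site = NA_character_,
                                   health = NA_character_,
                                   par_umol = NA_real_) {
  if (temporal_sd_nM < 0) stop("temporal_sd_nM must be >= 0")
  structure(list(concentration_nM = concentration_nM,
                 temporal_sd_nM = temporal_sd_nM,
                 scheme = scheme, curve_id = curve_id,
                 species = species, site = site, health = health,
                 par_umol = par_umol),
            class = "superoxide_measurement")
}

#' @export
print.superoxide_measurement <- function(x, ...) {
  cat(sprintf("<superoxide_measurement> %.2f +/- %.2f nM [%s, curve %s]\n",
              x$concentration_nM, x$temporal_sd_nM, x$scheme, x$curve_id))
  invisible(x)
}

#' Quantify an annotated segment pair into a measurement
#'
#' Convenience composition of [correct_signal()] and
#' [signal_to_concentration()]: the temporal sd of the target plateau is
#' divided by the calibration slope (calibration-fit uncertainty is not
#' folded in; only the temporal scatter is reported).
#'
#' @param target,reference [segment_stats()] for the target plateau and the
#'   blank reference.
#' @param scheme blank scheme, see [correct_signal()].
#' @param curve a calibration curve.
#' @param curve_id identifier recorded on the measurement.
#' @param ... metadata passed to [superoxide_measurement()].
#' @return a [superoxide_measurement()].
#' @export
quantify_segment <- function(target, reference, scheme, curve,
                             curve_id = "curve-1", ...) {
  corrected <- correct_signal(target, reference, scheme)
  conc <- signal_to_concentration(corrected, curve)
  superoxide_measurement(concentration_nM = conc,
                         temporal_sd_nM = corrected$temporal_sd /
                           abs(curve$slope),
                         scheme = scheme, curve_id = curve_id, ...)
}

#' Seawater-normalize a coral measurement
#'
#' Subtracts the background-seawater concentration (measured 5-15 cm from
#' the surface) from the coral-surface concentration; temporal standard
#' deviations combine in quadrature. Both measurements must come from the
#' same calibration curve.
#'
#' @param coral,background [superoxide_measurement()] objects sharing a
#'   `curve_id`.
#' @return a [superoxide_measurement()] holding the difference.
#' @export
seawater_normalize <- function(coral, background) {
  stopifnot(inherits(coral, "superoxide_measurement"),
            inherits(background, "superoxide_measurement"))
  if (!identical(coral$curve_id, background$curve_id))
    stop("measurements were quantified with different calibration curves (",
         coral$curve_id, " vs ", background$curve_id, ")")
  superoxide_measurement(
    concentration_nM = coral$concentration_nM - background$concentration_nM,
    temporal_sd_nM = sqrt(coral$temporal_sd_nM^2 +
                            background$temporal_sd_nM^2),
    scheme = "coral_minus_sw",
    curve_id = coral$curve_id,
    species = coral$species, site = coral$site, health = coral$health,
    par_umol = coral$par_umol)
}

#' Net superoxide production rate
#'
#' The product of the steady-state concentration and the carrier flow rate:
#' at steady state the analyte stream carries away exactly what the
#' organisms on the filter produce, so
#' `rate = Css[nM] * 1e-9 mol/L * flow[ml/min] * 1e-3 L/ml * 60 min/h`.
#'
#' @param css_nM steady-state superoxide concentration (nM).
#' @param flow_rate_ml_min carrier flow rate (ml min^-1), > 0; 2 ml min^-1
#'   in the standard filter-loading configuration.
#' @return total net production rate in mol h^-1.
#' @export
net_production_rate <- function(css_nM, flow_rate_ml_min) {
  if (flow_rate_ml_min <= 0) stop("flow_rate_ml_min must be > 0")
  css_nM * 1e-9 * flow_rate_ml_min * 1e-3 * 60
}

#' Per-organism production rate
#'
#' @param rate_total_mol_h total rate (mol h^-1) from
#'   [net_production_rate()].
#' @param n_organisms number of cells or larvae loaded on the filter, >= 1.
#' @return rate per organism in mol organism^-1 h^-1.
#' @export
per_organism_rate <- function(rate_total_mol_h, n_organisms) {
  if (n_organisms < 1) stop("n_organisms must be >= 1")
  rate_total_mol_h / n_organisms
}

#' Full production-rate record
#'
#' Combines [net_production_rate()] and [per_organism_rate()] and chooses a
#' reporting unit by magnitude: amol per organism per hour for cell-scale
#' rates (< 1 fmol), fmol for larva-scale rates.
#'
#' @param css_nM steady-state concentration (nM).
#' @param flow_rate_ml_min flow rate (ml min^-1).
#' @param n_organisms cells or larvae on the filter.
#' @return object of class `production_rate` with fields
#'   `steady_state_nM`, `flow_rate_ml_min`, `n_organisms`,
#'   `rate_total_mol_h`, `rate_per_organism_mol_h`, `reported_value`,
#'   `reported_unit`.
#' @export
production_rate <- function(css_nM, flow_rate_ml_min, n_organisms) {
  total <- net_production_rate(css_nM, flow_rate_ml_min)
  per_org <- per_organism_rate(total, n_organisms)
  if (abs(per_org) < 1e-15) {
    value <- per_org * 1e18; unit <- "amol/organism/h"
  } else {
    value <- per_org * 1e15; unit <- "fmol/organism/h"
  }
  structure(list(steady_state_nM = css_nM,
                 flow_rate_ml_min = flow_rate_ml_min,
                 n_organisms = n_organisms,
                 rate_total_mol_h = total,
                 rate_per_organism_mol_h = per_org,
                 reported_value = value,
                 reported_unit = unit),
            class = "production_rate")
}

#' @export
print.production_rate <- function(x, ...) {
  cat(sprintf("<production_rate> Css %.2f nM x %g ml/min -> %.3g mol/h total\n",
              x$steady_state_nM, x$flow_rate_ml_min, x$rate_total_mol_h))
  cat(sprintf("  %.3g %s over %g organisms\n",
              x$reported_value, x$reported_unit, x$n_organisms))
  invisible(x)
}
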