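#' Measure the band-area response of a raw spectrum
#'
#' The standard processing chain for one spectrum: resample onto a uniform
#' grid, take the smoothed first derivative, integrate the band area over
#' the analysis window.
#'
#' @param s An [ftir_spectrum()] (transmittance or absorbance channel).
#' @param w A [band_window()].
#' @param dcfg A [derivative_config()].
#' @param step Resampling step in cm^-1.
#' @param mode Area mode, see [band_area()].
#' @return The band-area response (a single number).
#' @export
measure_response <- function(s, w = band_window(),
                             dcfg = derivative_config(), step = 1,
                             mode = "absolute") {
  s <- resample_uniform(s, step)
  d <- first_derivative(s, dcfg)
  band_area(d, w, mode = mode)
}

#' Fit a calibration from spectra and their design concentrations
#'
#' Runs [measure_response()] on each spectrum and fits the calibration line
#' of response on concentration.
#'
#' @param spectra List of [ftir_spectrum()]s, or the output of
#'   [generate_calibration_series()] (in which case `concentrations` is
#'   taken from it).
#' @param concentrations Design concentrations in %w/w, one per spectrum.
#' @inheritParams measure_response
#' @return A `calibration_model`.
#' @export
calibrate_spectra <- function(spectra, concentrations = NULL,
                              w = band_window(),
                              dcfg = derivative_config(), step = 1,
                              mode = "absolute") {
  if (length(spectra) && is.list(spectra[[1L]]) &&
      !inherits(spectra[[1L]], "ftir_spectrum") &&
      all(c("concentration", "spectrum") %in% names(spectra[[1L]]))) {
    concentrations <- vapply(spectra, `[[`, numeric(1), "concentration")
    spectra <- lapply(spectra, `[[`, "spectrum")
  }
  if (is.null(concentrations) || length(concentrations) != length(spectra))
    stop("need one concentration per spectrum", call. = FALSE)
  resp <- vapply(spectra, measure_response, numeric(1), w = w, dcfg = dcfg,
                 step = step, mode = mode)
  fit_calibration(calibration_points(concentrations, resp))
}

#' Assay a sample spectrum against a calibration
#'
#' Measures the sample's band-area response and inverts the calibration
#' line to a concentration.
#'
#' @param s Sample [ftir_spectrum()].
#' @param model A `calibration_model`.
#' @inheritParams measure_response
#' @return Predicted concentration in %w/w.
#' @export
assay_concentration <- function(s, model, w = band_window(),
                                dcfg = derivative_config(), step = 1,
                                mode = "absolute") {
  predict_concentration(model, measure_response(s, w, dcfg, step, mode))
}

#' Robustness of the assay to deliberate parameter perturbation
#'
#' Re-runs the assay of one sample spectrum under a set of perturbed
#' processing parameters (derivative window/order and band-window bounds)
#' and summarises the spread of the predicted concentrations as %RSD. Small
#' %RSD means the result does not hinge on the exact processing settings.
#'
#' @param s Sample [ftir_spectrum()].
#' @param model A `calibration_model` (fitted under the nominal settings).
#' @param perturbations List of settings; each element a list with optional
#'   `w` ([band_window()]) and `dcfg` ([derivative_config()]) overriding the
#'   nominal values. The nominal setting itself is always included.
#' @param w,dcfg,step,mode Nominal processing settings.
#' @return A `precision_summary` (level `"intra_day"`) over the predicted
#'   concentrations, with the per-perturbation values in `$values`.
#' @export
robustness_harness <- function(s, model, perturbations,
                               w = band_window(),
                               dcfg = derivative_config(), step = 1,
                               mode = "absolute") {
  runs <- c(list(list(w = w, dcfg = dcfg)), perturbations)
  vals <- vapply(runs, function(p) {
    assay_concentration(s, model,
                        w = if (!is.null(p$w)) p$w else w,
                        dcfg = if (!is.null(p$dcfg)) p$dcfg else dcfg,
                        step = step, mode = mode)
  }, numeric(1))
  out <- precision_summary(vals, level = "intra_day")
  out$values <- vals
  out
}
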