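#' Savitzky-Golay derivative configuration
#'
#' Parameters of the smoothed-derivative transform. The defaults (window of
#' 9 points, quadratic polynomial, first derivative, differentiate the
#' absorbance channel) are the package's standard settings for a 1 cm^-1
#' grid; instrument software rarely documents its own choice, so these are
#' exposed rather than hard-coded.
#'
#' `channel_policy = "use_absorbance"` converts a percent-transmittance
#' spectrum to absorbance before differentiation (absorbance is the channel
#' that is additive in concentration, which is what makes a band-area
#' calibration linear); `"use_raw"` differentiates whatever channel the
#' spectrum carries, mimicking instrument-side processing of raw traces.
#'
#' @param window_points Odd integer >= 5, filter window length in points.
#' @param poly_order Integer in `[2, window_points - 1]`.
#' @param order Derivative order; 1 is the validated mode.
#' @param channel_policy `"use_absorbance"` or `"use_raw"`.
#' @return A `derivative_config` list.
#' @export
derivative_config <- function(window_points = 9L, poly_order = 2L,
                              order = 1L,
                              channel_policy = c("use_absorbance",
                                                 "use_raw")) {
  channel_policy <- match.arg(channel_policy)
  window_points <- as.integer(window_points)
  poly_order <- as.integer(poly_order)
  order <- as.integer(order)
  if (window_points < 5L || window_points %% 2L == 0L)
    stop("window_points must be an odd integer >= 5", call. = FALSE)
  if (poly_order < 2L || poly_order >= window_points)
    stop("poly_order must lie in [2, window_points - 1]", call. = FALSE)
  if (order < 1L || order > poly_order)
    stop("order must lie in [1, poly_order]", call. = FALSE)
  structure(list(window_points = window_points, poly_order = poly_order,
                 order = order, channel_policy = channel_policy),
            class = "derivative_config")
}

#' Smoothed first derivative of a spectrum
#'
#' Applies a Savitzky-Golay derivative filter (polynomial least-squares
#' convolution) to a spectrum on a uniform wavenumber grid. The output has
#' the same length as the input; boundary points are handled by the filter's
#' one-sided polynomial fits, so an analysis window placed well inside the
#' axis never sees edge effects. Differentiation removes any constant
#' baseline by construction and turns each absorption band into a
#' positive/negative lobe pair with a zero-crossing at the band centre.
#'
#' @param s An [ftir_spectrum()] on a uniform grid (use [resample_uniform()]
#'   first otherwise).
#' @param cfg A [derivative_config()].
#' @return An `ftir_spectrum` with `channel = "derivative"`, units AU per
#'   cm^-1 for order 1.
#' @export
#' @examples
#' s <- ftir_spectrum(seq(700, 2000), 0.01 * seq(700, 2000),
#'                    channel = "absorbance")
#' d <- first_derivative(s, derivative_config(channel_policy = "use_raw"))
#' range(intensities(d))  # ~0.01 everywhere
first_derivative <- function(s, cfg = derivative_config()) {
  stopifnot(inherits(s, "ftir_spectrum"), inherits(cfg, "derivative_config"))
  w <- s$wavenumbers
  if (!is_uniform_axis(w))
    stop("spectrum is not on a uniform grid; call resample_uniform() first",
         call. = FALSE)
  if (cfg$window_points > length(w))
    stop("window_points (", cfg$window_points,
         ") exceeds spectrum length (", length(w), ")", call. = FALSE)
  if (cfg$channel_policy == "use_absorbance") {
    if (s$channel == "transmittance_pct") s <- transmittance_to_absorbance(s)
    else if (s$channel == "derivative")
      stop("cannot apply use_absorbance policy to an already-differentiated ",
           "spectrum", call. = FALSE)
  }
  dy <- signal::sgolayfilt(s$intensities, p = cfg$poly_order,
                           n = cfg$window_points, m = cfg$order,
                           ts = axis_step(w))
  meta <- s$meta
  meta$sg <- sprintf("window=%d poly=%d order=%d", cfg$window_points,
                     cfg$poly_order, cfg$order)
  ftir_spectrum(w, dy, channel = "derivative",
                derivative_order = cfg$order, meta = meta)
}

#' Restrict a spectrum to a wavenumber window
#'
#' Keeps the points with wavenumber in `[lo, hi]`, both endpoints included
#' when they fall on the grid. The extracted sub-spectrum records its parent
#' span in the metadata.
#'
#' @param s An [ftir_spectrum()].
#' @param w A [band_window()]; the default is the CO-stretch window of the
#'   carboxylate salt, 1550-1605 cm^-1.
#' @return An `ftir_spectrum` on the restricted axis.
#' @export
extract_window <- function(s, w = band_window()) {
  stopifnot(inherits(s, "ftir_spectrum"), inherits(w, "band_window"))
  wn <- s$wavenumbers
  if (w$lo < min(wn) - 1e-9 || w$hi > max(wn) + 1e-9)
    stop("window [", w$lo, ", ", w$hi, "] lies outside the axis span [",
         min(wn), ", ", max(wn), "]", call. = FALSE)
  keep <- wn >= w$lo - 1e-9 & wn <= w$hi + 1e-9
  if (sum(keep) < 2L)
    stop("window [", w$lo, ", ", w$hi, "] contains fewer than 2 grid points",
         call. = FALSE)
  meta <- s$meta
  meta$parent_span <- sprintf("%.6g-%.6g", min(wn), max(wn))
  ftir_spectrum(wn[keep], s$intensities[keep], channel = s$channel,
                derivative_order = s$derivative_order, meta = meta)
}
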