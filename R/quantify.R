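#' Wavenumber window for band-area measurement
#'
#' A closed interval `[lo, hi]` in cm^-1. The default, 1550-1605 cm^-1,
#' covers the CO stretch of the carboxylate sodium salt used for
#' quantification of diclofenac sodium.
#'
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return A `band_window` object.
#' @export
band_window <- function(lo = 1550, hi = 1605) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || !is.finite(lo) || !is.finite(hi))
    stop("window bounds must be finite numbers", call. = FALSE)
  if (lo >= hi)
    stop("band window requires lo < hi (got [", lo, ", ", hi, "])",
         call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "band_window")
}

#' @export
print.band_window <- function(x, ...) {
  cat(sprintf("<band_window> [%g, %g] cm^-1\n", x$lo, x$hi))
  invisible(x)
}

#' Band area of a spectral trace over a window
#'
#' Trapezoidal integral over `[lo, hi]`. For a first-derivative trace the
#' signed integral of a complete band is ~0 (the derivative's positive and
#' negative lobes cancel, by the fundamental theorem of calculus), so the
#' default mode integrates `|y|`, which grows linearly with band intensity
#' and is robust to window placement. `"signed"` integrates `y` as-is and
#' `"positive"` integrates `max(y, 0)` (one-lobe area); both are retained
#' for sensitivity analysis.
#'
#' @param s An [ftir_spectrum()]; expected to be a derivative trace. Set
#'   `allow_nonderivative = TRUE` to integrate other channels (a warning is
#'   still emitted).
#' @param w A [band_window()] inside the spectrum's axis span.
#' @param mode `"absolute"` (default), `"signed"` or `"positive"`.
#' @param allow_nonderivative Proceed on non-derivative channels.
#' @return The area (response units: AU for an order-1 derivative trace).
#' @export
#' @examples
#' d <- ftir_spectrum(1550:1605, rep(1, 56), channel = "derivative",
#'                    derivative_order = 1)
#' band_area(d, band_window(1550, 1605), mode = "signed")  # 55
band_area <- function(s, w = band_window(),
                      mode = c("absolute", "signed", "positive"),
                      allow_nonderivative = FALSE) {
  stopifnot(inherits(s, "ftir_spectrum"))
  mode <- match.arg(mode)
  if (s$channel != "derivative") {
    if (!allow_nonderivative)
      stop("spectrum channel is '", s$channel, "', not 'derivative'; pass ",
           "allow_nonderivative = TRUE to integrate it anyway", call. = FALSE)
    warning("integrating a non-derivative channel ('", s$channel, "')",
            call. = FALSE)
  }
  sub <- extract_window(s, w)
  y <- switch(mode,
              absolute = abs(sub$intensities),
              signed = sub$intensities,
              positive = pmax(sub$intensities, 0))
  pracma::trapz(sub$wavenumbers, y)
}

#' Calibration design points
#'
#' @param concentration Analyte concentrations in %w/w, all >= 0.
#' @param response Band-area responses, same length.
#' @return A data frame with columns `concentration` and `response`.
#' @export
calibration_points <- function(concentration, response) {
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) != length(response))
    stop("concentration and response must have equal length", call. = FALSE)
  if (anyNA(concentration) || anyNA(response))
    stop("NA values are not allowed in calibration points", call. = FALSE)
  if (any(concentration < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  data.frame(concentration = concentration, response = response)
}

#' Fit a univariate calibration line
#'
#' Ordinary least squares of response Y on concentration X: `Y = S X + b`.
#' The residual standard deviation `sigma = sqrt(SS_res / (n - 2))` is the
#' regression's S_y/x, the quantity that feeds the detection and
#' quantification limits ([lod()], [loq()]).
#'
#' @param points A data frame from [calibration_points()] (columns
#'   `concentration`, `response`), n >= 3 with at least two distinct
#'   concentrations.
#' @return A `calibration_model` with elements `slope`, `intercept`,
#'   `r_squared`, `residual_sigma`, `intercept_se`, `points`, `n`.
#' @export
#' @examples
#' pts <- calibration_points(c(0.2, 0.4, 0.6, 0.8, 1.0),
#'                           1.375 * c(0.2, 0.4, 0.6, 0.8, 1.0) - 0.014)
#' fit_calibration(pts)
fit_calibration <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("concentration", "response") %in% names(points)))
    stop("points must be a data frame with columns 'concentration' and ",
         "'response' (see calibration_points())", call. = FALSE)
  n <- nrow(points)
  if (n < 3L)
    stop("calibration needs at least 3 points, got ", n, call. = FALSE)
  x <- points$concentration
  y <- points$response
  if (length(unique(x)) < 2L)
    stop("all concentrations are identical; the design is rank-deficient",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  sigma <- sqrt(ss_res / (n - 2))
  sxx <- sum((x - mean(x))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = min(max(r2, 0), 1),
                 residual_sigma = sigma,
                 intercept_se = sigma * sqrt(1 / n + mean(x)^2 / sxx),
                 points = points, n = n),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n")
  cat(sprintf("  Y = %.6g X %+.6g   (n = %d)\n", x$slope, x$intercept, x$n))
  cat(sprintf("  r^2 = %.4f, residual sigma = %.6g\n", x$r_squared,
              x$residual_sigma))
  invisible(x)
}

#' Predict response from concentration
#'
#' Evaluates the calibration line `S X + b`.
#'
#' @param m A `calibration_model` from [fit_calibration()].
#' @param concentration Concentration(s) in %w/w.
#' @return Predicted response(s).
#' @export
predict_response <- function(m, concentration) {
  stopifnot(inherits(m, "calibration_model"))
  m$slope * concentration + m$intercept
}

#' Inverse prediction: concentration from response
#'
#' Solves the calibration line for X: `(Y - b) / S`. Negative results are
#' returned as-is with a below-range warning; they arise for responses below
#' the blank level and should be read against [lod()].
#'
#' @param m A `calibration_model`.
#' @param response Measured response(s).
#' @return Predicted concentration(s) in %w/w.
#' @export
predict_concentration <- function(m, response) {
  stopifnot(inherits(m, "calibration_model"))
  if (m$slope == 0)
    stop("calibration slope is zero; concentration is unidentifiable",
         call. = FALSE)
  out <- (response - m$intercept) / m$slope
  if (any(out < 0))
    warning("predicted concentration below 0 %w/w (response below the ",
            "calibration range)", call. = FALSE)
  out
}
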