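#' Construct an FTIR spectrum object
#'
#' A spectrum is a sampled intensity trace on a wavenumber axis together with
#' an intensity channel tag. The axis is always stored in ascending cm^-1;
#' a descending input axis (the usual instrument export order) is reversed
#' together with its intensities on construction.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotone (ascending or descending), length >= 2.
#' @param intensities Numeric vector of the same length. Unit depends on
#'   `channel`: percent for `"transmittance_pct"`, absorbance units (AU) for
#'   `"absorbance"`, AU per cm^-1 (order 1) for `"derivative"`.
#' @param channel One of `"transmittance_pct"`, `"absorbance"`,
#'   `"derivative"`.
#' @param derivative_order Non-negative integer; must be > 0 exactly when
#'   `channel == "derivative"`.
#' @param meta Named list of character metadata (source file, notes, ...).
#'
#' @return An object of class `ftir_spectrum`.
#' @export
#' @examples
#' s <- ftir_spectrum(seq(700, 2000, 10), rep(100, 131))
#' channel(s)
ftir_spectrum <- function(wavenumbers, intensities,
                          channel = c("transmittance_pct", "absorbance",
                                      "derivative"),
                          derivative_order = 0L, meta = list()) {
  channel <- match.arg(channel)
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(wavenumbers) || anyNA(intensities))
    stop("NA values are not allowed in a spectrum", call. = FALSE)
  d <- diff(wavenumbers)
  if (all(d < 0)) {            # instrument order: high to low wavenumber
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
    d <- -rev(d)
  }
  if (any(d == 0))
    stop("duplicate wavenumbers at ",
         format(wavenumbers[which(d == 0)[1L]]),
         " cm^-1; refusing to average", call. = FALSE)
  if (any(d < 0))
    stop("wavenumber axis is not monotone and cannot be sorted uniquely",
         call. = FALSE)
  derivative_order <- as.integer(derivative_order)
  if (derivative_order < 0L)
    stop("derivative_order must be >= 0", call. = FALSE)
  if ((derivative_order > 0L) != (channel == "derivative"))
    stop("derivative_order > 0 exactly when channel is 'derivative'",
         call. = FALSE)
  if (channel == "transmittance_pct" && any(intensities <= 0))
    stop("transmittance_pct requires all intensities > 0 (first violation at ",
         format(wavenumbers[which(intensities <= 0)[1L]]), " cm^-1)",
         call. = FALSE)
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 channel = channel, derivative_order = derivative_order,
                 meta = meta),
            class = "ftir_spectrum")
}

#' @rdname ftir_spectrum
#' @param s An `ftir_spectrum`.
#' @export
wavenumbers <- function(s) {
  stopifnot(inherits(s, "ftir_spectrum"))
  s$wavenumbers
}

#' @rdname ftir_spectrum
#' @export
intensities <- function(s) {
  stopifnot(inherits(s, "ftir_spectrum"))
  s$intensities
}

#' @rdname ftir_spectrum
#' @export
channel <- function(s) {
  stopifnot(inherits(s, "ftir_spectrum"))
  s$channel
}

#' @rdname ftir_spectrum
#' @export
derivative_order <- function(s) {
  stopifnot(inherits(s, "ftir_spectrum"))
  s$derivative_order
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  w <- x$wavenumbers
  cat(sprintf("<ftir_spectrum> %d points, %.6g-%.6g cm^-1, channel: %s",
              length(w), min(w), max(w), x$channel))
  if (x$channel == "derivative")
    cat(sprintf(" (order %d)", x$derivative_order))
  cat("\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.ftir_spectrum <- function(x) length(x$wavenumbers)

# TRUE when the axis is equispaced to within a relative tolerance.
is_uniform_axis <- function(w, rtol = 1e-6) {
  d <- diff(w)
  step <- mean(d)
  all(abs(d - step) <= rtol * abs(step))
}

# Mean grid step; only meaningful when is_uniform_axis() holds.
axis_step <- function(w) mean(diff(w))

#' Convert percent transmittance to absorbance
#'
#' Applies A = 2 - log10(T%) pointwise (the Beer-Lambert working form for a
#' percent-transmittance trace). Absorbance is the additive channel: band
#' signal is proportional to concentration there, which is what makes a
#' band-area calibration linear.
#'
#' @param s An `ftir_spectrum` with `channel == "transmittance_pct"` and all
#'   intensities > 0.
#' @return An `ftir_spectrum` with `channel == "absorbance"` on the same axis.
#' @export
#' @examples
#' s <- ftir_spectrum(c(1550, 1605), c(100, 10))
#' intensities(transmittance_to_absorbance(s))  # 0, 1
transmittance_to_absorbance <- function(s) {
  stopifnot(inherits(s, "ftir_spectrum"))
  if (s$channel != "transmittance_pct")
    stop("channel must be 'transmittance_pct', got '", s$channel, "'",
         call. = FALSE)
  bad <- which(s$intensities <= 0)
  if (length(bad))
    stop("nonpositive %T at ", format(s$wavenumbers[bad[1L]]),
         " cm^-1; cannot take log", call. = FALSE)
  ftir_spectrum(s$wavenumbers, 2 - log10(s$intensities),
                channel = "absorbance", meta = s$meta)
}

#' Resample a spectrum onto a uniform wavenumber grid
#'
#' Linear interpolation onto an equispaced grid spanning the full axis. Both
#' endpoints are preserved exactly; when the span is not an integer multiple
#' of `step`, the effective step is adjusted to span/round(span/step) so the
#' grid stays equispaced and closes on the last point.
#'
#' Derivative filters require an equispaced grid, so this is the normal entry
#' point before [first_derivative()].
#'
#' @param s An `ftir_spectrum`.
#' @param step Target grid step in cm^-1; must be positive and no larger than
#'   the axis span.
#' @return An `ftir_spectrum` on the uniform grid, same channel.
#' @export
resample_uniform <- function(s, step = 1) {
  stopifnot(inherits(s, "ftir_spectrum"))
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a positive number", call. = FALSE)
  w <- s$wavenumbers
  span <- max(w) - min(w)
  if (step > span)
    stop("step (", format(step), ") exceeds the axis span (", format(span),
         ")", call. = FALSE)
  m <- max(1L, as.integer(round(span / step)))
  grid <- min(w) + (span / m) * (0:m)
  grid[m + 1L] <- max(w)   # guard against rounding drift at the far end
  y <- stats::approx(w, s$intensities, xout = grid, method = "linear")$y
  ftir_spectrum(grid, y, channel = s$channel,
                derivative_order = s$derivative_order, meta = s$meta)
}
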