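#' Parametric absorption band
#'
#' A single absorption band used by the spectrum simulator. `amplitude` is
#' the peak absorbance per %w/w for analyte bands (Beer-Lambert
#' proportionality) or the fixed peak absorbance for excipient bands.
#'
#' @param center Band centre in cm^-1.
#' @param width Half-width parameter in cm^-1 (Gaussian sigma, or Lorentzian
#'   half-width at half-maximum); > 0.
#' @param amplitude Peak absorbance (AU per %w/w for concentration-scaled
#'   bands); >= 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A `synthetic_band`.
#' @export
synthetic_band <- function(center, width, amplitude,
                           shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (!is.numeric(width) || width <= 0)
    stop("band width must be > 0", call. = FALSE)
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("band amplitude must be >= 0", call. = FALSE)
  structure(list(center = center, width = width, amplitude = amplitude,
                 shape = shape),
            class = "synthetic_band")
}

eval_band <- function(b, nu) {
  switch(b$shape,
         gaussian = b$amplitude * exp(-0.5 * ((nu - b$center) / b$width)^2),
         lorentzian = b$amplitude * b$width^2 /
           ((nu - b$center)^2 + b$width^2))
}

sum_bands <- function(bands, nu) {
  out <- numeric(length(nu))
  for (b in bands) out <- out + eval_band(b, nu)
  out
}

#' Simulator configuration: analyte bands, matrix, grid, noise
#'
#' @param api_bands List of [synthetic_band()]s whose absorbance scales with
#'   analyte concentration.
#' @param excipient_bands List of [synthetic_band()]s with fixed
#'   (concentration-independent) absorbance, modelling the tablet matrix.
#' @param baseline_slope Linear baseline drift, AU per cm^-1.
#' @param baseline_offset Constant baseline, AU.
#' @param noise_sd Additive i.i.d. Gaussian noise on absorbance, AU; >= 0.
#' @param grid `list(lo, hi, step)` in cm^-1, the instrument range.
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A `matrix_config`.
#' @export
matrix_config <- function(api_bands, excipient_bands = list(),
                          baseline_slope = 0, baseline_offset = 0,
                          noise_sd = 0,
                          grid = list(lo = 700, hi = 2000, step = 1),
                          seed = 42L) {
  if (!length(api_bands) ||
      !all(vapply(api_bands, inherits, logical(1), "synthetic_band")))
    stop("api_bands must be a non-empty list of synthetic_band objects",
         call. = FALSE)
  if (length(excipient_bands) &&
      !all(vapply(excipient_bands, inherits, logical(1), "synthetic_band")))
    stop("excipient_bands must be synthetic_band objects", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (grid$lo >= grid$hi || grid$step <= 0)
    stop("grid needs lo < hi and step > 0", call. = FALSE)
  rng <- c(grid$lo, grid$hi)
  centers <- vapply(api_bands, `[[`, numeric(1), "center")
  if (any(centers < rng[1L] | centers > rng[2L]))
    stop("analyte band centre outside the instrument range", call. = FALSE)
  structure(list(api_bands = api_bands, excipient_bands = excipient_bands,
                 baseline_slope = baseline_slope,
                 baseline_offset = baseline_offset, noise_sd = noise_sd,
                 grid = grid, seed = as.integer(seed)),
            class = "matrix_config")
}

#' Default diclofenac-sodium simulation profile
#'
#' Emulates an ATR-FTIR spectrum of diclofenac sodium dispersed in KBr over
#' the instrument range 700-2000 cm^-1: one dominant carboxylate CO-stretch
#' band centred mid-window at 1577 cm^-1 (Gaussian, width 12 cm^-1) plus
#' minor analyte bands outside the 1550-1605 window, and excipient bands
#' (polysaccharide C-O region and below) that also lie outside the window.
#' The dominant band's amplitude (0.7564 AU per %w/w) is set so that the
#' default pipeline — 1 cm^-1 grid, 9-point quadratic Savitzky-Golay first
#' derivative, absolute band area over 1550-1605 — has a sensitivity of
#' 1.375 response units per %w/w, the published calibration slope this
#' profile emulates.
#'
#' @param noise_sd Additive absorbance noise SD, AU; default 0.002.
#' @param seed Integer seed.
#' @return A `matrix_config`.
#' @export
default_ds_profile <- function(noise_sd = 0.002, seed = 42L) {
  matrix_config(
    api_bands = list(
      synthetic_band(1577, 12, 0.7564, "gaussian"),   # carboxylate CO stretch
      synthetic_band(1453, 10, 0.30, "gaussian"),     # ring / CH modes
      synthetic_band(1305, 9, 0.22, "gaussian"),
      synthetic_band(766, 8, 0.35, "lorentzian")),    # C-Cl / aromatic
    excipient_bands = list(
      synthetic_band(1022, 18, 0.15, "gaussian"),     # polysaccharide C-O
      synthetic_band(1120, 14, 0.10, "gaussian"),
      synthetic_band(1680, 10, 0.06, "gaussian"),
      synthetic_band(860, 10, 0.05, "gaussian")),
    baseline_slope = 5e-6, baseline_offset = 0.01,
    noise_sd = noise_sd,
    grid = list(lo = 700, hi = 2000, step = 1),
    seed = seed)
}

sim_grid <- function(cfg) seq(cfg$grid$lo, cfg$grid$hi, by = cfg$grid$step)

#' Ground truth attached to a simulated spectrum
#'
#' The simulator attaches a sidecar record (concentration and the noiseless
#' analyte absorbance band area inside the default window) to every spectrum
#' it generates; the record is never written into spectrum files, so it
#' cannot leak into the pipeline under test.
#'
#' @param s A simulated [ftir_spectrum()].
#' @return A list with `concentration` and `api_window_area`, or `NULL`.
#' @export
ground_truth <- function(s) attr(s, "ground_truth")

#' Simulate an absorbance spectrum of an analyte/KBr dispersion
#'
#' Absorbance is built as concentration x (analyte bands) + excipient bands
#' + linear baseline + i.i.d. Gaussian noise. The same (config,
#' concentration, seed) triple always yields a bit-identical spectrum; the
#' global RNG state is left untouched.
#'
#' @param cfg A [matrix_config()].
#' @param concentration Analyte concentration in %w/w, >= 0.
#' @param seed Seed for the noise draw; defaults to `cfg$seed`.
#' @param include_excipients Include the matrix bands (FALSE simulates the
#'   pure analyte/KBr calibration standards).
#' @return An `ftir_spectrum` (absorbance channel) with a [ground_truth()]
#'   attribute.
#' @export
simulate_spectrum <- function(cfg, concentration, seed = cfg$seed,
                              include_excipients = FALSE) {
  stopifnot(inherits(cfg, "matrix_config"))
  if (!is.numeric(concentration) || concentration < 0)
    stop("concentration must be >= 0", call. = FALSE)
  nu <- sim_grid(cfg)
  a <- concentration * sum_bands(cfg$api_bands, nu) +
    cfg$baseline_offset + cfg$baseline_slope * (nu - cfg$grid$lo)
  if (include_excipients && length(cfg$excipient_bands))
    a <- a + sum_bands(cfg$excipient_bands, nu)
  if (cfg$noise_sd > 0)
    a <- a + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(nu), 0, cfg$noise_sd))
  s <- ftir_spectrum(nu, a, channel = "absorbance",
                     meta = list(source = "simulated",
                                 concentration = format(concentration)))
  api_only <- concentration * sum_bands(cfg$api_bands, nu)
  win <- nu >= 1550 & nu <= 1605
  attr(s, "ground_truth") <- list(
    concentration = concentration,
    api_window_area = pracma::trapz(nu[win], api_only[win]))
  s
}

#' Simulate a calibration series
#'
#' One pure-analyte spectrum per concentration level; each level draws its
#' noise from a seed derived deterministically from `cfg$seed`, so series
#' are reproducible and levels are independent. The default levels are the
#' five standards 0.2-1.0 %w/w.
#'
#' @param cfg A [matrix_config()].
#' @param concentrations Non-empty vector of levels in %w/w.
#' @return A list with one element per level, each
#'   `list(concentration, spectrum)`.
#' @export
generate_calibration_series <- function(cfg,
                                        concentrations = c(0.2, 0.4, 0.6,
                                                           0.8, 1.0)) {
  stopifnot(inherits(cfg, "matrix_config"))
  if (!length(concentrations) || any(concentrations < 0))
    stop("concentrations must be a non-empty vector of values >= 0",
         call. = FALSE)
  lapply(seq_along(concentrations), function(i) {
    seed_i <- (cfg$seed + 7919L * i) %% 2147483647L
    list(concentration = concentrations[i],
         spectrum = simulate_spectrum(cfg, concentrations[i], seed = seed_i,
                                      include_excipients = FALSE))
  })
}

#' Simulate a formulated tablet spectrum
#'
#' Analyte plus the excipient matrix; an optional interferent band —
#' concentration-scaled like the analyte — can be injected inside the
#' analysis window as a negative control for selectivity checks. The
#' default concentration, 0.5 %w/w, is the tablet assay level.
#'
#' @param cfg A [matrix_config()].
#' @param concentration Analyte concentration in %w/w.
#' @param interferent Optional [synthetic_band()] added with
#'   concentration-proportional amplitude.
#' @param seed Seed for the noise draw; defaults to `cfg$seed`.
#' @return An `ftir_spectrum` (absorbance channel) with [ground_truth()].
#' @export
simulate_tablet_spectrum <- function(cfg, concentration = 0.5,
                                     interferent = NULL, seed = cfg$seed) {
  if (!is.null(interferent)) {
    stopifnot(inherits(interferent, "synthetic_band"))
    cfg$api_bands <- c(cfg$api_bands, list(interferent))
  }
  simulate_spectrum(cfg, concentration, seed = seed,
                    include_excipients = TRUE)
}

#' Noiseless pipeline sensitivity of a simulator profile
#'
#' The ground-truth response coefficient: the band area the quantification
#' pipeline assigns per unit concentration, computed on a noiseless,
#' matrix-free spectrum. Used to check fitted calibration slopes against the
#' simulator's construction.
#'
#' @param cfg A [matrix_config()].
#' @param w A [band_window()].
#' @param dcfg A [derivative_config()].
#' @param mode Area mode, as in [band_area()].
#' @return Response units per %w/w.
#' @export
true_response_slope <- function(cfg, w = band_window(),
                                dcfg = derivative_config(),
                                mode = "absolute") {
  cfg$noise_sd <- 0
  cfg$baseline_slope <- 0
  cfg$baseline_offset <- 0
  s <- simulate_spectrum(cfg, 1, include_excipients = FALSE)
  d <- first_derivative(s, dcfg)
  band_area(d, w, mode = mode)
}
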