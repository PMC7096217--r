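# Fixtures are built in code; nothing is stored on disk.

# Gaussian absorbance band on the instrument grid.
gauss_spec <- function(center = 1577, sigma = 10, amp = 0.5,
                       lo = 700, hi = 2000, step = 1,
                       channel = "absorbance") {
  w <- seq(lo, hi, by = step)
  ftir_spectrum(w, amp * exp(-0.5 * ((w - center) / sigma)^2),
                channel = channel)
}

ramp_spec <- function(slope = 0.01, lo = 700, hi = 2000, step = 1) {
  w <- seq(lo, hi, by = step)
  ftir_spectrum(w, slope * w, channel = "absorbance")
}

# Calibration points lying exactly on the reference line Y = 1.375 X - 0.014.
reference_line_points <- function(x = c(0.2, 0.4, 0.6, 0.8, 1.0)) {
  calibration_points(x, 1.375 * x - 0.014)
}

raw_dcfg <- function(...) derivative_config(channel_policy = "use_raw", ...)
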