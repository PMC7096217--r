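#' Truncate a value to a fixed number of decimals
#'
#' Reporting convention used throughout the validation tables: values are
#' truncated (chopped), not rounded — 98.8258 reports as 98.82 and 98.2490
#' as 98.24. A guard of 1e-9 absorbs floating-point representation noise so
#' that a value that is exactly on a boundary mathematically is not chopped
#' a whole decimal down. Full-precision values are kept internally; this is
#' a presentation transform only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimals to keep.
#' @param mode `"truncate"` (default), `"round"`, or `"full"` (no-op).
#' @return Numeric vector on the reporting precision.
#' @export
#' @examples
#' report_value(98.8258, 2)   # 98.82
#' report_value(0.1598697, 6) # 0.159869
report_value <- function(x, digits = 2, mode = c("truncate", "round",
                                                 "full")) {
  mode <- match.arg(mode)
  if (mode == "full") return(x)
  f <- 10^digits
  if (mode == "round") round(x, digits)
  else sign(x) * floor(abs(x) * f + 1e-9) / f
}

model_sigma <- function(m, sigma, sigma_definition) {
  switch(sigma_definition,
         residual = m$residual_sigma,
         intercept_se = m$intercept_se,
         manual = {
           if (is.null(sigma))
             stop("sigma_definition = 'manual' requires a sigma value",
                  call. = FALSE)
           sigma
         })
}

#' Limit of detection
#'
#' `LOD = 3.3 sigma / S`, the ICH Q2 calibration-based estimate, with S the
#' calibration slope. By default sigma is the residual standard deviation of
#' the calibration regression (S_y/x) — the only standard-deviation estimate
#' computable from the calibration itself; the standard error of the
#' intercept or an externally measured blank SD can be selected instead.
#'
#' @param m A `calibration_model` with positive slope.
#' @param sigma_definition `"residual"` (default), `"intercept_se"`, or
#'   `"manual"`.
#' @param sigma Standard deviation used when `sigma_definition = "manual"`
#'   (e.g. SD of blank responses).
#' @return LOD in %w/w.
#' @export
#' @examples
#' m <- structure(list(slope = 1.375, residual_sigma = 0.0219821),
#'                class = "calibration_model")
#' lod(m)  # ~0.0528
lod <- function(m, sigma_definition = c("residual", "intercept_se",
                                        "manual"), sigma = NULL) {
  stopifnot(inherits(m, "calibration_model"))
  sigma_definition <- match.arg(sigma_definition)
  if (!is.numeric(m$slope) || m$slope <= 0)
    stop("LOD requires a positive calibration slope", call. = FALSE)
  s <- model_sigma(m, sigma, sigma_definition)
  if (s < 0) stop("sigma must be >= 0", call. = FALSE)
  3.3 * s / m$slope
}

#' Limit of quantification
#'
#' `LOQ = 10 sigma / S`; with one sigma and one slope this is exactly
#' `(10 / 3.3) * LOD`.
#'
#' @inheritParams lod
#' @return LOQ in %w/w.
#' @export
loq <- function(m, sigma_definition = c("residual", "intercept_se",
                                        "manual"), sigma = NULL) {
  stopifnot(inherits(m, "calibration_model"))
  sigma_definition <- match.arg(sigma_definition)
  if (!is.numeric(m$slope) || m$slope <= 0)
    stop("LOQ requires a positive calibration slope", call. = FALSE)
  s <- model_sigma(m, sigma, sigma_definition)
  if (s < 0) stop("sigma must be >= 0", call. = FALSE)
  10 * s / m$slope
}

#' Percent recovery of a claimed analyte content
#'
#' Accuracy metric: measured amount as a percentage of the claimed (nominal)
#' amount. The record keeps the full-precision percentage; the reported view
#' truncates to 2 decimals (see [report_value()]).
#'
#' @param claimed Claimed content in %w/w, > 0.
#' @param measured Measured (recovered) content in %w/w.
#' @return A `recovery_record` with fields `claimed`, `measured`,
#'   `recovery_pct` (full precision) and `reported_pct` (truncated).
#' @export
#' @examples
#' recovery(0.511, 0.505)$reported_pct  # 98.82
recovery <- function(claimed, measured) {
  if (!is.numeric(claimed) || length(claimed) != 1L || claimed <= 0)
    stop("claimed content must be a single value > 0", call. = FALSE)
  if (!is.numeric(measured) || length(measured) != 1L)
    stop("measured content must be a single number", call. = FALSE)
  pct <- measured / claimed * 100
  structure(list(claimed = claimed, measured = measured,
                 recovery_pct = pct,
                 reported_pct = report_value(pct, 2)),
            class = "recovery_record")
}

#' Mean percent recovery of a replicate group
#'
#' Arithmetic mean of the recovery percentages, reported to 2 decimals under
#' the truncation convention.
#'
#' @param records A list of `recovery_record`s, or a numeric vector of
#'   recovery percentages.
#' @return The mean recovery, truncated to 2 decimals.
#' @export
#' @examples
#' mean_recovery(c(98.24, 99.41, 100.58))  # 99.41
mean_recovery <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- vapply(records, function(r) {
      if (!inherits(r, "recovery_record"))
        stop("records must be recovery_record objects or numeric",
             call. = FALSE)
      r$recovery_pct
    }, numeric(1))
  if (!is.numeric(records) || length(records) < 1L)
    stop("need at least one recovery value", call. = FALSE)
  report_value(mean(records), 2)
}

#' Precision summary (repeatability / intermediate precision)
#'
#' Mean, sample standard deviation (n - 1 denominator) and relative standard
#' deviation of repeated readings. `level` tags the design: `"intra_day"`
#' for same-day repeatability, `"inter_day"` for readings spread over
#' consecutive days (intermediate precision).
#'
#' @param values Numeric vector of repeated readings, length >= 2.
#' @param level `"intra_day"` or `"inter_day"`.
#' @return A `precision_summary` with `n`, `mean`, `sd`, `rsd_pct`, `level`.
#'   `rsd_pct` is `NA` (flagged undefined) when the mean is 0.
#' @export
#' @examples
#' precision_summary(c(1, 2, 3))$rsd_pct  # 50
precision_summary <- function(values, level = c("intra_day", "inter_day")) {
  level <- match.arg(level)
  if (!is.numeric(values) || length(values) < 2L)
    stop("precision needs at least 2 readings", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  structure(list(n = length(values), mean = m, sd = s,
                 rsd_pct = if (m != 0) s / m * 100 else NA_real_,
                 level = level),
            class = "precision_summary")
}

#' Selectivity of the analysis window
#'
#' Compares the derivative spectrum of a formulated sample against that of
#' the pure analyte: the api-only trace is scaled by the concentration ratio
#' and subtracted, and the residual absolute band area inside the window is
#' expressed as a fraction of the pure-analyte band area. Values much
#' smaller than 1 indicate that nothing but the analyte contributes inside
#' the window; the conventional flag threshold is 0.2.
#'
#' @param api_only First-derivative spectrum of the pure analyte.
#' @param formulated First-derivative spectrum of the formulated sample, on
#'   the identical grid.
#' @param w A [band_window()].
#' @param api_concentration,formulated_concentration Concentrations in %w/w
#'   behind the two spectra; their ratio scales `api_only` before
#'   subtraction. Both default to 1 (same concentration).
#' @return A `selectivity_result` with `score` (unitless ratio) and
#'   `selective` (logical, `score <= 0.2`).
#' @export
selectivity_score <- function(api_only, formulated, w = band_window(),
                              api_concentration = 1,
                              formulated_concentration = api_concentration) {
  stopifnot(inherits(api_only, "ftir_spectrum"),
            inherits(formulated, "ftir_spectrum"))
  if (api_only$channel != "derivative" || formulated$channel != "derivative")
    stop("selectivity_score needs first-derivative spectra", call. = FALSE)
  if (length(api_only) != length(formulated) ||
      max(abs(api_only$wavenumbers - formulated$wavenumbers)) > 1e-9)
    stop("spectra are on different grids; resample onto a common grid first",
         call. = FALSE)
  scale <- formulated_concentration / api_concentration
  diff_s <- ftir_spectrum(api_only$wavenumbers,
                          formulated$intensities -
                            scale * api_only$intensities,
                          channel = "derivative",
                          derivative_order = api_only$derivative_order)
  denom <- band_area(api_only, w, mode = "absolute")
  if (denom <= 0)
    stop("pure-analyte band area in the window is zero; cannot normalise",
         call. = FALSE)
  score <- band_area(diff_s, w, mode = "absolute") / denom
  structure(list(score = score, selective = score <= 0.2,
                 window = w),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity> score = %.4g over [%g, %g] cm^-1: %s\n",
              x$score, x$window$lo, x$window$hi,
              if (x$selective) "selective" else "NOT selective"))
  invisible(x)
}

#' Assemble a method-validation report
#'
#' Bundles the calibration model with its detection limits, grouped recovery
#' records, precision summaries and selectivity diagnostics into one
#' printable report. The LOQ/LOD ratio invariant (10 / 3.3, both limits from
#' the same sigma and slope) is asserted at build time.
#'
#' @param model A `calibration_model`.
#' @param recoveries Named list of groups; each group a list of
#'   `recovery_record`s (one group per sample/brand). Optional.
#' @param precision List of `precision_summary` objects. Optional.
#' @param selectivity A `selectivity_result`. Optional.
#' @param rounding Reporting mode passed to [report_value()]:
#'   `"truncate"` (default), `"round"` or `"full"`.
#' @param sigma_definition Passed to [lod()]/[loq()].
#' @param sigma Manual sigma when `sigma_definition = "manual"`.
#' @return A `validation_report`.
#' @export
build_report <- function(model, recoveries = NULL, precision = NULL,
                         selectivity = NULL,
                         rounding = c("truncate", "round", "full"),
                         sigma_definition = "residual", sigma = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  rounding <- match.arg(rounding)
  lod_v <- lod(model, sigma_definition, sigma)
  loq_v <- loq(model, sigma_definition, sigma)
  if (lod_v > 0 && abs(loq_v / lod_v - 10 / 3.3) > 1e-9)
    stop("internal error: LOQ/LOD ratio deviates from 10/3.3", call. = FALSE)
  if (!is.null(recoveries)) {
    ok <- vapply(recoveries, function(g)
      all(vapply(g, inherits, logical(1), "recovery_record")), logical(1))
    if (!all(ok))
      stop("recoveries must be a list of groups of recovery_record objects",
           call. = FALSE)
  }
  mean_rec <- if (!is.null(recoveries))
    vapply(recoveries, mean_recovery, numeric(1)) else NULL
  structure(list(model = model, lod = lod_v, loq = loq_v,
                 recoveries = recoveries, mean_recovery_pct = mean_rec,
                 precision = precision, selectivity = selectivity,
                 rounding = rounding),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  rep2 <- function(v) format(report_value(v, 2, mode = x$rounding),
                             nsmall = if (x$rounding == "full") 0 else 2)
  cat("== Method validation report ==\n")
  cat(sprintf("Regression: Y = %.6g X %+.6g   r^2 = %.4f   (n = %d)\n",
              x$model$slope, x$model$intercept, x$model$r_squared,
              x$model$n))
  cat(sprintf("LOD = %.6f %%w/w   LOQ = %.6f %%w/w\n",
              report_value(x$lod, 6, mode = x$rounding),
              report_value(x$loq, 6, mode = x$rounding)))
  if (!is.null(x$recoveries)) {
    cat("\nAccuracy (% recovery):\n")
    cat("sample\tclaimed\tmeasured\trecovery\n")
    for (g in names(x$recoveries)) {
      for (r in x$recoveries[[g]])
        cat(sprintf("%s\t%.3f\t%.3f\t%s\n", g, r$claimed, r$measured,
                    rep2(r$recovery_pct)))
      cat(sprintf("%s\taverage\t\t%s\n", g, rep2(x$mean_recovery_pct[[g]])))
    }
  }
  if (!is.null(x$precision)) {
    cat("\nPrecision:\n")
    cat("level\tn\tmean\tsd\t%RSD\n")
    for (p in x$precision)
      cat(sprintf("%s\t%d\t%.6g\t%.6g\t%s\n", p$level, p$n, p$mean, p$sd,
                  if (is.na(p$rsd_pct)) "undefined" else rep2(p$rsd_pct)))
  }
  if (!is.null(x$selectivity)) {
    cat("\nSelectivity: ")
    print(x$selectivity)
  }
  invisible(x)
}
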