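reference_model <- function(sigma = 0.0219821, slope = 1.375) {
  m <- fit_calibration(reference_line_points())
  m$slope <- slope
  m$residual_sigma <- sigma
  m
}

test_that("detection and quantification limits follow 3.3 and 10 sigma/S", {
  m <- reference_model()
  expect_equal(report_value(lod(m), 6), 0.052757)
  expect_equal(report_value(loq(m), 6), 0.159869)   # truncation, not rounding
  expect_equal(lod(reference_model(sigma = 0)), 0)
  expect_equal(lod(reference_model(sigma = 1.375 / 3.3)), 1)
  expect_equal(loq(reference_model(sigma = 0)), 0)
  # ratio identity for arbitrary valid models
  withr::with_seed(2, {
    for (rep in 1:10) {
      mm <- reference_model(sigma = runif(1, 1e-4, 0.1),
                        slope = runif(1, 0.1, 5))
      expect_equal(loq(mm) / lod(mm), 10 / 3.3, tolerance = 1e-12)
    }
  })
  bad <- reference_model(slope = -1)
  expect_error(lod(bad), "positive")
  # alternative sigma definitions
  expect_equal(lod(m, "manual", sigma = 0.01), 3.3 * 0.01 / 1.375)
  expect_error(lod(m, "manual"), "sigma")
})

test_that("percent recovery reproduces the assay-table arithmetic", {
  expect_equal(recovery(0.5, 0.499)$reported_pct, 99.80)
  expect_equal(recovery(0.511, 0.517)$reported_pct, 101.17)
  for (c in c(0.1, 0.5, 2))
    expect_equal(recovery(c, c)$reported_pct, 100.00)
  expect_error(recovery(0, 0.5), "> 0")
  # scale invariance
  withr::with_seed(4, {
    for (rep in 1:10) {
      a <- runif(1, 0.1, 1); b <- runif(1, 0.1, 1); k <- runif(1, 0.1, 10)
      expect_equal(recovery(k * a, k * b)$recovery_pct,
                   recovery(a, b)$recovery_pct, tolerance = 1e-12)
    }
  })
})

test_that("mean recovery averages replicate groups and ignores order", {
  expect_equal(mean_recovery(c(98.24, 99.41, 100.58)), 99.41)
  expect_equal(mean_recovery(c(98.82, 99.41, 101.17)), 99.80)
  expect_equal(mean_recovery(96.5), 96.5)
  recs <- list(recovery(0.511, 0.505), recovery(0.511, 0.508),
               recovery(0.511, 0.517))
  expect_equal(mean_recovery(recs), mean_recovery(rev(recs)))
  expect_error(mean_recovery(numeric(0)), "at least one")
})

test_that("precision summaries use the sample standard deviation", {
  p0 <- precision_summary(c(5, 5, 5))
  expect_equal(c(p0$sd, p0$rsd_pct), c(0, 0))
  p1 <- precision_summary(c(1, 2, 3))
  expect_equal(c(p1$mean, p1$sd, p1$rsd_pct), c(2, 1, 50))
  p2 <- precision_summary(c(2, 4), level = "inter_day")
  expect_equal(p2$sd, sqrt(2))
  expect_equal(p2$rsd_pct, 100 * sqrt(2) / 3, tolerance = 1e-9)
  expect_identical(p2$level, "inter_day")
  expect_error(precision_summary(5), "at least 2")
  expect_true(is.na(precision_summary(c(-1, 1))$rsd_pct))
  # %RSD is unit-free
  withr::with_seed(6, {
    for (rep in 1:10) {
      v <- runif(5, 1, 10); k <- runif(1, 0.01, 100)
      expect_equal(precision_summary(k * v)$rsd_pct,
                   precision_summary(v)$rsd_pct, tolerance = 1e-9)
    }
  })
})

derive_pair <- function(cfg, conc = 0.5, interferent = NULL) {
  api <- first_derivative(simulate_spectrum(cfg, conc), derivative_config())
  tab <- first_derivative(
    simulate_tablet_spectrum(cfg, conc, interferent = interferent),
    derivative_config())
  list(api = api, tab = tab)
}

test_that("selectivity separates excipient-free windows from injected interferents", {
  cfg <- default_ds_profile(noise_sd = 0)
  p <- derive_pair(cfg)
  expect_equal(selectivity_score(p$api, p$api)$score, 0)
  clean <- selectivity_score(p$api, p$tab)
  expect_lt(clean$score, 0.02)       # excipient leakage into the window
  expect_true(clean$selective)
  intf <- synthetic_band(1577, 12, 0.3 * 0.7564, "gaussian")
  p2 <- derive_pair(cfg, interferent = intf)
  hit <- selectivity_score(p2$api, p2$tab)
  expect_gt(hit$score, 0.2)
  expect_false(hit$selective)
  # mismatched grids refuse to compare
  short <- extract_window(p$api, band_window(1500, 1700))
  expect_error(selectivity_score(short, p$tab), "grid")
  expect_error(selectivity_score(simulate_spectrum(cfg, 0.5), p$tab),
               "derivative")
})

test_that("validation reports assemble, assert the LOQ/LOD ratio and render", {
  m <- reference_model()
  recov <- list(
    A = list(recovery(0.511, 0.505), recovery(0.511, 0.508),
             recovery(0.511, 0.517)),
    C = list(recovery(0.514, 0.505), recovery(0.514, 0.511),
             recovery(0.511, 0.514)))
  prec <- list(precision_summary(c(0.49, 0.50, 0.51)),
               precision_summary(c(0.48, 0.51), level = "inter_day"))
  rep <- build_report(m, recoveries = recov, precision = prec)
  expect_s3_class(rep, "validation_report")
  expect_equal(report_value(rep$lod, 6), 0.052757)
  expect_equal(report_value(rep$loq, 6), 0.159869)
  expect_equal(rep$loq / rep$lod, 10 / 3.3, tolerance = 1e-12)
  expect_equal(unname(rep$mean_recovery_pct["C"]), 99.41)
  txt <- capture.output(print(rep))
  expect_true(any(grepl("98.82", txt)))
  expect_true(any(grepl("99.41", txt)))
  expect_true(any(grepl("RSD", txt)))
  # optional sections are omitted when absent
  txt0 <- capture.output(print(build_report(m)))
  expect_false(any(grepl("Accuracy", txt0)))
  expect_false(any(grepl("Precision", txt0)))
})

test_that("reported values truncate rather than round", {
  expect_equal(report_value(98.8258, 2), 98.82)
  expect_equal(report_value(98.2490, 2), 98.24)
  expect_equal(report_value(99.999, 2), 99.99)
  expect_equal(report_value(99.999, 2, mode = "round"), 100)
  expect_identical(report_value(99.999, 2, mode = "full"), 99.999)
  expect_equal(report_value(-1.239, 2), -1.23)   # chop toward zero
})

test_that("robustness harness reports small spread under small perturbations", {
  cfg <- default_ds_profile(noise_sd = 0.001, seed = 33L)
  m <- calibrate_spectra(generate_calibration_series(cfg))
  tab <- simulate_tablet_spectrum(cfg, 0.5, seed = 77L)
  pert <- list(list(w = band_window(1548, 1607)),
               list(w = band_window(1552, 1603)),
               list(dcfg = derivative_config(window_points = 7)),
               list(dcfg = derivative_config(window_points = 11)))
  rb <- robustness_harness(tab, m, pert)
  expect_length(rb$values, 5L)
  expect_lt(rb$rsd_pct, 5)
  expect_equal(mean(rb$values), 0.5, tolerance = 0.05)
})
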