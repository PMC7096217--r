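test_that("spectrum construction enforces axis and channel invariants", {
  s <- ftir_spectrum(c(1550, 1605), c(0.10, 0.20), channel = "absorbance")
  expect_length(s, 2L)
  expect_equal(wavenumbers(s), c(1550, 1605))

  # descending instrument order is reversed in lockstep
  s2 <- ftir_spectrum(c(1605, 1550), c(0.20, 0.10), channel = "absorbance")
  expect_equal(intensities(s2), c(0.10, 0.20))

  expect_error(ftir_spectrum(c(1550, 1550, 1600), c(1, 2, 3)),
               "duplicate wavenumbers")
  expect_error(ftir_spectrum(c(1550, 1600, 1570), c(1, 2, 3)),
               "not monotone")
  expect_error(ftir_spectrum(1550, 1), "at least 2")
  expect_error(ftir_spectrum(c(1550, 1600), c(100, 0)), "> 0")
  expect_error(ftir_spectrum(c(1550, 1600), c(1, 2), channel = "absorbance",
                             derivative_order = 1), "derivative_order")
})

test_that("minimal two-point CSV reads as specified", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1550,0.10", "1605,0.20"), tf)
  s <- read_spectrum(tf, format = "csv", channel = "absorbance")
  expect_length(s, 2L)
  expect_equal(wavenumbers(s), c(1550, 1605))
  expect_equal(intensities(s), c(0.10, 0.20))
})

test_that("read-write round trip is the identity for both formats and all channels", {
  w <- seq(700, 2000, by = 2)          # 651 points
  withr::with_seed(11, {
    traces <- list(
      transmittance_pct = 100 - 40 * exp(-0.5 * ((w - 1577) / 12)^2),
      absorbance = 0.01 + 0.5 * exp(-0.5 * ((w - 1300) / 20)^2),
      derivative = sin(w / 50) / 30 + rnorm(length(w), 0, 1e-3))
    for (chan in names(traces)) {
      s <- ftir_spectrum(w, traces[[chan]], channel = chan,
                         derivative_order = if (chan == "derivative") 1L
                         else 0L)
      for (fmt in c("jcamp", "csv")) {
        tf <- withr::local_tempfile(
          fileext = if (fmt == "jcamp") ".jdx" else ".csv")
        write_spectrum(s, tf, format = fmt)
        s2 <- read_spectrum(tf)
        expect_length(s2, 651L)
        expect_lt(max(abs(wavenumbers(s2) - w)), 1e-9)
        expect_lt(max(abs(intensities(s2) - intensities(s))), 1e-9)
        expect_identical(channel(s2), chan)   # channel metadata restored
        expect_identical(derivative_order(s2), derivative_order(s))
      }
    }
  })
})

test_that("descending JCAMP axis is reversed against a hand-reversed copy", {
  w_desc <- seq(2000, 700, by = -10)
  withr::with_seed(7, y_desc <- round(runif(length(w_desc), 10, 90), 4))
  tf <- withr::local_tempfile(fileext = ".jdx")
  body <- vapply(split(seq_along(w_desc), ceiling(seq_along(w_desc) / 6)),
                 function(i) paste(c(w_desc[i[1]], y_desc[i]),
                                   collapse = " "), character(1))
  writeLines(c("##TITLE= descending", "##JCAMP-DX= 4.24",
               "##XUNITS= 1/CM", "##YUNITS= TRANSMITTANCE",
               "##XFACTOR= 1", "##YFACTOR= 1",
               "##FIRSTX= 2000", "##LASTX= 700",
               paste0("##NPOINTS= ", length(w_desc)),
               "##XYDATA= (X++(Y..Y))", body, "##END="), tf)
  s <- read_spectrum(tf)
  expect_equal(wavenumbers(s), rev(w_desc))
  expect_equal(intensities(s), rev(y_desc))   # hand-reversed oracle
  expect_identical(channel(s), "transmittance_pct")
})

test_that("JCAMP SQZ-encoded ordinates decode to their AFFN values", {
  # same table twice: AFFN and SQZ (@=0, A..I=1..9, a..i=-1..-9)
  hdr <- c("##TITLE= sqz", "##XUNITS= 1/CM", "##YUNITS= ABSORBANCE",
           "##XFACTOR= 1", "##YFACTOR= 0.001", "##FIRSTX= 1000",
           "##LASTX= 1005", "##NPOINTS= 6", "##XYDATA= (X++(Y..Y))")
  affn <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(hdr, "1000 120 135 -17 0 233 911", "##END="), affn)
  sqz <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(hdr, "1000A20A35a7@B33I11", "##END="), sqz)
  s1 <- read_spectrum(affn)
  s2 <- read_spectrum(sqz)
  expect_equal(intensities(s2), intensities(s1))
  expect_equal(intensities(s1)[1:3], c(0.120, 0.135, -0.017))  # YFACTOR
})

test_that("unparseable and compound JCAMP files fail with located messages", {
  tf <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE= bad", "##XUNITS= 1/CM", "##FIRSTX= 1", "##LASTX= 2",
               "##NPOINTS= 4", "##XYDATA= (X++(Y..Y))",
               "1 10 zz 30", "##END="), tf)
  expect_error(read_spectrum(tf), "line 7")
  tf2 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE= outer", "##BLOCKS= 2", "##TITLE= inner", "##END="),
             tf2)
  expect_error(read_spectrum(tf2), "multi-block")
})

test_that("CSV dialect flag switches to semicolon/comma-decimal", {
  s <- gauss_spec(step = 50)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, tf, format = "csv", csv_dialect = "comma")
  expect_true(any(grepl(";", readLines(tf), fixed = TRUE)))
  s2 <- read_spectrum(tf, format = "csv", csv_dialect = "comma")
  expect_lt(max(abs(intensities(s2) - intensities(s))), 1e-9)
  # bad rows are reported with their line number
  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,intensity", "700,1", "710;2"), tf3)
  expect_error(read_spectrum(tf3, format = "csv"), "line 3")
})

test_that("transmittance to absorbance follows A = 2 - log10(T%)", {
  w <- c(1550, 1577, 1605)
  expect_equal(intensities(transmittance_to_absorbance(
    ftir_spectrum(w, c(100, 100, 100)))), c(0, 0, 0))
  expect_equal(intensities(transmittance_to_absorbance(
    ftir_spectrum(w, c(10, 10, 10)))), c(1, 1, 1))
  expect_equal(intensities(transmittance_to_absorbance(
    ftir_spectrum(w, c(1, 1, 1)))), c(2, 2, 2))
  expect_error(transmittance_to_absorbance(
    ftir_spectrum(w, c(1, 2, 3), channel = "absorbance")), "channel")
})

test_that("absorbance is pointwise strictly decreasing in %T", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      w <- seq(700, 900, by = 10)
      t1 <- runif(length(w), 1, 99)
      t2 <- t1 + runif(length(w), 0.01, 1)   # strictly larger %T
      a1 <- intensities(transmittance_to_absorbance(ftir_spectrum(w, t1)))
      a2 <- intensities(transmittance_to_absorbance(ftir_spectrum(w, t2)))
      expect_true(all(a2 < a1))
    }
  })
})

test_that("uniform resampling preserves lines exactly and bands to tolerance", {
  # identity on an already-uniform grid at the same step
  s <- gauss_spec(step = 1)
  expect_equal(intensities(resample_uniform(s, 1)), intensities(s))
  # any polynomial of degree <= 1 reproduced exactly
  r <- ramp_spec()
  for (step in c(0.5, 2, 7)) {
    rs <- resample_uniform(r, step)
    expect_lt(max(abs(intensities(rs) - 0.01 * wavenumbers(rs))), 1e-9)
    expect_equal(range(wavenumbers(rs)), c(700, 2000))  # endpoints kept
  }
  # Gaussian band (width 20) at step 0.5 against the analytic oracle
  g <- gauss_spec(sigma = 20, amp = 1)
  gs <- resample_uniform(g, 0.5)
  oracle <- exp(-0.5 * ((wavenumbers(gs) - 1577) / 20)^2)
  expect_lt(max(abs(intensities(gs) - oracle)), 1e-3)
  expect_error(resample_uniform(g, 5000), "span")
  expect_error(resample_uniform(g, -1), "positive")
})
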