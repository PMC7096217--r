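Package: ftirquant
Title: Quantitative First-Derivative ATR-FTIR Band-Area Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Univariate quantification of an active pharmaceutical ingredient
    from ATR-FTIR spectra by first-derivative band-area measurement. Reads and
    writes JCAMP-DX and CSV spectra, converts percent transmittance to
    absorbance, resamples onto uniform wavenumber grids, computes smoothed
    Savitzky-Golay first derivatives, integrates band areas over a wavenumber
    window, fits ordinary least-squares calibration lines and inverts them to
    predict concentration. Includes an ICH Q2-style method-validation layer
    (limits of detection and quantification, accuracy as percent recovery,
    precision summaries, selectivity diagnostics) and a synthetic-spectrum
    simulator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
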