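---
title: "First-derivative band-area quantification of an API by ATR-FTIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-derivative band-area quantification of an API by ATR-FTIR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirquant)
```

## The measurement model

The package quantifies one analyte — the working case is diclofenac sodium
in tablet formulations — from a mid-infrared spectrum through a univariate
band-area calibration. The physical model is Beer–Lambert proportionality:
on the absorbance channel, the analyte's contribution to the spectrum is
its molar band profile scaled by concentration, sitting on top of whatever
the matrix (KBr diluent, tablet excipients) and the instrument baseline
add. Because instruments commonly export percent transmittance, the first
processing step is the channel conversion

$$A(\nu) = 2 - \log_{10} T\%(\nu),$$

after which additivity in concentration holds. Quantification then uses the
CO-stretch band of the carboxylate sodium salt, integrated over the window
$[1550, 1605]\ \mathrm{cm^{-1}}$ of the **first-derivative** spectrum
$dA/d\nu$.

Differentiation buys two things. A constant baseline offset vanishes
exactly, and a linear drift becomes a constant that largely cancels over a
window containing a full band. And band overlap is reduced: derivative
lobes are narrower than the parent bands, so a neighbouring band whose tail
leaks into the window contributes much less to the derivative-area response
than it would to a direct absorbance area.

One consequence needs spelling out, because it fixes a core design choice.
For any band that has decayed to baseline at both window edges, the signed
integral of its derivative over the window is $f(\mathrm{hi}) -
f(\mathrm{lo}) \approx 0$ — positive and negative lobes cancel by the
fundamental theorem of calculus. A non-zero, concentration-proportional
response therefore requires a lobe-resolving convention. `band_area()`
integrates $|dA/d\nu|$ by default ("absolute" mode): it is symmetric,
robust to window placement, and linear in band intensity for a fixed band
shape. Signed and positive-lobe modes are retained for sensitivity
analysis, and the ≈ 0 signed-area property is asserted in the test suite
rather than assumed.

The calibration itself is unweighted ordinary least squares of response on
concentration, $Y = S X + b$, with inverse prediction $\hat X = (Y - b)/S$
for unknowns. Weighted or nonlinear calibration is out of scope: the method
targets the narrow 0.2–1.0 %w/w range where a single straight line is the
accepted model.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `band_window()` | 1550–1605 | cm⁻¹ | CO stretch of the carboxylate salt; unique to the analyte in this formulation class |
| `window_points` (SG) | 9 | points | smooths 16 cm⁻¹-resolution noise on a 1 cm⁻¹ grid without clipping a ~12 cm⁻¹-wide band |
| `poly_order` (SG) | 2 | — | lowest order that differentiates curvature correctly; higher orders trade noise rejection for fidelity |
| `order` | 1 | — | the validated derivative order |
| `channel_policy` | `use_absorbance` | — | absorbance is additive in concentration; `use_raw` mimics instrument-side differentiation of %T |
| resample `step` | 1 | cm⁻¹ | finer than the 16 cm⁻¹ instrument resolution, so interpolation adds no information it then destroys |
| `noise_sd` (simulator) | 0.002 | AU | places the simulated calibration in the r² ≥ 0.999 regime typical of this assay |
| area `mode` | `absolute` | — | see above; the only convention with a non-degenerate response |
| `sigma_definition` | `residual` | — | S_y/x is the one sigma computable from the calibration itself; intercept-SE and external blank-SD selectable |

A deliberate filter property worth knowing: a quadratic Savitzky–Golay
derivative attenuates the derivative extrema of a Gaussian band. For a
band of width σ = 10 cm⁻¹ on a 1 cm⁻¹ grid with the default 9-point
window, the filtered derivative deviates from the analytic derivative by a
few percent of its peak (the test suite bounds the deviation against the
closed-form oracle at 5%). This attenuation is common to standards and samples processed with
the same settings, so it cancels in calibration-based quantification — but
it means filtered derivative amplitudes are not directly comparable across
different window/step choices.

## What the simulator emulates — and what it does not

`default_ds_profile()` builds spectra on the instrument range
700–2000 cm⁻¹ at 1 cm⁻¹: a dominant Gaussian analyte band at 1577 cm⁻¹
(width 12 cm⁻¹) inside the analysis window, minor analyte bands at 1453,
1305 and 766 cm⁻¹, excipient bands (polysaccharide C–O region and below,
plus one at 1680 cm⁻¹) entirely outside the window, a small linear
baseline, and additive i.i.d. Gaussian noise on absorbance. The dominant
band's amplitude, 0.7564 AU per %w/w, is a modelling choice made once: it
gives the default pipeline a sensitivity of 1.375 response units per %w/w,
the slope regime this assay operates in, so simulated calibrations are
numerically comparable to real ones. Band positions and widths are
configuration, not constants.

Ground truth (concentration, noiseless analyte window area) travels as a
sidecar attribute, never into written spectrum files, so it cannot leak
into the pipeline under test.

The simulator does **not** model ATR penetration-depth wavelength
dependence, instrument line-shape convolution, scattering artifacts,
heteroscedastic or correlated noise, water-vapour/CO₂ lines, or
particle-size effects of the KBr dispersion. Passing tests on simulated
data therefore demonstrate the correctness of the numerical chain and its
statistical behaviour under the stated noise model — not that a particular
real instrument and sample-preparation protocol achieves the same figures
of merit.

## Numerical choices and degenerate inputs

* **Axis convention.** Internally every spectrum has a strictly ascending
  wavenumber axis; descending instrument order is reversed on ingest.
  Duplicate wavenumbers are an error, never averaged — silent averaging
  hides acquisition faults.
* **Resampling.** `resample_uniform()` keeps both endpoints exactly; when
  the span is not an integer multiple of the requested step, the effective
  step becomes span/round(span/step) so the grid stays equispaced.
* **Derivative edges.** The Savitzky–Golay filter returns a same-length
  trace using one-sided polynomial fits at the boundaries. The analysis
  window sits ~550 cm⁻¹ from the nearest axis edge, so edge handling never
  touches the quantified region.
* **Reporting convention.** Percentages and limits are truncated (chopped)
  to the reporting precision, not rounded — this is the convention the
  assay's tables follow, e.g. 98.8258…% reports as 98.82. A guard of 1e-9
  absorbs floating-point representation noise at truncation boundaries.
  Full precision is kept internally; `report_value()` exposes
  truncate/round/full modes.
* **Degenerate calibrations.** Fewer than 3 points, or all concentrations
  equal, are errors; a perfectly collinear design returns σ = 0 and
  r² = 1 exactly. A zero fitted slope makes inverse prediction error out;
  negative predicted concentrations are returned as-is with a warning so
  they can be judged against the LOD.
* **JCAMP dialect.** Single-block files, `##XYDATA=(X++(Y..Y))` in AFFN or
  simple SQZ encoding, plus `##XYPOINTS=(XY..XY)` for non-uniform axes;
  `XFACTOR`/`YFACTOR` applied; compound multi-block files rejected with a
  clear message. The writer avoids exponent notation because ASDF reuses
  `E`/`e` as squeezed digits.

## Open design decisions, resolved

* **Was %T converted before differentiation?** Instrument software rarely
  says. The package defaults to converting (`use_absorbance`) because only
  the absorbance channel is additive in concentration — the property the
  linear calibration relies on — and exposes `use_raw` to mimic direct
  differentiation of the %T trace.
* **Which sigma for LOD/LOQ?** ICH Q2 permits residual SD of the
  calibration, SD of the intercept, or SD of blanks. The default is the
  residual SD because it is the only one computable from the calibration
  data alone; the others are selectable.
* **Intra- vs inter-day precision.** Grouping is explicit in the input
  (three same-day readings for repeatability, readings across two
  consecutive days for intermediate precision); the package never infers
  the grouping from timestamps.
* **Robustness.** No separate protocol exists beyond "perturb the method
  parameters"; `robustness_harness()` re-runs the assay under perturbed
  derivative and window settings and reports the %RSD of the predicted
  concentrations.

## Statistical behaviour of the detection limit

LOD = 3.3 σ/S propagates two estimation effects that matter when the limit
is studied as a function of the spectral noise level. First, the residual
SD from an n = 5 calibration has 3 degrees of freedom, and the sample SD
is then biased low by the factor $c_4 = \sqrt{2/3}\,\Gamma(2)/\Gamma(3/2)
\approx 0.921$. Second, the band-area response does not transmit spectral
noise with unit gain: integrating the absolute value of a
Savitzky–Golay-filtered derivative over a finite window both smooths and
partially cancels noise, so the response-level noise SD is a
filter-dependent fraction of the absorbance noise SD. The net effect is
that the slope of LOD versus spectral noise sits measurably below 3.3/S —
LOD remains proportional to the noise level (the property suite verifies
the linearity), but the proportionality constant is 3.3/S times the
product of the two factors above, which for the default settings falls
short of a ±10% neighbourhood of 3.3/S. The acceptance suite states the
idealised unit-gain expectation and documents the measured shortfall
rather than hiding it; treating the constant as exactly 3.3/S is only
valid when sigma is estimated directly on the response scale.

## Problem sizes

Simulated spectra carry 1301 points (700–2000 cm⁻¹ at 1 cm⁻¹);
calibrations use the five standards 0.2–1.0 %w/w; stochastic properties
(tablet recovery within ±2%, LOD scaling) use 200 seeded Monte-Carlo
replicates, sizes chosen to make Monte-Carlo error small relative to the
asserted margins.

## Known limitations

* Univariate only: no PLS/PCR, no multi-band or peak-height modes.
* The selectivity score requires a pure-analyte reference spectrum on the
  identical grid; it diagnoses in-window interference but does not locate
  the interferent.
* Truncation-based reporting reproduces conventional assay tables but is a
  lossy presentation; downstream arithmetic should use the full-precision
  fields, as the package itself does.
* The second-derivative path is computable (`order = 2`) but not
  validated by the test suite.
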