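---
title: "Methods: alpha-opic photometry, metamer design and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha-opic photometry, metamer design and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`melanophot` implements the computational chain of a melanopsin-targeted
evening light study: CIE S 026 alpha-opic photometry, silent-substitution
metamer design for a five-primary display, pupillometry preprocessing,
retinal (troland) dose computation, and dose-response analysis of pupil
size and melatonin suppression against corneal versus retinal melanopic
dose. This vignette documents the models, the numerical choices, and the
places where the design was genuinely open.

## Photometric model

All photometry lives on a canonical 380-780 nm grid at 1 nm, with
rectangular (delta-lambda weighted) summation. This matches the tabulated
summation practice of the CIE standards and of web calculators built on
them; a trapezoidal rule would change fourth-digit results. Spectra on
other grids are linearly interpolated inside their measured support and
set to exactly zero outside it -- a physical source emits nothing where it
was not measured, so edge-hold extrapolation would invent power.

The five alpha-opic irradiances are
`E_alpha = 1000 * sum(E(lambda) * s_alpha(lambda))` (mW m^-2), photopic
illuminance is `683 * sum(E(lambda) * V(lambda))` (lx), and the alpha-opic
equivalent daylight illuminance is `EDI_alpha = E_alpha / K_alpha`, where
`K_alpha` -- the daylight efficacy -- is the alpha-opic irradiance of D65
per lux of D65, a scale-invariant constant of the standard.

### Provenance of the embedded reference curves

The verbatim 1 nm machine-readable CIE tabulations are not shipped.
The package embeds a documented reconstruction (see `R/cie-data.R`):

* `V(lambda)`, D65 and the scotopic `V'(lambda)` are transcribed from the
  classic 5 nm tabulations and linearly interpolated to 1 nm, the
  interpolation rule the standards themselves prescribe. Fidelity check:
  the *derived* rhodopic daylight efficacy, which uses only these
  transcribed tables, lands well within 1% of the published constant
  (1.4497 mW/lm), as pinned by the test suite.
* The 10-degree cone fundamentals are rebuilt from 10 nm anchors by
  spline interpolation and peak-renormalised; their derived daylight
  efficacies agree with the published constants within ~3%.
* The melanopic curve is constructed from its definition: a Govardovskii
  A1 opsin nomogram (quantal, lambda_max 480 nm), filtered by
  ocular-media transmittance and converted to energy units. The media
  density curve has a single free scale factor, calibrated once so that
  the construction reproduces two published properties of the standard
  curve -- an energy-unit peak near 490 nm (achieved: 491 nm) and a D65
  melanopic efficacy of 1.3262 mW/lm (achieved exactly). This calibration
  is to the *standard*, not to any study outcome.

`d65_efficacy()` derives all five `K_alpha` from these tables at run
time; `s026_daylight_efficacy()` exposes the published constants, and the
test suite pins the derived/published agreement. Consequences of the
reconstruction: EDI conversions through the melanopic channel are exact
relative to the standard's constant, while cone-opic EDIs carry the ~3%
reconstruction uncertainty. Because metamer design, simulation and
recovery are all computed *within* one consistent set of curves, those
results are self-consistent regardless.

A note on reproducing printed tables: published alpha-opic tables print
irradiances rounded to two decimals. Converting such a rounded irradiance
to an EDI can therefore land up to one unit off in the EDI's last printed
decimal for *any* efficacy constant -- the rounding windows of different
rows are mutually inconsistent at half-ULP precision. The acceptance
tests check agreement within one unit in the last printed decimal, the
tightest tolerance the rounded inputs support.

## Silent-substitution metamer design

Receptor responses are linear in the drive weights, so a device is
summarised by its receptor matrix (alpha-opic irradiances of each primary
at full drive). For a three-primary subset, matching a cone-opic target
`(sc, mc, lc)` is a direct 3x3 solve; degenerate subsets (condition
number beyond 1e12) and out-of-gamut solutions are hard errors naming the
violating primary. Gamut checks allow 1e-12 slack to absorb rounding.

Melanopsin contrast `(E_mel,HM - E_mel,LM)/E_mel,LM` is invariant to a
common rescaling of both members, so "maximising contrast" is a search
over the *direction* of the cone target, not its magnitude:
every LM-feasible direction is `M_LM %*% w` with `w` on the unit simplex,
and `maximize_melanopsin_contrast()` scans that simplex (coarse grid,
then Nelder-Mead refinement) subject to nonnegative HM drives, then
scales the winning target to the gamut boundary -- or to a requested
illuminance -- reporting the binding primary. The rod channel is
deliberately left unconstrained: silencing rods as well would collapse
the achievable melanopsin contrast, and rhodopic and melanopic
irradiances covary in any realistic light in any case.

Measured primary spectra are rarely distributable, so
`gaussian_device()` provides the standard stand-in: Gaussian primaries at
the emulated display's dominant wavelengths (430/480/500/550/630 nm).
The default FWHM of 30 nm (within the plausible 20-30 nm LED range) was
chosen so that the model device's maximal melanopsin contrast falls in
the 200-300% range the physical display realised; with the published
group-1 cone-opic target the model then also reproduces the published
rhodopic irradiances to within a few percent, which we take as evidence
that the reconstruction is physically reasonable. The solver targets
exact cone matches; small cone-channel mismatches present in published
calibration tables are physical measurement error and are not modelled.

## Pupillometry pipeline

Samples are kept iff confidence >= 0.6 and diameter in [2, 10] mm. The
exclusion criteria are quoted as strict inequalities ("< 0.6", "less
than 2 mm", "greater than 10 mm"), so boundary values are retained; the
same strict reading keeps a part at exactly 2% valid data. Medians are
computed per 20-minute bin (configurable), with the even-count median as
the mean of the two central values. The denominator of `fraction_valid`
is the *nominal* expected sample count (duration x nominal rate), not
the recorded count: the dominant loss mode in practice is storage
dropout, which must count against quality. Only 3D-model diameters are
consumed. Test parts are treated as given labels; whether parts and bins
coincide is left to the caller (one bin per part with the defaults).

## Retinal dose

Conventional retinal illuminance is luminance x pupil area (trolands).
The alpha-opic generalisation multiplies alpha-opic *radiance*
(mW m^-2 sr^-1) by pupil area (mm^2). No absolute unit convention for
"alpha-opic trolands" is standardised; downstream use is exclusively
relative (correlations and regressions on log10 dose), where any fixed
unit factor cancels. Irradiance measurements are converted to radiance
as `L = E / omega` under a uniform-extended-source assumption, with
`screen_solid_angle()` providing `omega` for a flat display
(width x height / distance^2; default a 27-inch 16:9 panel at 60 cm).
Both the direct-radiance and the irradiance+geometry path are supported
because calibration practice varies; the two agree exactly by
construction when the geometry is consistent.

## Dose-response layer

Melatonin AUC is the trapezoidal integral over the light-exposure window
on the half-hourly sampling grid, with linear interpolation at window
endpoints so that AUC is exactly additive over adjacent windows. The
regression layer is ordinary least squares with the Pearson correlation,
written in closed form (no model-fitting framework behaviour in the
acceptance path) and cross-checked against `lm()`/`cor()` in the tests.
Nonpositive doses under the log10 transform are hard errors -- no +epsilon
offsets. The mixed-model/ANOVA machinery that typically accompanies such
studies is intentionally out of scope: it is routine, package-fitted
statistics, not part of this package's contribution.

## The synthetic study

The generator emulates the emulated study's design: 4 intensity groups x
18 subjects x 2 counterbalanced sessions (low/high melanopic), with the
eight published conditions (luminances, alpha-opic irradiances, mEDIs) as
the condition grid.

Pupil model: steady-state diameter is log-logistic in melanopic EDI,
`d = d_min + (d_max - d_min) / (1 + (mEDI/e50)^h)`. Over the study's
3.7-146 lx range this is close to the log-linear decline such studies
report while saturating sensibly outside it. Defaults
(`d_max = 7 mm`, `d_min = 2 mm`, `e50 = 20 lx`, `h = 0.5`) were chosen
once so that the noiseless LM-vs-HM diameter gaps fall inside the
16-23% band the emulated study observed across its intensity groups.
Measurement noise is AR(1) (marginal SD 0.15 mm, autocorrelation 0.95);
between-subject diameter offsets are Gaussian (SD 0.4 mm). Blink events
are Poisson (0.2 Hz, 0.3 s) producing low-confidence samples with
sub-2 mm diameter excursions, flanked by high-confidence out-of-range
samples, plus 2% isolated low-confidence samples -- together exercising
every filter clause. Within-condition pupil variance is not published
for the emulated study; these noise defaults are nominal.

Melatonin model: a logistic baseline rise centred 2 h before habitual
bedtime (the rise shape is plumbing; only the suppression factor matters
for recovery), multiplied from light onset by
`s(dose) = 1 / (1 + (dose/s50)^k)` with multiplicative lognormal noise.
The `suppression_driver` switch selects whether `dose` is the session's
mEDI (corneal) or its ground-truth melanopic trolands (retinal) -- the
mechanism question the predictor comparison probes. With the corneal
driver and dose-driven pupils, corneal and retinal predictors fit the
AUC near-identically (|delta |r|| well under 0.05); with the retinal
driver and strong independent pupil variation (subject SD 1.2 mm), the
troland predictor wins in >= 90% of replicates. These two regimes are the
package's testable restatement of the "similar fits" conclusion.

Problem sizes: `generate_study()` defaults to five 20-minute parts per
session sampled at 10 Hz (the 200 Hz instrument rate is decimatable by
design; single traces default to 200 Hz). That keeps the full 144-session
cohort at ~8.6M pupil samples, generated in under a minute, while the
median of a 12,000-sample bin estimates the steady state to well under
0.05 mm. Replicate-level property checks use an analytic fast path
(`pupil_traces = FALSE`) that draws part medians directly from the
model's sampling distribution, bypassing trace generation but not the
session-level analysis.

Parameter recovery: over a 1.6-decade dose range the four-parameter
log-logistic is poorly identified (asymptotes, `e50` and Hill slope
trade off along a likelihood ridge), so `recover_pupil_model()` accepts
the known physiological diameter range and then recovers the generating
`e50` within +/-25% at 144 sessions, with the dose-response slope sign
always negative. The unconstrained four-parameter fit is also available
and is documented as ridge-prone.

What passing synthetic tests do *not* show: the generator has no
circadian drift of pupil size, no pupil-light-reflex transients, no
cognitive-load or sleepiness effects, no per-observer spectral
sensitivity differences, and stationary noise; real cohort correlations
(which mix all of these) are therefore not reproduced, only the
generating structure is recovered.

## Known limitations

* Reconstructed reference curves: exact-to-the-tabulation alpha-opic
  values (beyond the melanopic channel's calibrated efficacy) carry up
  to ~3% uncertainty; swap in verbatim standard tables for normative use.
* No age-dependent prereceptoral filtering; the standard-observer curves
  are assumed for all observers, so designed metamers may not be
  metameric for every real observer.
* No CIE 1931 colorimetry (chromaticity, CCT, CRI) and no hardware
  (gamma/temporal) calibration -- device weights are treated as exact
  linear drive fractions.
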