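---
title: "Spectral pairing, wavelength shift, and SpO2 error: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral pairing, wavelength shift, and SpO2 error: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxishift)
```

## The problem

Dual-wavelength pulse oximetry estimates arterial oxygen saturation from
the ratio of pulsatile absorbances at a red and a near-infrared channel.
The textbook computation assumes two idealizations: the light sources are
monochromatic, and the photodetector responds uniformly across wavelength.
Neither holds for the LEDs and silicon photodiodes that real
(especially low-cost, wearable) oximeters are built from. An LED emits over
a band of 15-75 nm full width at half maximum, usually skewed, often with
a stray secondary feature; a photodiode's responsivity rises and falls
across the very region where the two channels sit. The product of the two
curves relocates the wavelength each channel *effectively* operates at,
which relocates the hemoglobin extinction coefficients entering the
saturation formula — a bias that is invisible to a designer reading only
center wavelengths off datasheets, and that matters most in the clinically
critical 90-100% saturation window.

`oxishift` quantifies this chain at design time, from a handful of
datasheet parameters.

## Models

### Beer-Lambert oximetry

Absorbance at wavelength $\lambda$ is $A(\lambda) = -\ln(I/I_0)$, and for
the two-chromophore blood model
$A = (\varepsilon_{HbO_2}[HbO_2] + \varepsilon_{Hb}[Hb])\,d$. Over one
cardiac cycle the pulsatile path increment $\Delta d$ is taken equal at
both wavelengths, so the ratio of ratios
$$R = \frac{AC_{\lambda_1}/DC_{\lambda_1}}{AC_{\lambda_2}/DC_{\lambda_2}}$$
reduces, in the small-signal limit, to the ratio of the mixed extinction
coefficients, and saturation follows in closed form:
$$SpO_2 = 100\,\frac{\varepsilon_{Hb}(\lambda_1) -
\varepsilon_{Hb}(\lambda_2)\,R}{\varepsilon_{Hb}(\lambda_1) -
\varepsilon_{HbO_2}(\lambda_1) + \left(\varepsilon_{HbO_2}(\lambda_2) -
\varepsilon_{Hb}(\lambda_2)\right) R}$$
(`spo2_bll()`). Deployed systems rarely evaluate this; they use the linear
approximation $SpO_2 = a R + b$, most commonly $110 - 25R$
(`calibration_line()`, `spo2_linear()`). The package's error profile
(`error_profile()`) is the relative deviation
$\Delta SpO_2 = (BLL - Approx)/BLL \times 100\%$ between the two, with the
Beer-Lambert side evaluated at *effective* — spectrally weighted —
coefficients.

### Spectral models

An LED line or detector lobe is a Gaussian parameterized by peak and FWHM:
$I(\lambda) = e^{-4\ln 2\,((\lambda-\lambda_{peak})/\Delta\lambda)^2}$
(`gaussian_band()`). Measured lines lean left or right; the skewed variant
(`skewed_band()`) is a skew-normal reparameterized by (mode, FWHM, shape)
and renormalized to unit maximum, chosen because no single published
skewed lineshape fits all LEDs — the parameterization is pluggable, and
zero shape reduces *exactly* to the Gaussian. The shape parameter's sign
is the lean: positive puts the centroid (the datasheet's "dominant
wavelength") above the mode.

Sampled curves (`ox_spectrum`) carry measured spectra. The synthetic
generator (`synth_led_spectrum()`) emulates a dark-corrected spectrometer
export: primary band plus stray bands on a 0.6 nm grid, additive seeded
Gaussian noise, clipped at zero, normalized.

### The pairing shift

The product of two Gaussians is a Gaussian, which gives the effective band
of a source-detector channel in closed form (`effective_band_exact()`):
with $w = \Delta\lambda_{LED}^2 / (\Delta\lambda_{LED}^2 +
\Delta\lambda_{PD}^2)$,
$$\lambda_{eff} = \lambda_{LED} + w\,(\lambda_{PD} - \lambda_{LED}),
\qquad
\Delta\lambda_{eff} = \frac{\Delta\lambda_{LED}\Delta\lambda_{PD}}
{\sqrt{\Delta\lambda_{LED}^2 + \Delta\lambda_{PD}^2}}.$$
The shift $\delta\lambda = \lambda_{eff} - \lambda_{LED}$ always points
from the source toward the detector peak. For the usual design regime of a
narrow source on a broad detector, the first-order form
$\delta\lambda \approx (\lambda_{PD} - \lambda_{LED})
(\Delta\lambda_{LED}/\Delta\lambda_{PD})^2$ (`effective_band_approx()`)
is the back-of-envelope screen; it is validated in the test suite against
the exact form (within 15% at a width ratio of 10, converging
quadratically) and obeys the same sign rule. The exact form is the
package's reference throughout; non-Gaussian cases (skewed sources,
measured or ramp-like detector curves) are handled numerically via the
sampled spectral product, and `pair_report()` flags that fallback.

### Effective extinction coefficients

The extinction a channel "sees" is the table averaged under the
emission x responsivity weight:
$$\varepsilon_{eff} = \frac{\sum_i \varepsilon(\lambda_i)\,
I_{LED}(\lambda_i)\,H_{PD}(\lambda_i)}{\sum_i I_{LED}(\lambda_i)\,
H_{PD}(\lambda_i)}.$$
We deliberately use the *normalized* weighted mean rather than a bare
weighted sum: the bare sum is not unit-consistent (its value would depend
on grid resolution and on the arbitrary scaling of relative spectra),
while the normalized form preserves L mol^-1 cm^-1, is invariant under
rescaling of either spectrum, and reduces to the pointwise table value in
the monochromatic-source/flat-detector limit — all three properties are
asserted in the test suite.

## Data and fixtures

**Extinction table.** The bundled `hemoglobin_extinction()` is a
*synthetic* smooth reconstruction: natural cubic splines in log space
through anchor values of the magnitude commonly cited in the oximetry
literature, anchored exactly at the canonical channel values (660 nm:
HbO2 319.6, Hb 3226.56; 940 nm: HbO2 1214, Hb 693.44 L mol^-1 cm^-1),
with the qualitative structure that drives oximetry: Hb dominant in the
red, HbO2 dominant in the NIR, isosbestic point near 805 nm, Hb bump near
760 nm. It spans 400-1100 nm at 1 nm so that wide IR sources keep
essentially all their pairing weight inside the table. It is **not** a
published compilation; shift magnitudes computed from it are
demonstrative, and quantitative work should load a measured or compiled
table via `read_extinction_csv()`.

**Component registry.** `load_registry()` ships a registry of candidate
LEDs spanning ~525-950 nm — single red and IR emitters, dual- and
triple-wavelength parts, and two commercial probes for which only
measured parameters exist — each entry carrying datasheet values
(dominant wavelength, peak wavelength, FWHM, any of which may be absent)
beside bench-measured peak/FWHM. Measured parameters are preferred for
modelling by default (they describe the part actually on the bench);
with `prefer = "datasheet"` the dominant wavelength is taken over the
peak when both are quoted, since the centroid is the better single-center
summary of a skewed line.

**Detectors.** Real photodiode responsivity curves are manufacturer data
and are not redistributed. `synthetic_detector()` provides labelled
synthetic stand-ins for the qualitative families: `flat` (the ideal of
the theory), `gaussian` (broad bell), `midpeak` (symmetric peak at
800 nm, between the channels, so red shifts up and IR shifts down), and
`ramp` (quasi-linear rise toward the NIR, with no long-wavelength
half-maximum crossing — the case that forces the numeric path). User
curves load through `read_spectrum_csv()`.

## The PPG simulator

`synth_ppg()` implements the forward model
$I(t) = I_0 \exp(-\varepsilon_{mix}\,c_{Hb}\,(d + \Delta d\,p(t)))$ with
$\varepsilon_{mix} = \varepsilon_{HbO_2} SaO_2 + \varepsilon_{Hb}
(1 - SaO_2)$ and $p(t)$ a periodic unimodal pulse at the heart rate
(raised cosine by default; an asymmetric fast-upstroke variant is
provided). Defaults are physiological: total hemoglobin 2.3 mmol/L
(~150 g/L), 1 cm static path, 0.01 cm pulsatile amplitude
($\Delta d / d = 10^{-2}$), 60 bpm, 125 Hz sampling, 10 s traces.

`ratio_of_ratios()` implements the peak-and-valley method. The per-cycle
AC/DC definition requires a cycle segmentation the theory leaves open; we
segment minima-to-minima on the IR trace, since the IR channel has the
larger DC (smaller absorbance) and hence the better noise immunity in
practice. The closed loop — simulate at known $SaO_2$, extract $R$,
invert through `spo2_bll()` — recovers the configured saturation to
within 0.5 percentage points across 80-100% under the defaults, which is
the simulator's validation contract in the test suite.

A practical caution encoded in the acceptance script: peak-to-peak AC
estimation is biased upward by additive noise, so intensity noise must be
kept small relative to the *AC amplitude* (itself ~$10^{-3}$ of the
incident intensity at physiological absorbances), not merely small
relative to the DC level.

## Numerical choices

- **Working grid:** 300-1100 nm at 0.2 nm (`default_grid()`), finer than
  the 0.6 nm of a typical fibre spectrometer so resampled instrument
  curves are not degraded. All resampling is linear interpolation with
  **zero outside the support** — spectra are physically negligible far
  from their band, and zero padding avoids extrapolation artifacts in the
  weighting sums.
- **Peak/FWHM extraction** (`peak_fwhm()`): grid argmax with ties broken
  to the lowest wavelength; half-maximum crossings located by walking
  outward from the peak and linearly interpolating between the bracketing
  samples. Stray peaks below half maximum therefore cannot disturb the
  result; curves without a crossing on one side (monotone ramps) raise an
  extraction error rather than fabricating a width.
- **Degenerate inputs:** all-zero spectra cannot be normalized; disjoint
  source-detector supports are a degenerate pairing error; extinction
  lookups refuse to extrapolate outside the table; the Beer-Lambert
  formula rejects ratios at its singularity; pairing weight falling
  outside the table warns when it exceeds 0.1%.
- **Seeding:** every stochastic operation (synthetic spectra, PPG noise)
  takes an explicit seed and restores the caller's RNG state, so seeded
  calls are bitwise reproducible and side-effect free.

## Problem sizes

The test suite validates the closed-form pairing against dense numeric
sampling of the spectral product over 10^4 seeded random parameter draws
(centers 600-950 nm, FWHM 5-120 nm, separation up to the sum of the two
widths, 0.2 nm sampling), and the sign/attraction rules over a further
2000 draws. Error profiles use 400 R points over [0.3, 3], which maps to
roughly 40-110% saturation for physiological coefficient sets. PPG
validation uses 10-12 s traces at 125 Hz. The whole suite runs in well
under a minute.

## Design choices where the design was open

- The first-order shift approximation is validated only against the exact
  Gaussian-product form and the sign rule, never used as the reference;
  where its regime ($\Delta\lambda_{LED} \le \Delta\lambda_{PD}$) is
  violated it warns and defers to the exact form.
- The skewed lineshape is one pluggable parameterization (skew-normal by
  mode/FWHM/shape), not a physical claim; the Gaussian remains the
  default model, consistent with standard practice of summarizing LED
  lines by peak and FWHM.
- The calibration fit (`fit_linear_calibration()`) samples the
  Beer-Lambert curve uniformly over the R range mapping to 70-100%
  saturation by default — a line should represent the region it will be
  used in, and published lines' fitted ranges are generally unstated.
- `spo2_linear()` does not clamp to [0, 100] by default: the textbook
  line exceeding 100% at small R is part of the error being quantified.
  A clamp flag exists for display.
- One property often assumed — that widening a source's FWHM can only
  worsen the *fixed-line* window error — is **not** generally true and is
  deliberately not asserted: against a fixed calibration line, a
  coefficient shift can pull the Beer-Lambert curve toward the line and
  reduce the apparent error, as happens on the bundled table. What grows
  monotonically with FWHM is the deviation of the effective-coefficient
  Beer-Lambert curve from the monochromatic one, and that is the property
  the suite asserts.

## What the synthetic data do and do not show

The generator and fixtures exercise every code path a real
characterization campaign would: skewed lines, stray secondary peaks,
instrument-resolution sampling, noise, non-Gaussian detectors, CSV
round trips. Passing tests demonstrate the *machinery* — closed forms,
weighting, inversion, recovery — to stated tolerances. They do not
certify quantitative shift magnitudes for real parts: those depend on the
true extinction compilation and the true detector curves, both of which
the user must supply. Known further limitations: temperature, drive
current and process dependence of spectra are out of scope, as are
dyshemoglobins (co-oximetry), in-vivo calibration lookup tables, and
motion/respiratory artifacts in the PPG model.
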