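---
title: "Methods: spectral deconvolution for non-invasive blood panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral deconvolution for non-invasive blood panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemospec)
```

## The measurement problem

Hemoglobin (Hb, g/dL), total serum bilirubin (TSB, mg/dL) and peripheral
oxygen saturation (SpO~2~, %) are the three laboratory quantities that
decide whether a neonate is anemic, jaundiced or hypoxic. All three leave a
signature in the visible diffuse-reflectance spectrum of perfused tissue:
bilirubin absorbs around 460 nm, oxyhemoglobin in its two Q bands near 539
and 577 nm, and deoxyhemoglobin near 568 nm. `hemospec` implements the
staged algorithm of a point-of-care device that estimates all three from a
single 450--650 nm nail-bed spectrum, together with a synthetic-spectrum
generator that makes every stage testable without any clinical data.

## From counts to absorbance

An acquisition consists of three count spectra on one wavelength grid: the
tissue measurement \(S\), a dark reading \(D\) (source off) and a
reference reading \(R\) from a reflectance standard. The processed
spectrum is the dark-corrected decadic absorbance
\[
A(\lambda) \;=\; -\log_{10}\frac{S(\lambda) - D(\lambda)}
                                {R(\lambda) - D(\lambda)},
\]
cropped to the 450--650 nm working window. A non-positive \(S - D\) or
\(R - D\) is treated as an acquisition fault and reported with the
offending wavelengths rather than masked: it is precisely the condition
the downstream quality gates exist to catch.

Acquisition software convention applies for smoothing: a boxcar of width
\(w\) is the centered running average over \(2w+1\) points
(`boxcarSmooth()`, device setting \(w = 2\)), with symmetrically truncated
windows at the spectrum ends so no data are fabricated. Whether smoothing
happens in spectrometer firmware or in software is an acquisition-chain
detail; it is therefore a configuration key (`boxcar$width`), and for
noise-free synthetic spectra it is turned off, since a running mean of a
noiseless curve can only distort line shapes.

**Amplitude gate.** The device constrains acquisition geometry (0.7 cm
spot, 0.6 cm probe distance) by requiring the absorbance at 620 nm to lie
in the closed interval \([0.5, 0.6]\). The device documentation writes the
condition with inconsistent inequality directions; the prose "within 0.5
and 0.6" makes the intended reading an inclusive interval, which is what
`checkGate()` implements, interpolating linearly to exactly 620 nm. By
default a gate failure is recorded and the measurement continues; in
strict mode (`gate$strict = TRUE`) it rejects the measurement with
re-acquisition guidance, mirroring the device behaviour.

## Five-Gaussian deconvolution

The absorbance spectrum is modelled as a cumulative sum of five Gaussian
components with *fixed* centers plus a shared offset:
\[
y(\lambda) \;=\; y_0 + \sum_{i=1}^{5}
  A_i \exp\!\Big(-\tfrac12\big((\lambda - x_{c,i})/w_i\big)^2\Big),
\qquad
x_c \in \{462.92,\; 539.34,\; 568.09,\; 577.2,\; 620\}\ \text{nm}.
\]
The 462.92 nm component tracks bilirubin, 539.34 and 577.2 nm the
oxyhemoglobin Q bands, 568.09 nm deoxyhemoglobin; the broad 620 nm
component absorbs baseline and scattering contributions and is excluded
from all downstream indices. Although the width parameter is sometimes
referred to as a full width at half maximum, the functional form above
makes \(w\) a standard deviation; `hemospec` treats it as such and reports
\(\mathrm{FWHM} = 2\sqrt{2\ln 2}\,w\) as a derived column.

`fitFiveGaussians()` minimises the mean squared residual over the 11 free
parameters (five amplitudes, five widths, one offset) by bounded
Levenberg--Marquardt (via `minpack.lm`), with \(A_i \ge 0\) and
\(w_i \in [1, 60]\) nm. Initial guesses are deterministic: \(y_0\) at the
spectrum minimum, \(A_i\) at the baseline-subtracted absorbance at each
center, widths at 10 nm. Because the centers are fixed, local minima are
rare; the residual risk (about 1% of noisy fits in our experiments) shows
up as a width pinned at a bound, so the fitter restarts from 5 nm and
20 nm initial widths when that happens and keeps the lowest-deviance
iterate. The procedure has no random element: identical inputs give
bit-identical fits.

**Residual acceptance.** A fit is accepted when at least a fraction
\(p\) of the per-point residuals lie within \(\pm t\) absorbance
(`residualFraction()`, `acceptFit()`). The defaults are \(t = 0.02\) and
\(p = 0.98\), with \(p \in \{0.90, 0.95\}\) as the device's alternative
training partitions. The tolerance is implemented in absolute absorbance
units: a relative reading ("0.02%") would reject essentially every real
fit of a \(\sim\)0.5-absorbance spectrum, and the calibration-stage
description uses the absolute figure. Acceptance is monotone: lowering
the partition can never reject a previously accepted spectrum.

## Indices, calibration and classification

Areas under the fitted components are computed by the trapezoidal rule on
the measurement grid over the working window (`componentAUC()`), applied
to the analytic component curves rather than the raw data, and combined
into three instrument indices:
\[
I_{\mathrm{Hb}} = \mathrm{AUC}_{539.34} + \mathrm{AUC}_{577.2}, \qquad
I_{\mathrm{TSB}} = \mathrm{AUC}_{462.92}, \qquad
I_{\mathrm{SpO_2}} = \mathrm{AUC}_{577.2} / \mathrm{AUC}_{568.09}.
\]
The device description mentions that "appropriate weightage" is applied to
the areas without quantifying it; the indices are implemented as the
explicit unweighted combinations above.

Each analyte has a fixed calibration family: Hb linear in its index, TSB
quadratic, SpO~2~ quartic (`fitCalibration()`, ordinary least squares with
raw polynomials). Coefficients are fit-time artifacts stored in a JSON
calibration file; no published coefficient set exists beyond the Hb line,
so test suites use the generator's ground-truth models. SpO~2~ is clamped
to \([0, 100]\) % after polynomial evaluation, with the clamp flagged, and
indices outside a model's observed range flag extrapolation.

Classification uses strict "less than" thresholds for anemia
(Hb \< 11 g/dL) and hypoxia (SpO~2~ \< 92 %). Clinically, jaundice is
zoned on an age-in-hours nomogram, which is out of scope here; `hemospec`
applies a single configurable TSB cut (default 15 mg/dL) and labels it as
such.

## The synthetic-data generator

No public spectra exist for this kind of device, so the generator *is* the
study-condition definition, not a convenience. `truthRecord()` starts from
a ground-truth blood panel and inverts fixed calibration models to obtain
target indices:

* Hb: the linear model `hb = 2.91 + 1.8 * index` — the device's own
  published hemoglobin calibration line at the strictest partition;
* TSB: `tsb = 1.5 b + 0.08 b²`, a monotone quadratic through the origin
  (zero bilirubin means a zero index);
* SpO~2~: `50 + 22 r − 1.2 r² + 0.3 r³ + 0.05 r⁴`, a monotone quartic
  mapping ratio values of roughly 0.46--2.33 onto 60--100 %.

The TSB and SpO~2~ coefficients are package choices (only the families are
published); they are chosen to be monotone over the physiological panel
ranges (Hb 5--22 g/dL, TSB 0--30 mg/dL, SpO~2~ 60--100 %) so the
inversion is unique. The hemoglobin index is split equally between the two
Q bands; the deoxyhemoglobin area is the 577.2 nm area divided by the
target ratio. Areas become amplitudes by dividing by the trapezoidal area
of a unit-amplitude Gaussian *on the same grid*, so that the pipeline's
own `componentAUC()` reproduces the target areas exactly, including the
edge truncation of the 462.92 nm band near 450 nm.

Generator widths are fixed per component at physically motivated values:
20 nm for the broad bilirubin band, 7/5 nm for the oxyhemoglobin Q bands
and 6 nm for deoxyhemoglobin (whole-blood Q bands have FWHM around
12--16 nm, i.e. \(\sigma \approx 5\text{--}7\) nm), and 25 nm for the
620 nm baseline term. A single shared width for all five components was
rejected: at 15 nm the 568.09 and 577.2 nm components are nearly collinear
(profile correlation \(\approx 0.91\)), which makes the amplitude split —
and with it the SpO~2~ ratio — ill-conditioned at any realistic noise
level. With gate targeting on (the default), the offset is chosen so the
absorbance at 620 nm is 0.55, the midpoint of the gate window.

The acquisition model uses a flat 12000-count reference, a 1500-count dark
with seeded 2-count read noise, and
`sample = dark + (reference − dark)·10^(−A)`. Detector noise of level
\(\sigma\) is added to the sample counts with standard deviation
\(\sigma (S-D)\ln 10\), which perturbs the absorbance by approximately
\(\sigma\); \(\sigma = 0.005\) plays the role of a clean acquisition and
\(\sigma = 0.05\) of a corrupted one. Everything is a pure function of the
panel and an integer seed; cohorts derive per-subject seeds from a master
seed.

What the generator does **not** emulate: melanin and skin scattering
spectra, the nail-plate layering, wavelength-dependent lamp shape,
correlated (non-white) detector noise, and any physiological coupling
between analytes. Passing the end-to-end tests therefore shows that the
algorithm inverts its own signal model in the stated noise regime — it
does not reproduce the device's clinical accuracy, whose patient data are
unavailable.

## Validation statistics

`pairedRegression()` regresses device on reference and reports Pearson
r, slope, intercept and the two-sided slope p-value. `blandAltman()`
orients differences as device − reference and reports bias, spread and
bias ± 1.96·SD limits of agreement. `repeatability()` computes per-subject
means and SDs over replicates and pools SDs as a root mean square. One
definitional note: the replicate-SD formula is implemented as the
population standard deviation \(\sqrt{\sum_i (x_i-\mu)^2 / N}\) (the
printed source formula omits the square, which would not be a real
number), and `blandAltman()` uses the same divide-by-N convention for
consistency.

`sampleSize()` implements the Buderer-form diagnostic sample-size
equations,
\(n = \lceil z^2 S(1-S) / (W^2 P) \rceil\) with \(P\) replaced by
\(1-P\) for specificity; with sensitivity 0.95, specificity 0.80,
half-width 0.05 and prevalence 0.15 it returns 487 and 290 subjects.

## Numerical choices and problem sizes

* Optimizer: `nls.lm` with `ftol = ptol = 1e-15`, at most 1024 iterations;
  noiseless synthetic spectra are recovered to better than \(10^{-9}\)
  relative on all 11 parameters.
* Grid: 450--650 nm at 0.47 nm (426 points) throughout; grid alignment is
  by linear interpolation (at this spacing, higher-order interpolation is
  indistinguishable below detector noise).
* The test suite and the acceptance script use cohorts of 200 subjects at
  \(\sigma \in \{0, 0.005\}\) and 40 subjects at \(\sigma = 0.05\), and 50
  seeds for the amplitude-recovery Monte Carlo; these sizes give stable
  rates while keeping a full run in seconds.
* Ties and boundaries: the residual count is inclusive
  (\(|r| \le t\)), the gate interval is closed, disease cuts are strict
  `<` (jaundice `>=`), all applied literally.

## Limitations

The package reproduces the *algorithm* of the device, not its clinical
performance; published correlation coefficients and Bland--Altman biases
derive from thousands of neonates whose spectra are not public. The
jaundice flag is a flat TSB cut, not a nomogram zone. The time-series
monitoring mode of the device and all hardware/IoT layers are out of
scope.

## A minimal session

```{r example, eval = FALSE}
truth <- truthRecord(BloodPanel(hb = 10.2, tsb = 29.8, spo2 = 92),
                     sigma = 0.005, seed = 7)
triple <- generateSpectrum(truth)
report <- runMeasurement(triple$sample, triple$dark, triple$reference,
                         calibration = truthCalibration(),
                         config = hemospecConfig(boxcar = list(width = 0L)))
report
```
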