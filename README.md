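# hemospec

Hemoglobin, total serum bilirubin and oxygen saturation from a single
visible-range diffuse-reflectance spectrum.

`hemospec` is aimed at biomedical-optics and point-of-care-diagnostics
researchers who work with nail-bed (or similar tissue) reflectance spectra
and want a reproducible, testable implementation of the staged
spectral-analysis algorithm behind non-invasive neonatal screening for
anemia, jaundice and hypoxia — plus a synthetic-spectrum generator so the
whole chain can be exercised, calibrated and validated without any
clinical acquisitions.

## The method

A measurement consists of three detector-count spectra on one 450–650 nm
grid — tissue sample *S*, dark *D*, reference *R* — combined into the
dark-corrected decadic absorbance

```
A(λ) = −log10( (S(λ) − D(λ)) / (R(λ) − D(λ)) )
```

A geometry gate requires A(620 nm) ∈ [0.5, 0.6]. The absorbance is then
deconvolved into five Gaussian components with fixed centers plus a shared
offset,

```
y(λ) = y0 + Σᵢ Aᵢ exp( −½ ((λ − x_c,i)/wᵢ)² ),
x_c = {462.92, 539.34, 568.09, 577.2, 620} nm
```

by bounded Levenberg–Marquardt least squares over the 11 free parameters.
A fit is accepted when ≥ 98 % (configurable: 90 %/95 %) of residuals lie
within ±0.02 absorbance. Trapezoidal areas under the fitted components
(the 620 nm baseline term excluded) form three instrument indices

```
I_Hb   = AUC(539.34) + AUC(577.2)      two oxyhemoglobin Q bands
I_TSB  = AUC(462.92)                   bilirubin band
I_SpO2 = AUC(577.2) / AUC(568.09)      oxy / deoxy ratio
```

mapped to blood values through per-analyte calibration curves (Hb linear,
TSB quadratic, SpO₂ quartic) and classified against disease thresholds
(anemia Hb < 11 g/dL, hypoxia SpO₂ < 92 %, jaundice TSB ≥ 15 mg/dL by
default). The validation battery (linear regression, Bland–Altman limits
of agreement, replicate repeatability, Buderer-form diagnostic sample
sizes) is included. See the methods vignette
(`vignettes/hemospec-methods.Rmd`) for the model details and design
decisions.

## Worked example

Generate one synthetic acquisition for an anemic, jaundiced subject with
known ground truth (Hb 10.2 g/dL, TSB 29.8 mg/dL, SpO₂ 92 %) at a
realistic noise level, and run the full measurement chain:

```r
library(hemospec)

truth  <- truthRecord(BloodPanel(hb = 10.2, tsb = 29.8, spo2 = 92),
                      sigma = 0.005, seed = 7)
triple <- generateSpectrum(truth)
report <- runMeasurement(triple$sample, triple$dark, triple$reference,
                         calibration = truthCalibration(),
                         config = hemospecConfig(boxcar = list(width = 0L)))
report
#> MeasurementReport [anon]: accepted
#> BloodPanel: Hb 10.27 g/dL, TSB 30.09 mg/dL, SpO2 90.8 %
#> ClassificationResult: anemia=TRUE, hypoxia=TRUE, jaundice=TRUE

report@fit
#> DeconvolutionResult (five-Gaussian cumulative fit)
#>   offset y0 = 0.39898, mse = 2.181e-05
#>     462.92 nm: A = 0.32622, w = 20.117 nm (FWHM 47.372)
#>     539.34 nm: A = 0.11532, w = 7.074 nm (FWHM 16.658)
#>     568.09 nm: A = 0.07021, w = 6.014 nm (FWHM 14.162)
#>     577.20 nm: A = 0.15934, w = 5.114 nm (FWHM 12.043)
#>     620.00 nm: A = 0.15151, w = 24.910 nm (FWHM 58.659)
#>   residual fraction 1.0000 within +/-0.02 -> ACCEPTED at partition 0.98
```

The recovered panel (10.27 / 30.09 / 90.8) sits within the noise-level
uncertainty of the ground truth, the fit passes the 98 % residual
partition, and all three disease flags fire as they should for this
subject. At `sigma = 0` the recovery is exact to numerical precision; at
`sigma = 0.05` the residual-fraction rule rejects the spectrum and the
report asks for re-acquisition instead of producing a panel.

A thin command-line interface over the same functions is installed at
`inst/cli/hemospec.R` (`measure`, `batch`, `calibrate`, `synth`
subcommands; exit code 0 = accepted, 3 = rejected, 4 = input error).

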