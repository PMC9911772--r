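#' @import methods
NULL

#' Fixed deconvolution peak centers (nm)
#'
#' The five wavelengths at which Gaussian components are anchored during
#' spectral deconvolution: the bilirubin absorption feature (462.92 nm), the
#' two Q bands of oxyhemoglobin (539.34 and 577.2 nm), the deoxyhemoglobin
#' feature (568.09 nm), and a broad 620 nm component that absorbs baseline
#' and scattering contributions. Centers are never free parameters.
#'
#' @format Named numeric vector of length 5 (nm), in increasing order.
#' @export
peakCenters <- c(
  bilirubin = 462.92,
  oxyhb_q1  = 539.34,
  deoxyhb   = 568.09,
  oxyhb_q2  = 577.20,
  baseline  = 620.00
)

.validGrid <- function(w) {
  if (length(w) < 2L) return("wavelength grid must have at least 2 points")
  if (!all(is.finite(w))) return("wavelengths must be finite")
  if (any(diff(w) <= 0)) return("wavelengths must be strictly increasing")
  TRUE
}

#' RawSpectrum: a detector-count spectrum with an acquisition role
#'
#' Wavelength/intensity pairs from a single acquisition, tagged with its role
#' in the absorbance computation: the tissue measurement (`"sample"`), the
#' ambient/dark reading with the source off (`"dark"`), or the reflectance
#' standard reading (`"reference"`).
#'
#' @slot wavelength strictly increasing wavelengths in nm.
#' @slot intensity detector counts, finite and non-negative, same length.
#' @slot role one of `"sample"`, `"dark"`, `"reference"`.
#' @slot meta list of acquisition metadata (e.g. `integration_time_ms`,
#'   `boxcar_width`).
#' @export
setClass("RawSpectrum",
  representation(wavelength = "numeric", intensity = "numeric",
                 role = "character", meta = "list"),
  prototype(meta = list()))

setValidity("RawSpectrum", function(object) {
  msgs <- character()
  g <- .validGrid(object@wavelength)
  if (!isTRUE(g)) msgs <- c(msgs, g)
  if (length(object@intensity) != length(object@wavelength))
    msgs <- c(msgs, "intensity and wavelength must have equal length")
  if (!all(is.finite(object@intensity)))
    msgs <- c(msgs, "intensities must be finite")
  else if (any(object@intensity < 0))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(object@role) != 1L ||
      !object@role %in% c("sample", "dark", "reference"))
    msgs <- c(msgs, "role must be one of 'sample', 'dark', 'reference'")
  if (length(msgs)) msgs else TRUE
})

#' AbsorbanceSpectrum: processed decadic absorbance on a wavelength grid
#'
#' The unitless processed spectrum
#' \eqn{A(\lambda) = -\log_{10}((S - D)/(R - D))} computed from a
#' sample/dark/reference triple and cropped to the working window
#' (450--650 nm by default).
#'
#' @slot wavelength strictly increasing wavelengths in nm.
#' @slot absorbance finite unitless absorbance values, same length.
#' @export
setClass("AbsorbanceSpectrum",
  representation(wavelength = "numeric", absorbance = "numeric"))

setValidity("AbsorbanceSpectrum", function(object) {
  msgs <- character()
  g <- .validGrid(object@wavelength)
  if (!isTRUE(g)) msgs <- c(msgs, g)
  if (length(object@absorbance) != length(object@wavelength))
    msgs <- c(msgs, "absorbance and wavelength must have equal length")
  if (!all(is.finite(object@absorbance)))
    msgs <- c(msgs, "absorbance values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' GateResult: outcome of the 620 nm absorbance amplitude gate
#'
#' The acquisition-quality gate requires the absorbance at 620 nm to lie in
#' the closed interval \[lower, upper\] (default \[0.5, 0.6\]); in the device
#' this enforces a consistent probe-to-nail-bed geometry.
#'
#' @slot value absorbance at the gate wavelength (linear interpolation).
#' @slot wavelength gate wavelength in nm (620 by default).
#' @slot lower,upper inclusive interval bounds.
#' @slot passed `TRUE` iff `lower <= value <= upper`.
#' @export
setClass("GateResult",
  representation(value = "numeric", wavelength = "numeric",
                 lower = "numeric", upper = "numeric", passed = "logical"))

setValidity("GateResult", function(object) {
  ok <- object@passed == (object@value >= object@lower &
                          object@value <= object@upper)
  if (!isTRUE(ok)) "passed must equal (lower <= value <= upper)" else TRUE
})

#' DeconvolutionResult: a fitted five-Gaussian spectral decomposition
#'
#' Result of fitting \eqn{y_0 + \sum_i A_i \exp(-0.5((\lambda - x_{c,i})/w_i)^2)}
#' to an absorbance spectrum with the five centers held fixed. Carries the
#' fitted parameters, the cumulative curve, per-point residuals, the mean
#' squared error, and the residual-fraction acceptance decision.
#'
#' @slot wavelength fit grid (nm).
#' @slot observed the absorbance values that were fitted.
#' @slot components `data.frame` with one row per component: `center`,
#'   `amplitude`, `width` (the sigma-like parameter of the Gaussian), `fwhm`
#'   (`2 sqrt(2 log 2) * width`, derived), and `at_bound` (logical; parameter
#'   pinned at an optimizer bound).
#' @slot offset shared additive offset \eqn{y_0}.
#' @slot fitted cumulative fitted curve on the grid.
#' @slot residuals `observed - fitted`, per point.
#' @slot mse mean squared residual (the minimised objective).
#' @slot tolerance absolute absorbance half-width used for the residual count.
#' @slot residualFraction fraction of points with `|residual| <= tolerance`.
#' @slot partition acceptance threshold on the residual fraction.
#' @slot accepted `TRUE` iff `residualFraction >= partition`.
#' @slot convergence list with optimizer diagnostics (`info`, `message`,
#'   `iterations`, `deviance`).
#' @export
setClass("DeconvolutionResult",
  representation(wavelength = "numeric", observed = "numeric",
                 components = "data.frame", offset = "numeric",
                 fitted = "numeric", residuals = "numeric", mse = "numeric",
                 tolerance = "numeric", residualFraction = "numeric",
                 partition = "numeric", accepted = "logical",
                 convergence = "list"),
  prototype(convergence = list()))

setValidity("DeconvolutionResult", function(object) {
  msgs <- character()
  if (nrow(object@components) != 5L)
    msgs <- c(msgs, "exactly five Gaussian components are required")
  else if (!isTRUE(all.equal(sort(object@components$center),
                             sort(unname(peakCenters)))))
    msgs <- c(msgs, "component centers must be the five canonical centers")
  if (any(object@components$amplitude < 0))
    msgs <- c(msgs, "amplitudes must be non-negative")
  if (any(object@components$width <= 0))
    msgs <- c(msgs, "widths must be positive")
  n <- length(object@wavelength)
  if (length(object@fitted) != n || length(object@residuals) != n ||
      length(object@observed) != n)
    msgs <- c(msgs, "observed/fitted/residuals must match the grid length")
  if (object@residualFraction < 0 || object@residualFraction > 1)
    msgs <- c(msgs, "residualFraction must lie in [0, 1]")
  if (object@accepted != (object@residualFraction >= object@partition))
    msgs <- c(msgs, "accepted must equal residualFraction >= partition")
  if (length(msgs)) msgs else TRUE
})

#' InstrumentIndices: AUC-derived scalar indices for the three analytes
#'
#' Areas under the fitted chromophore components combined into one scalar per
#' analyte: hemoglobin index \eqn{AUC_{539.34} + AUC_{577.2}}, bilirubin
#' index \eqn{AUC_{462.92}}, oxygen-saturation index
#' \eqn{AUC_{577.2}/AUC_{568.09}}. The 620 nm baseline component never enters
#' an index.
#'
#' @slot hb hemoglobin index (nm x absorbance), >= 0.
#' @slot bilirubin bilirubin index (nm x absorbance), >= 0.
#' @slot spo2 oxygen-saturation index (unitless ratio), finite, >= 0.
#' @export
setClass("InstrumentIndices",
  representation(hb = "numeric", bilirubin = "numeric", spo2 = "numeric"))

setValidity("InstrumentIndices", function(object) {
  msgs <- character()
  if (!is.finite(object@hb) || object@hb < 0)
    msgs <- c(msgs, "hb index must be finite and non-negative")
  if (!is.finite(object@bilirubin) || object@bilirubin < 0)
    msgs <- c(msgs, "bilirubin index must be finite and non-negative")
  if (!is.finite(object@spo2) || object@spo2 < 0)
    msgs <- c(msgs, "spo2 index must be finite and non-negative")
  if (length(msgs)) msgs else TRUE
})

#' CalibrationModel: a per-analyte polynomial index-to-value mapping
#'
#' Each analyte has a fixed model family: hemoglobin is linear in its index,
#' total serum bilirubin quadratic, oxygen saturation quartic. Coefficients
#' are ordered from the constant term upward.
#'
#' @slot analyte one of `"Hb"`, `"TSB"`, `"SpO2"`.
#' @slot family one of `"linear"`, `"poly2"`, `"poly4"`.
#' @slot coefficients numeric of length degree + 1, constant term first.
#' @slot indexRange length-2 numeric; indices outside it flag extrapolation.
#' @slot diagnostics list of fit diagnostics (Pearson `r` for linear,
#'   `adj_r_squared` for polynomial families, plus `n`).
#' @export
setClass("CalibrationModel",
  representation(analyte = "character", family = "character",
                 coefficients = "numeric", indexRange = "numeric",
                 diagnostics = "list"),
  prototype(diagnostics = list()))

.familyDegree <- c(linear = 1L, poly2 = 2L, poly4 = 4L)
.analyteFamily <- c(Hb = "linear", TSB = "poly2", SpO2 = "poly4")

setValidity("CalibrationModel", function(object) {
  msgs <- character()
  if (!object@analyte %in% names(.analyteFamily))
    msgs <- c(msgs, "analyte must be one of 'Hb', 'TSB', 'SpO2'")
  else if (object@family != .analyteFamily[[object@analyte]])
    msgs <- c(msgs, sprintf("analyte %s requires family '%s'",
                            object@analyte, .analyteFamily[[object@analyte]]))
  if (!object@family %in% names(.familyDegree))
    msgs <- c(msgs, "family must be one of 'linear', 'poly2', 'poly4'")
  else if (length(object@coefficients) != .familyDegree[[object@family]] + 1L)
    msgs <- c(msgs, "coefficient count must equal polynomial degree + 1")
  if (length(object@indexRange) != 2L ||
      object@indexRange[1] > object@indexRange[2])
    msgs <- c(msgs, "indexRange must be an increasing length-2 numeric")
  if (length(msgs)) msgs else TRUE
})

#' BloodPanel: estimated (or true) blood values for one subject
#'
#' @slot hb hemoglobin, g/dL.
#' @slot tsb total serum bilirubin, mg/dL.
#' @slot spo2 oxygen saturation, percent, clamped to \[0, 100\].
#' @slot flags list: `spo2_clamped` (polynomial evaluated outside \[0, 100\])
#'   and `extrapolated` (character vector of analytes whose index fell
#'   outside the calibration range).
#' @export
setClass("BloodPanel",
  representation(hb = "numeric", tsb = "numeric", spo2 = "numeric",
                 flags = "list"),
  prototype(flags = list(spo2_clamped = FALSE, extrapolated = character())))

setValidity("BloodPanel", function(object) {
  msgs <- character()
  if (!all(is.finite(c(object@hb, object@tsb, object@spo2))))
    msgs <- c(msgs, "panel values must be finite")
  if (object@spo2 < 0 || object@spo2 > 100)
    msgs <- c(msgs, "spo2 must lie in [0, 100] (clamped on construction)")
  if (length(msgs)) msgs else TRUE
})

#' ClassificationResult: disease flags for one blood panel
#'
#' Anemia and hypoxia use strict "less than" thresholds (Hb < 11 g/dL,
#' SpO2 < 92 %); jaundice uses a single configurable TSB cut
#' (>= 15 mg/dL by default; this is a flat cut, not an age-dependent
#' nomogram zone).
#'
#' @slot anemia,hypoxia,jaundice logical flags.
#' @slot thresholds named list of the thresholds used.
#' @export
setClass("ClassificationResult",
  representation(anemia = "logical", hypoxia = "logical",
                 jaundice = "logical", thresholds = "list"))

#' MeasurementReport: structured end-to-end result for one measurement
#'
#' Produced by [runMeasurement()]. Rejected measurements (gate failure or
#' residual-fraction failure) still yield a report, with `panel` and
#' `classification` absent and `status` naming the failing criterion.
#'
#' @slot subject caller-supplied subject identifier.
#' @slot status `"accepted"`, `"rejected_gate"` or `"rejected_residuals"`.
#' @slot gate the [GateResult-class].
#' @slot fit the [DeconvolutionResult-class] (or `NULL` on gate rejection in
#'   strict mode).
#' @slot indices [InstrumentIndices-class] or `NULL`.
#' @slot panel [BloodPanel-class] or `NULL`.
#' @slot classification [ClassificationResult-class] or `NULL`.
#' @slot provenance list: input file names, config, timestamp.
#' @export
setClass("MeasurementReport",
  representation(subject = "character", status = "character", gate = "ANY",
                 fit = "ANY", indices = "ANY", panel = "ANY",
                 classification = "ANY", provenance = "list"),
  prototype(gate = NULL, fit = NULL, indices = NULL, panel = NULL,
            classification = NULL, provenance = list()))
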