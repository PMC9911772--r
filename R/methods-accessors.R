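#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("wavelengths", "RawSpectrum", function(x) x@wavelength)

#' @rdname accessors
#' @export
setMethod("wavelengths", "AbsorbanceSpectrum", function(x) x@wavelength)

#' @rdname accessors
#' @export
setMethod("wavelengths", "DeconvolutionResult", function(x) x@wavelength)

#' @rdname accessors
#' @export
setMethod("intensities", "RawSpectrum", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("spectrumRole", "RawSpectrum", function(x) x@role)

#' @rdname accessors
#' @export
setMethod("spectrumMeta", "RawSpectrum", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("absorbance", "AbsorbanceSpectrum", function(x) x@absorbance)

#' @rdname accessors
#' @export
setMethod("components", "DeconvolutionResult", function(x) x@components)

#' @rdname accessors
#' @export
setMethod("fitOffset", "DeconvolutionResult", function(x) x@offset)

#' @rdname accessors
#' @export
setMethod("mse", "DeconvolutionResult", function(x) x@mse)

#' @rdname accessors
#' @export
setMethod("fitted", "DeconvolutionResult", function(object) object@fitted)

#' @rdname accessors
#' @export
setMethod("residuals", "DeconvolutionResult", function(object) object@residuals)

#' @rdname accessors
#' @export
setMethod("isAccepted", "DeconvolutionResult", function(x) x@accepted)

#' @rdname accessors
#' @export
setMethod("isAccepted", "GateResult", function(x) x@passed)

#' @rdname accessors
#' @export
setMethod("isAccepted", "MeasurementReport",
          function(x) identical(x@status, "accepted"))

#' @rdname accessors
#' @param row.names,optional passed through for the `as.data.frame` contract.
#' @export
setMethod("as.data.frame", "BloodPanel",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(hb = x@hb, tsb = x@tsb, spo2 = x@spo2,
               row.names = row.names)
  })

#' @rdname accessors
#' @export
setMethod("as.data.frame", "InstrumentIndices",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(hb_index = x@hb, bili_index = x@bilirubin,
               spo2_index = x@spo2, row.names = row.names)
  })

setMethod("show", "RawSpectrum", function(object) {
  cat(sprintf("RawSpectrum [%s]: %d points, %.2f-%.2f nm\n",
              object@role, length(object@wavelength),
              min(object@wavelength), max(object@wavelength)))
  invisible(object)
})

setMethod("show", "AbsorbanceSpectrum", function(object) {
  cat(sprintf("AbsorbanceSpectrum: %d points, %.2f-%.2f nm, A in [%.4f, %.4f]\n",
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength), min(object@absorbance),
              max(object@absorbance)))
  invisible(object)
})

setMethod("show", "GateResult", function(object) {
  cat(sprintf("GateResult: A(%.0f nm) = %.4f, interval [%.2f, %.2f] -> %s\n",
              object@wavelength, object@value, object@lower, object@upper,
              if (object@passed) "PASS" else "FAIL"))
  invisible(object)
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat("DeconvolutionResult (five-Gaussian cumulative fit)\n")
  cat(sprintf("  offset y0 = %.5f, mse = %.3e\n", object@offset, object@mse))
  df <- object@components
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %8.2f nm: A = %.5f, w = %.3f nm (FWHM %.3f)%s\n",
                df$center[i], df$amplitude[i], df$width[i], df$fwhm[i],
                if (isTRUE(df$at_bound[i])) " [at bound]" else ""))
  cat(sprintf("  residual fraction %.4f within +/-%.3g -> %s at partition %.2f\n",
              object@residualFraction, object@tolerance,
              if (object@accepted) "ACCEPTED" else "REJECTED",
              object@partition))
  invisible(object)
})

setMethod("show", "InstrumentIndices", function(object) {
  cat(sprintf(
    "InstrumentIndices: Hb = %.4f, bilirubin = %.4f (nm*abs), SpO2 ratio = %.4f\n",
    object@hb, object@bilirubin, object@spo2))
  invisible(object)
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel [%s, %s]: coefficients (%s), index range [%.3g, %.3g]\n",
              object@analyte, object@family,
              paste(signif(object@coefficients, 6), collapse = ", "),
              object@indexRange[1], object@indexRange[2]))
  invisible(object)
})

setMethod("show", "BloodPanel", function(object) {
  cat(sprintf("BloodPanel: Hb %.2f g/dL, TSB %.2f mg/dL, SpO2 %.1f %%\n",
              object@hb, object@tsb, object@spo2))
  if (isTRUE(object@flags$spo2_clamped)) cat("  (SpO2 clamped)\n")
  if (length(object@flags$extrapolated))
    cat("  (extrapolated: ",
        paste(object@flags$extrapolated, collapse = ", "), ")\n", sep = "")
  invisible(object)
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult: anemia=%s, hypoxia=%s, jaundice=%s\n",
              object@anemia, object@hypoxia, object@jaundice))
  invisible(object)
})

setMethod("show", "MeasurementReport", function(object) {
  cat(sprintf("MeasurementReport [%s]: %s\n", object@subject, object@status))
  if (!is.null(object@panel)) show(object@panel)
  if (!is.null(object@classification)) show(object@classification)
  invisible(object)
})
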