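#' @include AllClasses.R
NULL

#' @title Accessors for hemospec objects
#' @description Accessor generics for the spectrum and fit classes. Slot
#'   access (`@`) is internal; user code should go through these.
#' @param x,object a hemospec S4 object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("spectrumRole", function(x) standardGeneric("spectrumRole"))

#' @rdname accessors
#' @export
setGeneric("spectrumMeta", function(x) standardGeneric("spectrumMeta"))

#' @rdname accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("fitOffset", function(x) standardGeneric("fitOffset"))

#' @rdname accessors
#' @export
setGeneric("mse", function(x) standardGeneric("mse"))

#' Residual fraction: share of residuals within a tolerance band
#'
#' The acceptance statistic of the deconvolution stage: the fraction of
#' per-point residuals whose absolute value is less than or equal to
#' `tolerance` (inclusive at equality). For a numeric vector the fraction is
#' computed; for a [DeconvolutionResult-class] the stored value is returned.
#'
#' @param x numeric residual vector, or a `DeconvolutionResult`.
#' @param tolerance positive absolute absorbance tolerance (default 0.02).
#' @return a fraction in \[0, 1\].
#' @examples
#' residualFraction(c(0, 0.01, -0.05), tolerance = 0.02)  # 2/3
#' @export
setGeneric("residualFraction",
           function(x, tolerance = 0.02) standardGeneric("residualFraction"))

#' @rdname accessors
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))
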