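#' @include AllClasses.R
NULL

#' Boxcar (running-average) smoothing
#'
#' Replaces every point by the arithmetic mean of the window of
#' `2 * width + 1` points centered on it, the smoothing convention of
#' spectrometer acquisition software (the device acquisition setting is
#' width 2, i.e. a 5-point running average). At the spectrum ends the window
#' is truncated symmetrically -- a point `k` steps from the edge uses a
#' `2k + 1`-point window -- so no data are fabricated beyond the measured
#' range.
#'
#' @param spectrum a [RawSpectrum-class].
#' @param width non-negative integer half-width; 0 returns the spectrum
#'   unchanged.
#' @return the smoothed [RawSpectrum-class].
#' @export
boxcarSmooth <- function(spectrum, width = 2L) {
  stopifnot(is(spectrum, "RawSpectrum"))
  width <- as.integer(width)
  if (width < 0) stop("boxcar width must be non-negative")
  n <- length(spectrum@intensity)
  if (width == 0L) return(spectrum)
  if (n <= 2L * width)
    stop(sprintf("spectrum of length %d is too short for boxcar width %d",
                 n, width))
  y <- spectrum@intensity
  # cumulative-sum running mean with symmetric truncation at the edges
  cs <- c(0, cumsum(y))
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(width, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  RawSpectrum(spectrum@wavelength, out, role = spectrum@role,
              meta = spectrum@meta)
}

#' Compute the processed absorbance spectrum
#'
#' The dark-corrected decadic absorbance
#' \deqn{A(\lambda) = -\log_{10}\frac{S(\lambda) - D(\lambda)}
#'   {R(\lambda) - D(\lambda)}}
#' where \eqn{S}, \eqn{D}, \eqn{R} are the sample, dark and reference count
#' spectra on a common grid. Subtracting the dark reading and ratioing
#' against the reflectance standard compensates ambient light and the
#' scattering geometry. The result is cropped to the working window.
#'
#' @param sample,dark,reference [RawSpectrum-class] objects on one grid.
#' @param crop length-2 working window in nm (default `c(450, 650)`).
#' @return an [AbsorbanceSpectrum-class] on the cropped grid.
#' @examples
#' w <- seq(450, 650, by = 0.47)
#' s <- RawSpectrum(w, rep(1000, length(w)), "sample")
#' d <- RawSpectrum(w, rep(0, length(w)), "dark")
#' r <- RawSpectrum(w, rep(10000, length(w)), "reference")
#' absorbance(computeAbsorbance(s, d, r))[1]  # -log10(0.1) = 1
#' @export
computeAbsorbance <- function(sample, dark, reference,
                              crop = c(450, 650)) {
  for (s in list(sample, dark, reference))
    stopifnot(is(s, "RawSpectrum"))
  w <- sample@wavelength
  if (!identical(length(dark@wavelength), length(w)) ||
      !identical(length(reference@wavelength), length(w)) ||
      any(dark@wavelength != w) || any(reference@wavelength != w))
    stop("sample, dark and reference must share a wavelength grid; ",
         "use alignToCommonGrid() first")
  denom <- reference@intensity - dark@intensity
  if (any(denom <= 0)) {
    bad <- w[denom <= 0]
    stop(sprintf(
      "reference - dark is non-positive at %d wavelength(s) (e.g. %.2f nm): saturated or invalid reference",
      length(bad), bad[1]))
  }
  numer <- sample@intensity - dark@intensity
  if (any(numer <= 0)) {
    bad <- w[numer <= 0]
    stop(sprintf(
      "sample - dark is non-positive at %d wavelength(s) (e.g. %.2f nm): acquisition fault, re-acquire",
      length(bad), bad[1]))
  }
  a <- -log10(numer / denom)
  keep <- w >= crop[1] & w <= crop[2]
  if (sum(keep) < 2)
    stop("fewer than 2 grid points inside the working window")
  AbsorbanceSpectrum(w[keep], a[keep])
}

#' Absorbance amplitude gate at 620 nm
#'
#' Evaluates the absorbance at the gate wavelength (620 nm) by linear
#' interpolation between the flanking grid points and tests it against the
#' inclusive interval \[0.5, 0.6\]. In the device this gate enforces the
#' acquisition geometry (0.7 cm spot, 0.6 cm probe distance); spectra
#' outside the band indicate a mispositioned probe.
#'
#' @param spectrum an [AbsorbanceSpectrum-class] whose grid covers the gate
#'   wavelength.
#' @param lower,upper inclusive interval bounds (defaults 0.5 and 0.6).
#' @param wavelength_nm gate wavelength (default 620).
#' @return a [GateResult-class].
#' @export
checkGate <- function(spectrum, lower = 0.5, upper = 0.6,
                      wavelength_nm = 620) {
  stopifnot(is(spectrum, "AbsorbanceSpectrum"))
  w <- spectrum@wavelength
  if (wavelength_nm < min(w) || wavelength_nm > max(w))
    stop(sprintf("grid does not cover the gate wavelength %.1f nm",
                 wavelength_nm))
  a620 <- stats::approx(w, spectrum@absorbance, xout = wavelength_nm)$y
  new("GateResult", value = a620, wavelength = wavelength_nm,
      lower = lower, upper = upper,
      passed = a620 >= lower && a620 <= upper)
}
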