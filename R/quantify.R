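#' @include AllClasses.R deconvolve.R
NULL

#' Instrument indices from a fitted deconvolution
#'
#' Combines the areas under the fitted chromophore components into the three
#' instrument indices: hemoglobin \eqn{AUC_{539.34} + AUC_{577.2}} (the two
#' oxyhemoglobin Q bands), bilirubin \eqn{AUC_{462.92}}, and oxygen
#' saturation \eqn{AUC_{577.2} / AUC_{568.09}} (oxy over deoxy). The 620 nm
#' component corrects baseline and scattering only and is excluded from
#' every index.
#'
#' @param result an accepted [DeconvolutionResult-class].
#' @param grid wavelength grid for the component integrals; defaults to the
#'   fit grid.
#' @param force evaluate indices even for a rejected fit (default `FALSE`).
#' @return an [InstrumentIndices-class].
#' @export
computeIndices <- function(result, grid = wavelengths(result),
                           force = FALSE) {
  stopifnot(is(result, "DeconvolutionResult"))
  if (!result@accepted && !force)
    stop("deconvolution was rejected (residual fraction ",
         signif(result@residualFraction, 4), " < partition ",
         result@partition, "); use force = TRUE to override")
  comps <- result@components
  aucOf <- function(center) {
    i <- which(abs(comps$center - center) < 1e-6)
    componentAUC(comps$center[i], comps$amplitude[i], comps$width[i], grid)
  }
  auc539 <- aucOf(539.34)
  auc568 <- aucOf(568.09)
  auc577 <- aucOf(577.20)
  auc462 <- aucOf(462.92)
  if (auc568 <= 0)
    stop("degenerate fit: deoxyhemoglobin component area is not positive, ",
         "SpO2 ratio undefined")
  new("InstrumentIndices", hb = auc539 + auc577, bilirubin = auc462,
      spo2 = auc577 / auc568)
}

#' Construct a calibration model from known coefficients
#'
#' @param analyte `"Hb"`, `"TSB"` or `"SpO2"`.
#' @param coefficients numeric, constant term first; length must match the
#'   analyte's fixed family (linear, quadratic, quartic respectively).
#' @param indexRange length-2 valid index range.
#' @param diagnostics optional list of fit diagnostics.
#' @return a [CalibrationModel-class].
#' @export
CalibrationModel <- function(analyte, coefficients,
                             indexRange = c(-Inf, Inf),
                             diagnostics = list()) {
  new("CalibrationModel", analyte = analyte,
      family = unname(.analyteFamily[analyte]),
      coefficients = as.numeric(coefficients),
      indexRange = as.numeric(indexRange), diagnostics = diagnostics)
}

.polyEval <- function(coef, x) {
  y <- 0
  for (k in rev(seq_along(coef))) y <- y * x + coef[k]
  y
}

#' Fit a per-analyte calibration curve
#'
#' Ordinary least squares of the laboratory value on the instrument index
#' with the analyte's fixed polynomial family: hemoglobin linear, total
#' serum bilirubin quadratic, oxygen saturation quartic. Diagnostics carry
#' the Pearson correlation `r` for the linear family and the (standard,
#' degree-adjusted) adjusted R-squared for polynomial families.
#'
#' @param table paired table from [pairedTable()] or [readPairedTable()]:
#'   `device` holds the instrument index, `reference` the laboratory value.
#' @param analyte `"Hb"`, `"TSB"` or `"SpO2"`.
#' @return a [CalibrationModel-class] whose `indexRange` is the observed
#'   index range.
#' @export
fitCalibration <- function(table, analyte = c("Hb", "TSB", "SpO2")) {
  analyte <- match.arg(analyte)
  degree <- .familyDegree[[.analyteFamily[[analyte]]]]
  x <- table$device
  y <- table$reference
  if (length(x) < degree + 2L)
    stop(sprintf(
      "calibration for %s needs at least %d rows (degree %d), got %d",
      analyte, degree + 2L, degree, length(x)))
  if (stats::sd(x) == 0)
    stop("degenerate calibration data: all indices are equal")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  if (anyNA(coefs))
    stop("rank-deficient calibration design for ", analyte)
  diag <- list(n = length(x))
  if (degree == 1L) {
    diag$r <- stats::cor(x, y)
  } else {
    diag$adj_r_squared <- summary(fit)$adj.r.squared
  }
  CalibrationModel(analyte, coefs, indexRange = range(x),
                   diagnostics = diag)
}

#' Map instrument indices to a blood panel
#'
#' Evaluates each analyte's calibration polynomial at its instrument index.
#' An index outside a model's valid range is flagged as extrapolated; the
#' oxygen-saturation polynomial is unbounded so its value is clamped to
#' \[0, 100\] % with the clamp flagged.
#'
#' @param indices an [InstrumentIndices-class].
#' @param models named list with one [CalibrationModel-class] per analyte
#'   (`Hb`, `TSB`, `SpO2`), e.g. from [readCalibration()].
#' @return a [BloodPanel-class].
#' @export
applyCalibration <- function(indices, models) {
  stopifnot(is(indices, "InstrumentIndices"))
  need <- c("Hb", "TSB", "SpO2")
  missing_m <- setdiff(need, names(models))
  if (length(missing_m))
    stop("missing calibration model(s): ", paste(missing_m, collapse = ", "))
  for (m in need) {
    stopifnot(is(models[[m]], "CalibrationModel"))
    if (models[[m]]@analyte != m)
      stop("calibration model under key '", m, "' is for analyte '",
           models[[m]]@analyte, "'")
  }
  xs <- c(Hb = indices@hb, TSB = indices@bilirubin, SpO2 = indices@spo2)
  extrapolated <- character()
  vals <- vapply(need, function(m) {
    rng <- models[[m]]@indexRange
    if (xs[[m]] < rng[1] || xs[[m]] > rng[2])
      extrapolated <<- c(extrapolated, m)
    .polyEval(models[[m]]@coefficients, xs[[m]])
  }, 0)
  spo2 <- vals[["SpO2"]]
  clamped <- spo2 < 0 || spo2 > 100
  spo2 <- min(100, max(0, spo2))
  new("BloodPanel", hb = vals[["Hb"]], tsb = vals[["TSB"]], spo2 = spo2,
      flags = list(spo2_clamped = clamped, extrapolated = extrapolated))
}

#' Construct a blood panel directly
#'
#' @param hb hemoglobin, g/dL.
#' @param tsb total serum bilirubin, mg/dL.
#' @param spo2 oxygen saturation, percent.
#' @return a [BloodPanel-class].
#' @export
BloodPanel <- function(hb, tsb, spo2) {
  new("BloodPanel", hb = as.numeric(hb), tsb = as.numeric(tsb),
      spo2 = as.numeric(spo2),
      flags = list(spo2_clamped = FALSE, extrapolated = character()))
}

#' Classify a blood panel against disease thresholds
#'
#' Applies the strict "less than" cuts for anemia (Hb < 11 g/dL) and
#' hypoxia (SpO2 < 92 %), and a flat configurable cut for jaundice
#' (TSB >= 15 mg/dL by default). The jaundice cut is a single threshold,
#' not an age-in-hours nomogram zone.
#'
#' @param panel a [BloodPanel-class].
#' @param thresholds list with `hb_anemia`, `spo2_hypoxia`, `tsb_jaundice`
#'   (defaults from [hemospecConfig()]).
#' @return a [ClassificationResult-class].
#' @examples
#' classifyPanel(BloodPanel(hb = 10.2, tsb = 29.8, spo2 = 92))
#' @export
classifyPanel <- function(panel, thresholds = hemospecConfig()$classify) {
  stopifnot(is(panel, "BloodPanel"))
  new("ClassificationResult",
      anemia = panel@hb < thresholds$hb_anemia,
      hypoxia = panel@spo2 < thresholds$spo2_hypoxia,
      jaundice = panel@tsb >= thresholds$tsb_jaundice,
      thresholds = thresholds)
}

#' Write calibration models to a JSON file
#'
#' One object per analyte with `analyte`, `family`, `coefficients`
#' (constant term first), `index_range` and `diagnostics`.
#'
#' @param models named list of [CalibrationModel-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCalibration <- function(models, path) {
  obj <- lapply(models, function(m) list(
    analyte = m@analyte, family = m@family,
    coefficients = m@coefficients, index_range = m@indexRange,
    diagnostics = m@diagnostics))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read calibration models from a JSON file
#'
#' @param path path written by [writeCalibration()].
#' @return named list of [CalibrationModel-class] objects.
#' @export
readCalibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(m)
    CalibrationModel(m$analyte, unlist(m$coefficients),
                     indexRange = unlist(m$index_range),
                     diagnostics = as.list(m$diagnostics)))
  names(out) <- vapply(out, function(m) m@analyte, "")
  out
}
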