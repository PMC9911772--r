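#' @include synthgen.R valstats.R preprocess.R config.R
NULL

.asRawSpectrum <- function(x, role) {
  if (is(x, "RawSpectrum")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(readSpectrum(x, role = role))
  stop("expected a RawSpectrum or a file path for the ", role, " spectrum")
}

.asCalibration <- function(x) {
  if (is.character(x) && length(x) == 1L) return(readCalibration(x))
  if (is.list(x)) return(x)
  stop("calibration must be a named list of models or a JSON file path")
}

#' Run one end-to-end measurement
#'
#' Executes the full measurement chain: read, align to a common grid,
#' boxcar-smooth, compute absorbance, check the 620 nm gate, fit the
#' five-Gaussian model, apply the residual-fraction acceptance rule,
#' compute instrument indices, map them through the calibration curves,
#' and classify the resulting panel. A rejected measurement (gate failure
#' in strict mode, or residual fraction below the partition) still yields
#' a structured report whose `status` names the failing criterion as
#' re-acquisition guidance; no panel is reported for it.
#'
#' @param sample,dark,reference [RawSpectrum-class] objects or file paths.
#' @param calibration named list of [CalibrationModel-class] objects (keys
#'   `Hb`, `TSB`, `SpO2`) or the path of a calibration JSON file.
#' @param config configuration list from [hemospecConfig()] or a config
#'   JSON path.
#' @param subject subject identifier recorded in the report.
#' @return a [MeasurementReport-class].
#' @export
runMeasurement <- function(sample, dark, reference, calibration,
                           config = hemospecConfig(), subject = "anon") {
  if (is.character(config)) config <- readConfig(config)
  models <- .asCalibration(calibration)
  missing_m <- setdiff(c("Hb", "TSB", "SpO2"), names(models))
  if (length(missing_m))
    stop("calibration is missing model(s): ",
         paste(missing_m, collapse = ", "))

  spectra <- list(sample = .asRawSpectrum(sample, "sample"),
                  dark = .asRawSpectrum(dark, "dark"),
                  reference = .asRawSpectrum(reference, "reference"))
  spectra <- alignToCommonGrid(spectra, crop = config$crop)
  if (config$boxcar$width > 0)
    spectra <- lapply(spectra, boxcarSmooth, width = config$boxcar$width)

  absorb <- computeAbsorbance(spectra$sample, spectra$dark,
                              spectra$reference, crop = config$crop)
  gate <- checkGate(absorb, lower = config$gate$lower,
                    upper = config$gate$upper,
                    wavelength_nm = config$gate$wavelength_nm)
  prov <- list(config = config, timestamp = format(Sys.time(), tz = "UTC"),
               inputs = list(
                 sample = if (is.character(sample)) sample else "<memory>",
                 dark = if (is.character(dark)) dark else "<memory>",
                 reference = if (is.character(reference)) reference
                             else "<memory>"))

  if (!gate@passed && isTRUE(config$gate$strict))
    return(new("MeasurementReport", subject = subject,
               status = "rejected_gate", gate = gate, provenance = prov))

  fit <- fitFiveGaussians(absorb, config = config)
  if (!fit@accepted)
    return(new("MeasurementReport", subject = subject,
               status = "rejected_residuals", gate = gate, fit = fit,
               provenance = prov))

  indices <- computeIndices(fit)
  panel <- applyCalibration(indices, models)
  cls <- classifyPanel(panel, thresholds = config$classify)
  new("MeasurementReport", subject = subject, status = "accepted",
      gate = gate, fit = fit, indices = indices, panel = panel,
      classification = cls, provenance = prov)
}

#' Run a batch of measurements from a manifest
#'
#' The manifest is a CSV with columns `subject_id`, `sample`, `dark`,
#' `reference` (file paths). A malformed row is recorded as a row-level
#' error and the batch continues. Counts conserve:
#' `processed = accepted + rejected` (errors are counted separately).
#'
#' @param manifest manifest CSV path, or a `data.frame` with those columns.
#' @param calibration as in [runMeasurement()].
#' @param config as in [runMeasurement()].
#' @return list of class `"hemospec_batch"`: `reports` (per-subject
#'   [MeasurementReport-class] or error condition), `summary` (`data.frame`
#'   with per-subject status and panel values), `counts` (list
#'   `processed`, `accepted`, `rejected`, `errors`).
#' @export
runBatch <- function(manifest, calibration, config = hemospecConfig()) {
  df <- if (is.data.frame(manifest)) manifest
        else utils::read.csv(manifest, stringsAsFactors = FALSE)
  needed <- c("subject_id", "sample", "dark", "reference")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("manifest is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (is.character(config)) config <- readConfig(config)
  models <- .asCalibration(calibration)

  reports <- vector("list", nrow(df))
  names(reports) <- df$subject_id
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    rep_i <- tryCatch(
      runMeasurement(df$sample[i], df$dark[i], df$reference[i],
                     calibration = models, config = config,
                     subject = df$subject_id[i]),
      error = function(e) e)
    reports[[i]] <- rep_i
    if (inherits(rep_i, "error")) {
      rows[[i]] <- data.frame(
        subject_id = df$subject_id[i], status = "error",
        hb = NA_real_, tsb = NA_real_, spo2 = NA_real_,
        residual_fraction = NA_real_, stringsAsFactors = FALSE)
    } else {
      has_panel <- !is.null(rep_i@panel)
      rows[[i]] <- data.frame(
        subject_id = df$subject_id[i], status = rep_i@status,
        hb = if (has_panel) rep_i@panel@hb else NA_real_,
        tsb = if (has_panel) rep_i@panel@tsb else NA_real_,
        spo2 = if (has_panel) rep_i@panel@spo2 else NA_real_,
        residual_fraction = if (!is.null(rep_i@fit))
          rep_i@fit@residualFraction else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  summary_df <- do.call(rbind, rows)
  if (is.null(summary_df))
    summary_df <- data.frame(subject_id = character(), status = character(),
                             hb = numeric(), tsb = numeric(),
                             spo2 = numeric(),
                             residual_fraction = numeric())
  n_err <- sum(summary_df$status == "error")
  n_acc <- sum(summary_df$status == "accepted")
  structure(
    list(reports = reports, summary = summary_df,
         counts = list(processed = nrow(summary_df) - n_err,
                       accepted = n_acc,
                       rejected = nrow(summary_df) - n_err - n_acc,
                       errors = n_err)),
    class = "hemospec_batch")
}

#' @export
print.hemospec_batch <- function(x, ...) {
  cat(sprintf("Batch: %d processed (%d accepted, %d rejected), %d error(s)\n",
              x$counts$processed, x$counts$accepted, x$counts$rejected,
              x$counts$errors))
  invisible(x)
}

#' Validate device output against reference values
#'
#' Runs the validation statistics battery -- linear regression and
#' Bland--Altman agreement -- for each analyte's device-vs-reference pairs.
#'
#' @param pairs named list of paired tables (see [pairedTable()]), typically
#'   with entries `Hb`, `TSB`, `SpO2`. Analytes absent from the list are
#'   reported as skipped.
#' @return list of class `"hemospec_validation"`: per analyte either a list
#'   with `regression` and `bland_altman`, or the string `"skipped"`.
#' @export
validateDevice <- function(pairs) {
  stopifnot(is.list(pairs))
  analytes <- c("Hb", "TSB", "SpO2")
  out <- lapply(analytes, function(a) {
    tab <- pairs[[a]]
    if (is.null(tab)) return("skipped")
    if (nrow(tab) < 3)
      stop("validation for ", a, " needs at least 3 pairs")
    list(regression = pairedRegression(tab), bland_altman = blandAltman(tab))
  })
  names(out) <- analytes
  structure(out, class = "hemospec_validation")
}

#' @export
print.hemospec_validation <- function(x, ...) {
  for (a in names(x)) {
    cat(a, ": ", sep = "")
    if (identical(x[[a]], "skipped")) { cat("skipped\n"); next }
    cat("\n  ")
    print(x[[a]]$regression)
    cat("  ")
    print(x[[a]]$bland_altman)
  }
  invisible(x)
}

#' Process an in-memory synthetic cohort through the pipeline
#'
#' Convenience wrapper used in testing and validation studies: runs
#' [runMeasurement()] on every subject of a [generateCohort()] cohort
#' against the cohort's own ground-truth calibration and joins the
#' recovered panels to the truth table.
#'
#' @param cohort a `"hemospec_cohort"` object.
#' @param config configuration list (default disables boxcar smoothing,
#'   since generated spectra carry no high-frequency artifacts unless noise
#'   was requested).
#' @return `data.frame`: one row per subject with true (`hb`, `tsb`,
#'   `spo2`) and recovered (`hb_est`, `tsb_est`, `spo2_est`) values,
#'   `status` and `residual_fraction`.
#' @export
processCohort <- function(cohort,
                          config = hemospecConfig(boxcar = list(width = 0L))) {
  stopifnot(inherits(cohort, "hemospec_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    rep_i <- tryCatch(
      runMeasurement(s$spectra$sample, s$spectra$dark,
                     s$spectra$reference,
                     calibration = cohort$models, config = config,
                     subject = s$id),
      error = function(e) e)
    if (inherits(rep_i, "error"))
      return(data.frame(subject_id = s$id, status = "error",
                        hb_est = NA_real_, tsb_est = NA_real_,
                        spo2_est = NA_real_,
                        residual_fraction = NA_real_,
                        stringsAsFactors = FALSE))
    has_panel <- !is.null(rep_i@panel)
    data.frame(
      subject_id = s$id, status = rep_i@status,
      hb_est = if (has_panel) rep_i@panel@hb else NA_real_,
      tsb_est = if (has_panel) rep_i@panel@tsb else NA_real_,
      spo2_est = if (has_panel) rep_i@panel@spo2 else NA_real_,
      residual_fraction = if (!is.null(rep_i@fit))
        rep_i@fit@residualFraction else NA_real_,
      stringsAsFactors = FALSE)
  })
  merge(cohort$truth_table, do.call(rbind, rows), by = "subject_id",
        sort = TRUE)
}

#' Serialize a measurement report to JSON
#'
#' @param report a [MeasurementReport-class].
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
reportToJSON <- function(report, path = NULL) {
  stopifnot(is(report, "MeasurementReport"))
  obj <- list(
    schema = "hemospec-report/1",
    subject = report@subject, status = report@status,
    gate = if (!is.null(report@gate)) list(
      value = report@gate@value, lower = report@gate@lower,
      upper = report@gate@upper, passed = report@gate@passed),
    fit = if (!is.null(report@fit)) list(
      mse = report@fit@mse,
      residual_fraction = report@fit@residualFraction,
      partition = report@fit@partition, accepted = report@fit@accepted),
    indices = if (!is.null(report@indices)) list(
      hb = report@indices@hb, bilirubin = report@indices@bilirubin,
      spo2 = report@indices@spo2),
    panel = if (!is.null(report@panel)) list(
      hb = report@panel@hb, tsb = report@panel@tsb,
      spo2 = report@panel@spo2, flags = report@panel@flags),
    classification = if (!is.null(report@classification)) list(
      anemia = report@classification@anemia,
      hypoxia = report@classification@hypoxia,
      jaundice = report@classification@jaundice),
    provenance = report@provenance[c("timestamp", "inputs")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
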