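#' @include quantify.R
NULL

#' Default measurement grid
#'
#' The working wavelength grid of the instrument: 450 to 650 nm in steps of
#' 0.47 nm (426 points, the spectrograph resolution).
#'
#' @return numeric wavelength vector.
#' @export
defaultGrid <- function() seq(450, 650, by = 0.47)

# Per-component generator widths (nm, sigma-like parameter). Chosen on the
# line shapes of the chromophores: the bilirubin band is broad, the
# hemoglobin Q bands narrow (whole-blood Q-band FWHM ~ 12-16 nm, i.e.
# sigma ~ 5-7 nm); the 620 nm baseline component is broad by construction.
# Fixed during generation; the fit treats widths as free.
.generatorWidths <- c(
  bilirubin = 20, oxyhb_q1 = 7, deoxyhb = 6, oxyhb_q2 = 5, baseline = 25)

.physioRanges <- list(hb = c(5, 22), tsb = c(0, 30), spo2 = c(60, 100))

#' Ground-truth calibration models for the synthetic generator
#'
#' The fixed index-to-analyte mappings that define the synthetic study
#' conditions, one per analyte in the device's model families:
#'
#' * Hb (linear): `hb = 2.91 + 1.8 * index` -- the device's own
#'   98%-partition hemoglobin calibration line.
#' * TSB (quadratic): `tsb = 1.5 * index + 0.08 * index^2`, monotone
#'   increasing from the origin (zero bilirubin gives a zero index).
#' * SpO2 (quartic): `spo2 = 50 + 22 r - 1.2 r^2 + 0.3 r^3 + 0.05 r^4`,
#'   monotone increasing over the physiological ratio range and mapping
#'   ratios of roughly 0.46--2.33 onto 60--100 %.
#'
#' The generator inverts these mappings to turn a ground-truth blood panel
#' into component areas; fitting a calibration to generated cohorts
#' recovers them.
#'
#' @return named list of [CalibrationModel-class] objects (`Hb`, `TSB`,
#'   `SpO2`).
#' @export
truthCalibration <- function() {
  list(
    Hb = CalibrationModel("Hb", c(2.91, 1.8), indexRange = c(0.5, 12)),
    TSB = CalibrationModel("TSB", c(0, 1.5, 0.08), indexRange = c(0, 14)),
    SpO2 = CalibrationModel("SpO2", c(50, 22, -1.2, 0.3, 0.05),
                            indexRange = c(0.3, 2.6)))
}

#' Invert a calibration model
#'
#' Finds the instrument index at which the model's polynomial equals
#' `value`. The linear and quadratic families are inverted in closed form;
#' the quartic numerically (the generator families are monotone over their
#' index range, so the root is unique).
#'
#' @param model a [CalibrationModel-class].
#' @param value analyte value to invert.
#' @return the index.
#' @export
invertCalibration <- function(model, value) {
  stopifnot(is(model, "CalibrationModel"))
  cf <- model@coefficients
  if (model@family == "linear")
    return((value - cf[1]) / cf[2])
  if (model@family == "poly2") {
    # cf[3] x^2 + cf[2] x + (cf[1] - value) = 0, positive branch
    disc <- cf[2]^2 - 4 * cf[3] * (cf[1] - value)
    if (disc < 0) stop("value outside the range of the quadratic model")
    return((-cf[2] + sqrt(disc)) / (2 * cf[3]))
  }
  rng <- model@indexRange
  lo <- rng[1] - 0.5
  hi <- rng[2] + 0.5
  f <- function(x) .polyEval(cf, x) - value
  if (f(lo) * f(hi) > 0)
    stop("value ", value, " outside the invertible range of the ",
         model@analyte, " model")
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# trapezoidal area of a unit-amplitude Gaussian on the grid; the generator
# divides target areas by this so that componentAUC() on the same grid
# reproduces them exactly (incl. edge truncation of the bilirubin band)
.unitAUC <- function(center, width, grid)
  .trapz(grid, exp(-0.5 * ((grid - center) / width)^2))

#' Build a ground-truth generating record from a blood panel
#'
#' Inverts the ground-truth calibrations to obtain the three target indices,
#' splits the hemoglobin index equally between the two oxyhemoglobin Q
#' bands, sizes the deoxyhemoglobin area from the SpO2 ratio, and converts
#' each target area to an amplitude on the measurement grid. With
#' `gate_targeting` the shared offset is chosen so the absorbance at 620 nm
#' is 0.55, the midpoint of the acquisition gate.
#'
#' @param panel a [BloodPanel-class] inside the physiological ranges
#'   (Hb 5--22 g/dL, TSB 0--30 mg/dL, SpO2 60--100 %).
#' @param sigma detector noise level in absorbance-equivalent units
#'   (see [generateSpectrum()]).
#' @param seed integer seed that fully determines the generated triple.
#' @param grid wavelength grid (default [defaultGrid()]).
#' @param models ground-truth calibrations (default [truthCalibration()]).
#' @param gate_targeting tune the offset into the 620 nm gate window
#'   (default `TRUE`).
#' @return list of class `"hemospec_truth"`: `panel`, `indices`,
#'   `components` (generating amplitudes/widths), `offset`, `sigma`,
#'   `seed`, `grid`, `models`.
#' @export
truthRecord <- function(panel, sigma = 0, seed = 1L,
                        grid = defaultGrid(),
                        models = truthCalibration(),
                        gate_targeting = TRUE) {
  stopifnot(is(panel, "BloodPanel"))
  rng <- .physioRanges
  if (panel@hb < rng$hb[1] || panel@hb > rng$hb[2] ||
      panel@tsb < rng$tsb[1] || panel@tsb > rng$tsb[2] ||
      panel@spo2 < rng$spo2[1] || panel@spo2 > rng$spo2[2])
    stop("panel outside physiological generator ranges ",
         "(Hb 5-22 g/dL, TSB 0-30 mg/dL, SpO2 60-100 %)")

  hb_index <- invertCalibration(models$Hb, panel@hb)
  bili_index <- invertCalibration(models$TSB, panel@tsb)
  spo2_index <- invertCalibration(models$SpO2, panel@spo2)
  if (hb_index <= 0 || bili_index < 0 || spo2_index <= 0)
    stop("panel maps to non-positive indices under the truth calibration")

  # target areas: split Hb equally over the two Q bands; deoxy area from
  # the oxy/deoxy ratio
  auc <- c(bilirubin = bili_index,
           oxyhb_q1 = hb_index / 2,
           deoxyhb = (hb_index / 2) / spo2_index,
           oxyhb_q2 = hb_index / 2)
  widths <- .generatorWidths
  amps <- vapply(names(auc), function(k)
    auc[[k]] / .unitAUC(peakCenters[[k]], widths[[k]], grid), 0)
  amps <- c(amps, baseline = 0.15)

  comps <- data.frame(
    center = unname(peakCenters[names(amps)]),
    amplitude = unname(amps), width = unname(widths[names(amps)]),
    row.names = names(amps))
  comps <- comps[order(comps$center), ]

  if (gate_targeting) {
    at620 <- sum(.gauss(620, comps$center, comps$amplitude, comps$width))
    offset <- 0.55 - at620
  } else {
    offset <- 0.10
  }

  structure(
    list(panel = panel,
         indices = new("InstrumentIndices", hb = hb_index,
                       bilirubin = bili_index, spo2 = spo2_index),
         components = comps, offset = offset, sigma = sigma,
         seed = as.integer(seed), grid = grid, models = models),
    class = "hemospec_truth")
}

#' Generate a synthetic sample/dark/reference triple
#'
#' Forward model of one acquisition. The target absorbance is the
#' five-Gaussian cumulative curve of the truth record; the reference is a
#' flat lamp spectrum (12000 counts), the dark a small constant (1500
#' counts) with seeded read noise, and the sample is reconstructed through
#' the absorbance definition,
#' `sample = dark + (reference - dark) * 10^(-A)`. Detector noise of level
#' `sigma` (interpreted on the absorbance scale) is added to the sample
#' counts as Gaussian noise with standard deviation
#' `sigma * (sample - dark) * log(10)`, so the induced absorbance
#' perturbation has standard deviation approximately `sigma`.
#'
#' Because the same dark and reference arrays are returned with the sample,
#' [computeAbsorbance()] of a noiseless triple reproduces the target
#' absorbance to machine precision.
#'
#' @param truth a record from [truthRecord()].
#' @return named list of three [RawSpectrum-class] objects (`sample`,
#'   `dark`, `reference`) plus the noise-free `absorbance` target
#'   ([AbsorbanceSpectrum-class]).
#' @export
generateSpectrum <- function(truth) {
  stopifnot(inherits(truth, "hemospec_truth"))
  grid <- truth$grid
  a_target <- evalCumulative(truth$components, truth$offset, grid)

  set.seed(truth$seed)
  ref_counts <- rep(12000, length(grid))
  dark_counts <- 1500 + stats::rnorm(length(grid), 0, 2)
  signal <- (ref_counts - dark_counts) * 10^(-a_target)
  sample_counts <- dark_counts + signal
  if (truth$sigma > 0)
    sample_counts <- sample_counts +
      stats::rnorm(length(grid), 0, truth$sigma * signal * log(10))

  meta <- list(integration_time_ms = 3000, boxcar_width = 0,
               synthetic = "true", seed = truth$seed, sigma = truth$sigma)
  list(
    sample = RawSpectrum(grid, sample_counts, "sample", meta = meta),
    dark = RawSpectrum(grid, dark_counts, "dark", meta = meta),
    reference = RawSpectrum(grid, ref_counts, "reference", meta = meta),
    absorbance = AbsorbanceSpectrum(grid, a_target))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n` blood panels uniformly from the stated physiological ranges
#' and generates one spectrum triple per subject, with per-subject seeds
#' derived deterministically from the master seed. Output is a pure
#' function of the arguments.
#'
#' @param n number of subjects.
#' @param seed master seed.
#' @param sigma detector noise level on the absorbance scale (default 0).
#' @param hb_range,tsb_range,spo2_range sampling ranges; defaults
#'   Hb 6--21 g/dL, TSB 0.5--29 mg/dL, SpO2 62--99.5 % span the disease and
#'   normal zones while staying inside the generator's valid ranges.
#' @param gate_targeting tune offsets into the 620 nm gate (default `TRUE`).
#' @param models ground-truth calibrations (default [truthCalibration()]).
#' @return list of class `"hemospec_cohort"`: `subjects` (list of lists
#'   with `id`, `truth`, `spectra`), `truth_table` (`data.frame` of ids,
#'   true panel values and indices), `models`, `sigma`, `seed`.
#' @export
generateCohort <- function(n, seed = 1L, sigma = 0,
                           hb_range = c(6, 21), tsb_range = c(0.5, 29),
                           spo2_range = c(62, 99.5),
                           gate_targeting = TRUE,
                           models = truthCalibration()) {
  stopifnot(n >= 1)
  set.seed(seed)
  hb <- stats::runif(n, hb_range[1], hb_range[2])
  tsb <- stats::runif(n, tsb_range[1], tsb_range[2])
  spo2 <- stats::runif(n, spo2_range[1], spo2_range[2])
  subject_seeds <- (as.integer(seed) + 1009L * seq_len(n)) %% 2147483647L

  subjects <- lapply(seq_len(n), function(i) {
    truth <- truthRecord(BloodPanel(hb[i], tsb[i], spo2[i]), sigma = sigma,
                         seed = subject_seeds[i], models = models,
                         gate_targeting = gate_targeting)
    list(id = sprintf("S%04d", i), truth = truth,
         spectra = generateSpectrum(truth))
  })
  truth_table <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "id"),
    hb = hb, tsb = tsb, spo2 = spo2,
    hb_index = vapply(subjects, function(s) s$truth$indices@hb, 0),
    bili_index = vapply(subjects, function(s) s$truth$indices@bilirubin, 0),
    spo2_index = vapply(subjects, function(s) s$truth$indices@spo2, 0),
    seed = vapply(subjects, function(s) s$truth$seed, 0L),
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, truth_table = truth_table,
                 models = models, sigma = sigma, seed = as.integer(seed)),
            class = "hemospec_cohort")
}

#' @export
print.hemospec_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subject(s), sigma = %g, master seed = %d\n",
              length(x$subjects), x$sigma, x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject spectrum CSVs (`<id>_sample.csv`, `<id>_dark.csv`,
#' `<id>_reference.csv`), a `truth.csv` table, a `manifest.csv` suitable
#' for [runBatch()], and the ground-truth calibration as
#' `calibration.json`.
#'
#' @param cohort a cohort from [generateCohort()].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
writeCohortFiles <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hemospec_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    paths <- vapply(c("sample", "dark", "reference"), function(role) {
      p <- file.path(dir, sprintf("%s_%s.csv", s$id, role))
      writeSpectrum(s$spectra[[role]], p)
      p
    }, "")
    data.frame(subject_id = s$id, sample = paths[["sample"]],
               dark = paths[["dark"]], reference = paths[["reference"]],
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  utils::write.csv(cohort$truth_table, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  writeCalibration(cohort$models, file.path(dir, "calibration.json"))
  invisible(manifest_path)
}
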