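#' @include AllClasses.R
NULL

#' Construct a RawSpectrum
#'
#' @param wavelength strictly increasing wavelengths in nm.
#' @param intensity non-negative detector counts, same length.
#' @param role acquisition role: `"sample"`, `"dark"` or `"reference"`.
#' @param meta optional named list of acquisition metadata.
#' @return a validated [RawSpectrum-class].
#' @export
RawSpectrum <- function(wavelength, intensity, role = "sample",
                        meta = list()) {
  new("RawSpectrum", wavelength = as.numeric(wavelength),
      intensity = as.numeric(intensity), role = role, meta = meta)
}

#' Construct an AbsorbanceSpectrum
#'
#' @param wavelength strictly increasing wavelengths in nm.
#' @param absorbance finite unitless absorbance values, same length.
#' @return a validated [AbsorbanceSpectrum-class].
#' @export
AbsorbanceSpectrum <- function(wavelength, absorbance) {
  new("AbsorbanceSpectrum", wavelength = as.numeric(wavelength),
      absorbance = as.numeric(absorbance))
}

.parseNumericColumn <- function(txt, lines, col) {
  suppressWarnings(x <- as.numeric(txt))
  bad <- which(!is.finite(x) & !(txt %in% c("NA", "NaN")))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column %d at line %d",
                 txt[bad[1]], col, lines[bad[1]]))
  x
}

#' Read a spectrum file
#'
#' Reads a two-column spectrum file. The canonical dialect is
#' comma-separated with header `wavelength_nm,<value>` and `#`-prefixed
#' metadata lines (`# role: sample`, `# integration_time_ms: 3000`, ...).
#' Tab-separated files with a header (`"tsv"`) and headerless two-column
#' files (`"headerless"`, comma or whitespace separated) are also accepted.
#'
#' @param path path to the spectrum file.
#' @param dialect `"csv"` (default), `"tsv"` or `"headerless"`.
#' @param role acquisition role; overrides any role recorded in the file
#'   metadata. Required for headerless files without metadata.
#' @return a [RawSpectrum-class] (or an [AbsorbanceSpectrum-class] when the
#'   file's value column is named `absorbance`).
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(path, dialect = c("csv", "tsv", "headerless"),
                         role = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  all_lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(trimws(all_lines), "#")
  meta <- .parseMetaLines(all_lines[is_meta])
  body_idx <- which(!is_meta & nzchar(trimws(all_lines)))
  if (!length(body_idx)) stop("empty spectrum file: ", path)
  body <- all_lines[body_idx]

  sep <- switch(dialect, csv = ",", tsv = "\t", headerless = NA)
  header <- NULL
  if (dialect != "headerless") {
    header <- trimws(strsplit(body[1], sep, fixed = TRUE)[[1]])
    body <- body[-1]
    body_idx <- body_idx[-1]
  }
  if (!length(body)) stop("spectrum file has a header but no data: ", path)

  if (is.na(sep)) {
    fields <- strsplit(trimws(body), "[,\t ]+")
  } else {
    fields <- strsplit(body, sep, fixed = TRUE)
  }
  nf <- lengths(fields)
  if (any(nf < 2))
    stop(sprintf("expected two columns but found %d at line %d",
                 nf[which(nf < 2)[1]], body_idx[which(nf < 2)[1]]))
  w <- .parseNumericColumn(trimws(vapply(fields, `[`, "", 1L)), body_idx, 1L)
  v <- .parseNumericColumn(trimws(vapply(fields, `[`, "", 2L)), body_idx, 2L)

  g <- .validGrid(w)
  if (!isTRUE(g)) stop("invalid wavelength grid in ", path, ": ", g)

  value_name <- if (!is.null(header) && length(header) >= 2)
    tolower(header[2]) else "intensity"
  if (identical(value_name, "absorbance"))
    return(AbsorbanceSpectrum(w, v))

  role <- role %||% meta$role %||% "sample"
  meta$role <- NULL
  RawSpectrum(w, v, role = role, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parseMetaLines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) {
      val <- trimws(kv[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(kv[2])]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Write a spectrum file in the canonical dialect
#'
#' Writes a two-column comma-separated file with header
#' `wavelength_nm,intensity` (raw spectra) or `wavelength_nm,absorbance`
#' (absorbance spectra); the role and metadata go into `#`-prefixed comment
#' lines. Values are written with 15 significant digits so that
#' `readSpectrum(writeSpectrum(x))` reproduces the payload.
#'
#' @param spectrum a [RawSpectrum-class] or [AbsorbanceSpectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  if (is(spectrum, "RawSpectrum")) {
    w <- spectrum@wavelength; v <- spectrum@intensity
    value_name <- "intensity"
    meta <- c(list(role = spectrum@role), spectrum@meta)
  } else if (is(spectrum, "AbsorbanceSpectrum")) {
    w <- spectrum@wavelength; v <- spectrum@absorbance
    value_name <- "absorbance"
    meta <- list()
  } else stop("spectrum must be a RawSpectrum or AbsorbanceSpectrum")
  if (!length(w)) stop("refusing to write an empty spectrum")
  lines <- c(
    vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]), ""),
    paste0("wavelength_nm,", value_name),
    paste(format(w, digits = 15, trim = TRUE, scientific = FALSE),
          format(v, digits = 15, trim = TRUE), sep = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.interpSpectrum <- function(spec, grid) {
  if (length(spec@wavelength) == length(grid) &&
      all(spec@wavelength == grid)) return(spec)
  v <- stats::approx(spec@wavelength, spec@intensity, xout = grid,
                     rule = 1)$y
  RawSpectrum(grid, v, role = spec@role, meta = spec@meta)
}

#' Align spectra onto a common wavelength grid
#'
#' Restricts the first spectrum's grid to the working window (450--650 nm by
#' default) intersected with the wavelength span common to all spectra, then
#' linearly interpolates every spectrum onto that grid. Absorbance
#' computation is elementwise, so all spectra entering one measurement must
#' share a grid.
#'
#' @param spectra list of [RawSpectrum-class] objects.
#' @param crop length-2 numeric working window in nm.
#' @param min_overlap minimum acceptable overlap in nm (default 100).
#' @return list of `RawSpectrum` objects on the shared grid, same order.
#' @export
alignToCommonGrid <- function(spectra, crop = c(450, 650),
                              min_overlap = 100) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  lo <- max(c(crop[1], vapply(spectra, function(s) min(s@wavelength), 0)))
  hi <- min(c(crop[2], vapply(spectra, function(s) max(s@wavelength), 0)))
  if (hi - lo < min_overlap)
    stop(sprintf(
      "insufficient wavelength overlap: %.1f nm shared, %.0f nm required",
      max(0, hi - lo), min_overlap))
  base <- spectra[[1]]@wavelength
  grid <- base[base >= lo & base <= hi]
  lapply(spectra, .interpSpectrum, grid = grid)
}

#' Read a paired device-vs-reference table
#'
#' Reads a CSV with header `subject_id,device,reference`, the layout used by
#' calibration and validation: one row per subject, the device value (or
#' instrument index) and the laboratory reference value.
#'
#' @param path path to the CSV file.
#' @param analyte optional analyte label attached as an attribute.
#' @param units optional units string attached as an attribute.
#' @return a `data.frame` with columns `subject_id`, `device`, `reference`
#'   and attributes `analyte`/`units`.
#' @export
readPairedTable <- function(path, analyte = NULL, units = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "device", "reference")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("paired table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  pairedTable(df$device, df$reference, subject_id = df$subject_id,
              analyte = analyte, units = units)
}

#' Construct a paired table in memory
#'
#' @param device device values or instrument indices.
#' @param reference laboratory reference values, same length.
#' @param subject_id optional subject identifiers.
#' @param analyte,units optional labels stored as attributes.
#' @return a `data.frame` with columns `subject_id`, `device`, `reference`.
#' @export
pairedTable <- function(device, reference, subject_id = NULL,
                        analyte = NULL, units = NULL) {
  device <- as.numeric(device); reference <- as.numeric(reference)
  if (length(device) != length(reference))
    stop("device and reference must have equal length")
  if (anyNA(device) || anyNA(reference))
    stop("paired table must not contain missing values")
  if (is.null(subject_id)) subject_id <- seq_along(device)
  out <- data.frame(subject_id = subject_id, device = device,
                    reference = reference, stringsAsFactors = FALSE)
  attr(out, "analyte") <- analyte
  attr(out, "units") <- units
  out
}
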