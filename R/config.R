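#' Pipeline configuration
#'
#' Builds the configuration list consumed by every pipeline stage, starting
#' from the device defaults and applying any overrides. Keys:
#'
#' * `gate`: `lower` (0.5), `upper` (0.6), `wavelength_nm` (620),
#'   `strict` (`FALSE`; when `TRUE` a gate failure rejects the measurement
#'   with re-acquisition guidance instead of merely being recorded).
#' * `boxcar`: `width` (2) -- centered running average of `2*width + 1`
#'   points applied to the raw spectra; 0 disables smoothing.
#' * `crop`: working wavelength window in nm (`c(450, 650)`).
#' * `fit`: `tolerance` (0.02 absorbance), `partition` (0.98; the device's
#'   alternative partitions are 0.90 and 0.95), `width_bounds`
#'   (`c(1, 60)` nm), `amp_upper` (5), `max_iter` (1000).
#' * `classify`: `hb_anemia` (11 g/dL), `spo2_hypoxia` (92 %),
#'   `tsb_jaundice` (15 mg/dL).
#'
#' @param ... named overrides, e.g. `fit = list(partition = 0.95)`.
#'   Sub-lists are merged key-wise into the defaults.
#' @return a named configuration list.
#' @examples
#' cfg <- hemospecConfig(fit = list(partition = 0.90))
#' cfg$fit$partition
#' @export
hemospecConfig <- function(...) {
  defaults <- list(
    gate = list(lower = 0.5, upper = 0.6, wavelength_nm = 620,
                strict = FALSE),
    boxcar = list(width = 2L),
    crop = c(450, 650),
    fit = list(tolerance = 0.02, partition = 0.98,
               width_bounds = c(1, 60), amp_upper = 5, max_iter = 1000L),
    classify = list(hb_anemia = 11, spo2_hypoxia = 92, tsb_jaundice = 15)
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]]))
    overrides <- overrides[[1L]]
  if (length(overrides) && is.null(names(overrides)))
    stop("configuration overrides must be named")
  cfg <- utils::modifyList(defaults, overrides)
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  stopifnot(
    cfg$gate$lower <= cfg$gate$upper,
    cfg$boxcar$width >= 0,
    length(cfg$crop) == 2L, cfg$crop[1] < cfg$crop[2],
    cfg$fit$tolerance > 0,
    cfg$fit$partition > 0, cfg$fit$partition <= 1,
    length(cfg$fit$width_bounds) == 2L,
    cfg$fit$width_bounds[1] > 0,
    cfg$fit$width_bounds[1] < cfg$fit$width_bounds[2],
    cfg$fit$amp_upper > 0, cfg$fit$max_iter >= 1
  )
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a JSON configuration file whose keys mirror [hemospecConfig()] and
#' merges it over the defaults. Unknown keys are an error.
#'
#' @param path path to a JSON file.
#' @return a validated configuration list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("gate", "boxcar", "crop", "fit", "classify")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(hemospecConfig, raw)
}
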