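#' @include spectra-io.R
NULL

#' Linear regression of device values on reference values
#'
#' Ordinary least squares of the device reading on the laboratory reference,
#' with the Pearson correlation and the two-sided p-value for the slope --
#' the regression summary used to validate each analyte against its gold
#' standard.
#'
#' @param table paired table from [pairedTable()] or [readPairedTable()].
#' @return list of class `"hemospec_regression"` with `r`, `slope`,
#'   `intercept`, `n`, `p_value`.
#' @export
pairedRegression <- function(table) {
  x <- table$reference
  y <- table$device
  n <- length(x)
  if (n < 2) stop("regression needs at least 2 pairs")
  if (stats::sd(x) == 0) stop("degenerate data: reference values constant")
  if (stats::sd(y) == 0) stop("degenerate data: device values constant")
  fit <- stats::lm(y ~ x)
  p <- if (n >= 3) summary(fit)$coefficients["x", "Pr(>|t|)"] else NA_real_
  structure(
    list(r = stats::cor(x, y), slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), n = n, p_value = p),
    class = "hemospec_regression")
}

#' @export
print.hemospec_regression <- function(x, ...) {
  cat(sprintf("Regression (device ~ reference, n = %d): r = %.4f, slope = %.4f, intercept = %.4f, p = %.3g\n",
              x$n, x$r, x$slope, x$intercept, x$p_value))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented `device - reference` throughout. The bias is
#' their mean; the spread is the population standard deviation (divide by
#' N, consistent with the repeatability SD definition in
#' [repeatability()]); the 95% limits of agreement are
#' `bias +/- 1.96 * sd`.
#'
#' @param table paired table from [pairedTable()] or [readPairedTable()].
#' @return list of class `"hemospec_blandaltman"` with `bias`, `sd`,
#'   `loa_low`, `loa_high`, `n`, plus the `means` and `differences` used
#'   (for plotting).
#' @export
blandAltman <- function(table) {
  d <- table$device - table$reference
  n <- length(d)
  if (n < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  bias <- mean(d)
  sd_d <- sqrt(sum((d - bias)^2) / n)
  structure(
    list(bias = bias, sd = sd_d,
         loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
         n = n, means = (table$device + table$reference) / 2,
         differences = d),
    class = "hemospec_blandaltman")
}

#' @export
print.hemospec_blandaltman <- function(x, ...) {
  cat(sprintf("Bland-Altman (device - reference, n = %d): bias = %.4f, sd = %.4f, LoA [%.4f, %.4f]\n",
              x$n, x$bias, x$sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of differences against pair means with the bias line (solid) and
#' the 95% limits of agreement (dashed).
#'
#' @param x result of [blandAltman()].
#' @param ... passed to [graphics::plot()].
#' @export
plotBlandAltman <- function(x, ...) {
  stopifnot(inherits(x, "hemospec_blandaltman"))
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of device and reference",
                 ylab = "Device - reference", ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Repeatability of replicated measurements
#'
#' For each subject with k replicate measurements: the mean is the sum of
#' the replicates over their number, and the standard deviation is the
#' population form \eqn{\sqrt{\sum_i (x_i - \mu)^2 / N}}. The pooled SD is
#' the root-mean-square of the per-subject SDs.
#'
#' @param replicates list of numeric vectors, one per subject, each with
#'   at least 2 replicates; names are subject ids.
#' @return list of class `"hemospec_repeatability"` with `per_subject`
#'   (`data.frame` of `subject`, `k`, `mean`, `sd`), `pooled_sd`, `k`.
#' @examples
#' repeatability(list(a = c(1, 2, 3, 4, 5)))$per_subject$sd  # sqrt(2)
#' @export
repeatability <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  ks <- lengths(replicates)
  if (any(ks < 2))
    stop("every subject needs at least 2 replicates; subject(s) ",
         paste(which(ks < 2), collapse = ", "), " have fewer")
  ids <- names(replicates) %||% as.character(seq_along(replicates))
  mu <- vapply(replicates, function(x) sum(x) / length(x), 0)
  sds <- vapply(seq_along(replicates), function(i) {
    x <- replicates[[i]]
    sqrt(sum((x - mu[i])^2) / length(x))
  }, 0)
  structure(
    list(per_subject = data.frame(subject = ids, k = as.integer(ks),
                                  mean = unname(mu), sd = unname(sds),
                                  stringsAsFactors = FALSE),
         pooled_sd = sqrt(mean(sds^2)), k = as.integer(ks)),
    class = "hemospec_repeatability")
}

#' @export
print.hemospec_repeatability <- function(x, ...) {
  cat(sprintf("Repeatability: %d subject(s), pooled SD = %.4f\n",
              nrow(x$per_subject), x$pooled_sd))
  invisible(x)
}

#' Diagnostic-test sample size (Buderer form)
#'
#' Minimum subject counts to estimate a diagnostic sensitivity and
#' specificity to a given confidence half-width at a given disease
#' prevalence:
#' \deqn{n_{SN} = \lceil z^2\, SN(1-SN) / (W^2 P) \rceil, \qquad
#'       n_{SP} = \lceil z^2\, SP(1-SP) / (W^2 (1-P)) \rceil.}
#'
#' With the planning inputs used for the device study (lowest expected
#' sensitivity 95%, specificity 80%, half-width 5%, prevalence 15%,
#' z = 1.96) this yields 487 and 290 subjects.
#'
#' @param sensitivity expected sensitivity SN, fraction in (0, 1).
#' @param specificity expected specificity SP, fraction in (0, 1).
#' @param width confidence-interval half-width W, fraction in (0, 1).
#' @param prevalence disease prevalence P, fraction in (0, 1) exclusive.
#' @param z standard-normal quantile (default 1.96 for 95% confidence).
#' @return list with integer `n_sensitivity` and `n_specificity`.
#' @examples
#' sampleSize(0.95, 0.80, width = 0.05, prevalence = 0.15)
#' @export
sampleSize <- function(sensitivity, specificity, width = 0.05,
                       prevalence = 0.15, z = 1.96) {
  for (v in c(sensitivity, specificity, width))
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop("sensitivity, specificity and width must be fractions in (0, 1)")
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly between 0 and 1")
  if (z <= 0) stop("z must be positive")
  n_sn <- ceiling(z^2 * sensitivity * (1 - sensitivity) /
                    (width^2 * prevalence))
  n_sp <- ceiling(z^2 * specificity * (1 - specificity) /
                    (width^2 * (1 - prevalence)))
  list(n_sensitivity = as.integer(n_sn), n_specificity = as.integer(n_sp))
}
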