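# Morphometry summaries: box statistics with 1.5 * IQR fences and
# log-normal length-distribution fitting.

#' Box summary of a sample
#'
#' Quartiles by linear interpolation between order statistics
#' (`quantile()` type 7; the convention is recorded in the output).
#' Fences sit at `q1 - 1.5 * IQR` and `q3 + 1.5 * IQR`; the whiskers are
#' the extreme data values inside the fences, and every value outside
#' them is reported individually as an outlier.
#'
#' @param values non-empty numeric vector.
#' @return An object of class `ab_box_summary` with fields `n`, `median`,
#'   `q1`, `q3`, `whisker_lo`, `whisker_hi`, `outliers`, and
#'   `quartile_convention`.
#' @export
box_summary <- function(values) {
  if (length(values) == 0L || anyNA(values))
    stop("values must be non-empty with no NA")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  fence_lo <- q[1] - 1.5 * iqr
  fence_hi <- q[3] + 1.5 * iqr
  inside <- values[values >= fence_lo & values <= fence_hi]
  structure(list(
    n = length(values), median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(inside), whisker_hi = max(inside),
    outliers = sort(values[values < fence_lo | values > fence_hi]),
    quartile_convention = "linear interpolation (type 7)"
  ), class = "ab_box_summary")
}

#' @export
print.ab_box_summary <- function(x, ...) {
  cat(sprintf(
    "<ab_box_summary> n=%d median=%.3g [q1=%.3g, q3=%.3g] whiskers [%.3g, %.3g], %d outlier(s)\n",
    x$n, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi,
    length(x$outliers)))
  invisible(x)
}

#' Maximum-likelihood log-normal fit
#'
#' Closed-form MLE on the log scale: `mu_log` is the mean of the logs and
#' `sigma_log` the maximum-likelihood standard deviation (divisor n).
#' Goodness of fit is reported as the Kolmogorov-Smirnov distance between
#' the empirical distribution and the fitted log-normal, without a
#' p-value.
#'
#' @param values strictly positive numeric vector, length >= 2.
#' @return An object of class `ab_lognormal_fit` with fields `mu_log`,
#'   `sigma_log`, `n`, `gof_ks`.
#' @export
fit_lognormal <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to fit sigma")
  if (anyNA(values) || any(values <= 0))
    stop("all values must be strictly positive")
  lx <- log(values)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  ks <- if (sigma > 0)
    suppressWarnings(
      unname(ks.test(values, plnorm, meanlog = mu,
                     sdlog = sigma)$statistic))
  else 1 - 1 / length(values)  # degenerate fit: D against a point mass
  structure(list(mu_log = mu, sigma_log = sigma, n = length(values),
                 gof_ks = ks),
            class = "ab_lognormal_fit")
}

#' @export
print.ab_lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<ab_lognormal_fit> n=%d mu_log=%.4f sigma_log=%.4f (KS distance %.4f)\n",
    x$n, x$mu_log, x$sigma_log, x$gof_ks))
  invisible(x)
}

#' Per-sample morphometry report
#'
#' Arithmetic means of the accepted objects' length, width and voxel
#' volume, box summaries of length and width, and the log-normal length
#' fit.
#'
#' @param ab_table an `ab_table` from [detect_ab()] with at least one
#'   accepted object.
#' @return A list with `n`, `mean_length_um`, `mean_width_um`,
#'   `mean_volume_um3`, `length_box`, `width_box`, `length_fit` (`NULL`
#'   when fewer than 2 objects).
#' @export
morphometry_report <- function(ab_table) {
  stopifnot(inherits(ab_table, "ab_table"))
  acc <- ab_table$accepted
  if (nrow(acc) == 0L) stop("no accepted objects to summarize")
  list(
    n = nrow(acc),
    mean_length_um = mean(acc$length_um),
    mean_width_um = mean(acc$width_um),
    mean_volume_um3 = mean(acc$volume_um3),
    length_box = box_summary(acc$length_um),
    width_box = box_summary(acc$width_um),
    length_fit = if (nrow(acc) >= 2L) fit_lognormal(acc$length_um)
                 else NULL
  )
}
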