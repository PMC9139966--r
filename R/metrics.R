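#' Positivity cut-off from unstimulated controls
#'
#' The empirical quantile (linear interpolation between order statistics,
#' [stats::quantile()] type 7) of the control intensity distribution,
#' defining the threshold above which a cell counts as reporter-positive.
#'
#' @param control_intensities Unstimulated control intensities (>= 20
#'   values).
#' @param quantile Quantile level.
#' @return Cut-off intensity.
#' @export
positivity_cutoff <- function(control_intensities, quantile = 0.995) {
  if (length(control_intensities) < 20L) {
    stop("invalid input: need at least 20 control values", call. = FALSE)
  }
  unname(stats::quantile(control_intensities, probs = quantile, type = 7,
                         names = FALSE))
}

#' Percentage of positive cells
#'
#' @param intensities Measured intensities.
#' @param cutoff Positivity cut-off (finite).
#' @return `100 * #{x > cutoff} / n`.
#' @export
percent_positive <- function(intensities, cutoff) {
  if (length(intensities) == 0L) {
    stop("invalid input: no intensities supplied", call. = FALSE)
  }
  if (!is.finite(cutoff)) {
    stop("invalid input: cutoff must be finite", call. = FALSE)
  }
  100 * sum(intensities > cutoff) / length(intensities)
}

#' Area under a time course
#'
#' Trapezoidal integral of a summary statistic over the observed time span.
#'
#' @param t Time points (h), strictly increasing, >= 2 points.
#' @param value Statistic per time point (finite).
#' @return Area in value-units x h.
#' @export
auc <- function(t, value) {
  if (length(t) < 2L || length(t) != length(value)) {
    stop("invalid input: need >= 2 matched (t, value) points",
         call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("invalid input: t must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(value))) {
    stop("invalid input: values must be finite", call. = FALSE)
  }
  sum(diff(t) * (utils::head(value, -1) + utils::tail(value, -1)) / 2)
}

#' Signal over background
#'
#' Mean stimulated intensity divided by the mean of unstimulated controls.
#'
#' @param stim_mean Mean intensity under stimulation.
#' @param ctrl_mean Mean intensity of unstimulated controls (> 0).
#' @return Ratio.
#' @export
signal_over_background <- function(stim_mean, ctrl_mean) {
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop("invalid input: ctrl_mean must be > 0", call. = FALSE)
  }
  stim_mean / ctrl_mean
}

#' Z-prime screening-assay quality factor
#'
#' The standard Z' factor
#' `1 - 3 (sd_pos + sd_neg) / |avg_pos - avg_neg|` (sample SDs, n - 1
#' denominator), with the group moments and signal-over-background
#' returned alongside.  Z' > 0.5 together with s/b > 2 is the usual bar
#' for an excellent screening assay.  Z' is invariant under positive
#' affine transforms applied to both groups.
#'
#' @param pos_values Positive-control (stimulated) readouts, >= 2 values.
#' @param neg_values Negative-control (unstimulated) readouts, >= 2
#'   values.
#' @return An object of class `screen_stats`: list with `avg_pos`,
#'   `avg_neg`, `sd_pos`, `sd_neg`, `s_over_b` (`NA` when `avg_neg <= 0`),
#'   `z_prime`.
#' @export
z_prime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L) {
    stop("invalid input: need >= 2 values per group", call. = FALSE)
  }
  avg_pos <- mean(pos_values)
  avg_neg <- mean(neg_values)
  if (avg_pos == avg_neg) {
    stop("degenerate separation: group means are equal", call. = FALSE)
  }
  sd_pos <- stats::sd(pos_values)
  sd_neg <- stats::sd(neg_values)
  structure(list(
    avg_pos = avg_pos, avg_neg = avg_neg,
    sd_pos = sd_pos, sd_neg = sd_neg,
    s_over_b = if (avg_neg > 0) avg_pos / avg_neg else NA_real_,
    z_prime = 1 - 3 * (sd_pos + sd_neg) / abs(avg_pos - avg_neg)),
    class = "screen_stats")
}

#' @export
print.screen_stats <- function(x, ...) {
  cat(sprintf(
    "screen stats: avg+ %.4g (sd %.3g), avg- %.4g (sd %.3g), s/b %.3g, Z' %.3f\n",
    x$avg_pos, x$sd_pos, x$avg_neg, x$sd_neg, x$s_over_b, x$z_prime))
  invisible(x)
}

#' Confluency-corrected field intensity
#'
#' Total field fluorescence divided by the number of cells in the field, a
#' per-cell intensity that stands in for instrument-side confluency
#' normalisation.
#'
#' @param total_intensity Summed field fluorescence.
#' @param n_cells Cell count in the field (> 0).
#' @return Corrected intensity per cell.
#' @export
confluency_correct <- function(total_intensity, n_cells) {
  if (n_cells <= 0) stop("invalid input: n_cells must be > 0",
                         call. = FALSE)
  total_intensity / n_cells
}
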