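#' Summarise a duration series: central tendency and variability
#'
#' Computes the median, interquartile range, range, and the Poincaré-plot
#' variability indices of a series of phase or cycle durations. In the
#' Poincaré (lag-1 return) plot of \eqn{(x_i, x_{i+1})}, SD1 is the
#' dispersion perpendicular to the identity line (short-term,
#' cycle-to-cycle variability) and SD2 the dispersion along it (long-term
#' variability):
#' \deqn{SD1 = \sqrt{\mathrm{Var}(x_{i+1} - x_i) / 2}, \quad
#'       SD2 = \sqrt{\max(0,\; 2\,\mathrm{Var}(x) - SD1^2)}.}
#' Sample (n-1) variance is used throughout; with only 17 cycles per trial
#' the denominator convention is material, so it is fixed here. For
#' strongly anti-correlated short series \eqn{2\mathrm{Var}(x) - SD1^2} can
#' go negative; it is clamped to zero and flagged (`sd2_clamped`) rather
#' than returned as NaN.
#'
#' @param x numeric vector of at least 2 finite values (same units
#'   throughout; typically seconds or % of cycle).
#' @return A `pb_summary` list: `median`, `iqr` (75th - 25th percentile),
#'   `range` (max - min), `sd1`, `sd2`, `n`, `sd2_clamped`. `sd1`/`sd2` are
#'   `NA` for `n = 2` (a single successive difference has no variance).
#' @export
#' @examples
#' summarize_durations(c(1, 2, 3, 4, 5))  # sd1 = 0, sd2 = sqrt(5)
summarize_durations <- function(x) {
  check_finite_numeric(x, "x")
  n <- length(x)
  if (n < 2L) abort_pb("need at least 2 values", "pb_input_error")
  sd1 <- sd2 <- NA_real_
  clamped <- FALSE
  if (n >= 3L) {
    sd1 <- sqrt(stats::var(diff(x)) / 2)
    sd2sq <- 2 * stats::var(x) - sd1^2
    clamped <- sd2sq < 0
    sd2 <- sqrt(max(0, sd2sq))
  }
  structure(list(median = stats::median(x),
                 iqr = percentile(x, 75) - percentile(x, 25),
                 range = max(x) - min(x),
                 sd1 = sd1, sd2 = sd2, n = n, sd2_clamped = clamped),
            class = "pb_summary")
}

#' @export
print.pb_summary <- function(x, ...) {
  cat(sprintf(
    "<pb_summary> n=%d median=%.4g iqr=%.4g range=%.4g sd1=%.4g sd2=%.4g%s\n",
    x$n, x$median, x$iqr, x$range, x$sd1, x$sd2,
    if (isTRUE(x$sd2_clamped)) " (clamped)" else ""))
  invisible(x)
}

#' Linear-interpolation percentile
#'
#' Percentiles use linear interpolation between closest order statistics
#' (the convention of [stats::quantile()] type 7), fixed here so that
#' percentile-style outputs are reproducible bit-for-bit.
#'
#' @param x numeric vector, at least one finite value.
#' @param q percentile in \[0, 100\].
#' @return The interpolated percentile value.
#' @export
#' @examples
#' percentile(c(1, 2, 3, 4), 50)  # 2.5
percentile <- function(x, q) {
  check_finite_numeric(x, "x")
  if (!length(x)) abort_pb("empty series", "pb_input_error")
  if (any(q < 0 | q > 100)) abort_pb("`q` must lie in [0, 100]", "pb_parameter_error")
  stats::quantile(x, q / 100, names = FALSE, type = 7)
}

#' Per-trial variability summaries from a phase table
#'
#' Convenience wrapper producing [summarize_durations()] for selected
#' columns of a [phase_table()] (by default Cycle duration in seconds and
#' Placing expressed as % of its cycle, the two measures that pass the
#' video-agreement reliability gate).
#'
#' @param tab a [phase_table()] data frame.
#' @param variables column names to summarise.
#' @return Named list of `pb_summary` objects.
#' @export
summarize_trial <- function(tab, variables = c("cycle_s", "placing_pct")) {
  missing_cols <- setdiff(variables, names(tab))
  if (length(missing_cols)) {
    abort_pb(paste0("unknown phase-table column(s): ",
                    paste(missing_cols, collapse = ", ")), "pb_input_error")
  }
  stats::setNames(lapply(variables, function(v) summarize_durations(tab[[v]])),
                  variables)
}
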