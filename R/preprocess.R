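#' Build the scalar target signal from a recording
#'
#' The target variable for event detection is the algebraic sum of the
#' angular-velocity components around the longitudinal and antero-posterior
#' axes; summing (rather than taking a norm) retains peak signs, which
#' discriminate bricks-to-board flights (positive) from board-to-bricks
#' flights (negative). The medio-lateral axis is not used.
#'
#' @param rec a [pb_recording()].
#' @return A `pb_target` object: list with `values` (deg/s), `sample_rate`,
#'   `filtered` and `sign_flipped` flags.
#' @export
compute_target <- function(rec) {
  stopifnot(inherits(rec, "pb_recording"))
  new_target(rec$omega_l + rec$omega_ap, rec$sample_rate,
             filtered = FALSE, sign_flipped = FALSE)
}

new_target <- function(values, sample_rate, filtered, sign_flipped) {
  structure(list(values = as.numeric(values), sample_rate = sample_rate,
                 filtered = filtered, sign_flipped = sign_flipped),
            class = "pb_target")
}

#' @export
print.pb_target <- function(x, ...) {
  cat(sprintf("<pb_target> %d samples at %g Hz, %sfiltered%s\n",
              length(x$values), x$sample_rate,
              if (x$filtered) "" else "un",
              if (x$sign_flipped) ", sign-flipped" else ""))
  invisible(x)
}

# Direct-form II transposed IIR filter. `zi` is the initial state vector
# (length max(length(a), length(b)) - 1); a[1] must be 1.
filter_df2t <- function(b, a, x, zi = NULL) {
  m <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  z <- if (is.null(zi)) rep(0, m) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 1L) {
      z[1:(m - 1L)] <- b[2:m] * xi + z[2:m] - a[2:m] * yi
    }
    z[m] <- b[m + 1L] * xi - a[m + 1L] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-step input (so that filtering a
# constant c with state c * zi yields exactly c when the DC gain is 1).
filter_zi <- function(b, a) {
  m <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  g <- sum(b) / sum(a)  # DC gain (1 for a Butterworth low-pass)
  zi <- numeric(m)
  zi[1] <- g - b[1]
  if (m > 1L) {
    for (k in 2:m) zi[k] <- zi[k - 1L] - b[k] + a[k] * g
  }
  zi
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters the target signal forward and backward with a Butterworth
#' low-pass design (default 4th order, 6 Hz cut-off), giving zero phase
#' distortion and an effective magnitude response
#' \eqn{|H(f)|^2 = (1 + (f/f_c)^{2n})^{-1}}. Zero phase matters here:
#' a causal filter would delay every detected event by tens of
#' milliseconds. Edges are handled by odd-reflection padding of
#' `3 * order` samples with steady-state initial conditions, so a constant
#' signal passes through exactly (unit DC gain).
#'
#' @param ts a `pb_target` from [compute_target()].
#' @param cutoff cut-off frequency in Hz (default 6); must be below the
#'   Nyquist frequency.
#' @param order filter order (default 4).
#' @return A `pb_target` with `filtered = TRUE`, same length as the input.
#' @export
lowpass <- function(ts, cutoff = 6, order = 4) {
  stopifnot(inherits(ts, "pb_target"))
  fs <- ts$sample_rate
  if (cutoff >= fs / 2) {
    abort_pb("`cutoff` must be below the Nyquist frequency", "pb_parameter_error")
  }
  if (cutoff <= 0 || order < 1) {
    abort_pb("`cutoff` and `order` must be positive", "pb_parameter_error")
  }
  x <- ts$values
  npad <- 3L * as.integer(order)
  if (length(x) <= 3L * order) {
    abort_pb("signal too short to filter (need length > 3 * order)",
             "pb_input_error")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  b <- bf$b
  a <- bf$a
  zi <- filter_zi(b, a)
  n <- length(x)
  # odd (point-symmetric) reflection about both end samples
  xp <- c(2 * x[1] - x[(npad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- filter_df2t(b, a, xp, zi * xp[1])
  y <- rev(filter_df2t(b, a, rev(y), zi * y[length(y)]))
  new_target(y[(npad + 1L):(npad + n)], fs,
             filtered = TRUE, sign_flipped = ts$sign_flipped)
}

#' Orient the sign of the target signal
#'
#' The detection convention is bricks-to-board flights positive and
#' board-to-bricks flights negative; the raw sign depends on which wrist
#' wore the sensor. Orientation is decided from the signal itself by a
#' timing asymmetry of the task: the interval following a bricks-to-board
#' peak contains the Placing phase (the longest contact phase), while the
#' interval following a board-to-bricks peak contains the much shorter
#' Grasping phase. The signal is flipped when the median gap after positive
#' peaks is shorter than after negative peaks. When too few peaks are
#' available to estimate the gaps (fewer than one gap per sign), the sign of
#' the first prominent peak is used instead (the first flight of the task
#' proper carries a brick to the board, hence is positive).
#'
#' @param ts a filtered `pb_target`.
#' @param params a [detection_params()] list; peak prominence and
#'   separation settings are reused for the internal peak scan.
#' @return A `pb_target` with `sign_flipped` recording whether the signal
#'   was negated.
#' @export
orient_sign <- function(ts, params = detection_params()) {
  stopifnot(inherits(ts, "pb_target"))
  pk <- find_signed_peaks(ts$values, ts$sample_rate, params)
  if (nrow(pk) == 0L) {
    abort_pb("no prominent peak found; cannot orient signal", "pb_detection_error")
  }
  # use the same alternation-pruned peak model as the flight-peak detector,
  # so secondary same-sign peaks (e.g. placement adjustments) do not bias
  # the gap statistics
  pk <- prune_alternation(pk)
  flip <- FALSE
  gaps <- diff(pk$time)
  after_pos <- gaps[pk$amplitude[-nrow(pk)] > 0]
  after_neg <- gaps[pk$amplitude[-nrow(pk)] < 0]
  if (length(after_pos) >= 1L && length(after_neg) >= 1L) {
    flip <- stats::median(after_pos) < stats::median(after_neg)
  } else {
    flip <- pk$amplitude[1] < 0
  }
  if (flip) {
    new_target(-ts$values, ts$sample_rate, filtered = ts$filtered,
               sign_flipped = !ts$sign_flipped)
  } else {
    ts
  }
}
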