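#' Detection parameters
#'
#' Peak-picking thresholds are relative to the trial's own amplitude scale,
#' so detection is invariant to multiplying the signal by any positive
#' constant (units and sensor gain do not matter).
#'
#' @param min_peak_separation minimum separation in seconds between two
#'   detected peaks of the same sign (default 0.3; true flight peaks are
#'   farther apart, given median flight durations around 0.37-0.49 s plus
#'   the intervening contact phase).
#' @param prominence_fraction peak amplitude threshold as a fraction of the
#'   90th percentile of the absolute filtered signal (default 0.2).
#' @param valley_floor_fraction a candidate event minimum must fall below
#'   this fraction of the adjacent peak's absolute amplitude (default 0.5);
#'   otherwise the valley's global minimum is used.
#' @return A list of class `pb_detection_params`.
#' @export
detection_params <- function(min_peak_separation = 0.3,
                             prominence_fraction = 0.2,
                             valley_floor_fraction = 0.5) {
  if (min_peak_separation <= 0) {
    abort_pb("`min_peak_separation` must be positive", "pb_parameter_error")
  }
  if (prominence_fraction <= 0 || prominence_fraction >= 1 ||
      valley_floor_fraction <= 0 || valley_floor_fraction >= 1) {
    abort_pb("fractions must lie in (0, 1)", "pb_parameter_error")
  }
  structure(list(min_peak_separation = min_peak_separation,
                 prominence_fraction = prominence_fraction,
                 valley_floor_fraction = valley_floor_fraction),
            class = "pb_detection_params")
}

# indices of local maxima of v (plateaus contribute their midpoint)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  d <- diff(v)
  # collapse flat runs: sign of the last non-zero slope before / first after
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer())
  # forward-fill zero slopes with the preceding non-zero slope
  s_ff <- s
  for (i in seq_len(n - 1L)[-1]) if (s_ff[i] == 0) s_ff[i] <- s_ff[i - 1L]
  idx <- which(s_ff[-length(s_ff)] > 0 & s[-1] < 0) + 1L
  idx
}

# Find prominent signed peaks: local extrema of the signal whose absolute
# amplitude exceeds prominence_fraction * 90th percentile of |v|, with
# same-sign peaks at least min_peak_separation apart (larger amplitude wins).
find_signed_peaks <- function(v, fs, params) {
  thr <- params$prominence_fraction *
    stats::quantile(abs(v), 0.9, names = FALSE, type = 7)
  if (thr <= 0) return(data.frame(index = integer(), time = numeric(),
                                  amplitude = numeric()))
  min_gap <- params$min_peak_separation * fs
  pick <- function(x) {  # maxima of x above thr, pruned by min_gap
    idx <- local_maxima(x)
    idx <- idx[x[idx] >= thr]
    if (length(idx) < 2L) return(idx)
    keep <- logical(length(idx))
    for (j in order(x[idx], decreasing = TRUE)) {
      if (!any(keep & abs(idx - idx[j]) < min_gap)) keep[j] <- TRUE
    }
    sort(idx[keep])
  }
  pos <- pick(v)
  neg <- pick(-v)
  idx <- sort(c(pos, neg))
  data.frame(index = idx, time = (idx - 1) / fs, amplitude = v[idx])
}

# Enforce sign alternation on a signed-peak table: among consecutive
# same-sign peaks keep the largest (small secondary same-sign peaks
# typically reflect placement-adjustment movements, not separate flights).
prune_alternation <- function(pk) {
  if (nrow(pk) < 2L) return(pk)
  keep <- rep(TRUE, nrow(pk))
  sgn <- sign(pk$amplitude)
  run_start <- 1L
  for (i in seq_len(nrow(pk))[-1]) {
    if (sgn[i] != sgn[run_start]) {
      run_start <- i
    } else {
      if (abs(pk$amplitude[i]) > abs(pk$amplitude[run_start])) {
        keep[run_start] <- FALSE
        run_start <- i
      } else {
        keep[i] <- FALSE
      }
    }
  }
  out <- pk[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect flight-phase peaks on the filtered target signal
#'
#' Flight phases (hand transport between brick pile and board) appear as
#' prominent absolute peaks of the filtered target signal: positive for
#' bricks-to-board, negative for board-to-bricks. The returned peaks
#' alternate in sign; when two same-sign peaks are adjacent in the raw
#' pick, only the larger is kept (small secondary peaks typically reflect
#' placement-adjustment movements, not separate flights).
#'
#' @param ts a filtered, sign-oriented `pb_target`.
#' @param params a [detection_params()] list.
#' @return Data frame of class `pb_peaks`: columns `index` (sample),
#'   `time` (s), `amplitude` (deg/s, signed) and `direction`
#'   (`"bricks_to_board"` / `"board_to_bricks"`).
#' @export
detect_flight_peaks <- function(ts, params = detection_params()) {
  stopifnot(inherits(ts, "pb_target"))
  pk <- find_signed_peaks(ts$values, ts$sample_rate, params)
  if (nrow(pk) == 0L) {
    abort_pb("no peaks above the prominence threshold", "pb_detection_error")
  }
  pk <- prune_alternation(pk)
  pk$direction <- ifelse(pk$amplitude > 0, "bricks_to_board", "board_to_bricks")
  class(pk) <- c("pb_peaks", "data.frame")
  pk
}

# Nearest qualifying |v| minimum to a peak within a valley.
# side = -1 searches (from_idx .. peak), side = +1 searches (peak .. to_idx);
# returns the sample index of the first local minimum of |v| (scanning away
# from the peak) whose value is below `floor`, else the valley's global
# minimum (ties broken toward the peak).
valley_event_index <- function(absv, peak_idx, bound_idx, side, floor) {
  rng <- if (side < 0) {
    if (bound_idx > peak_idx - 1L) integer(0) else (peak_idx - 1L):bound_idx
  } else {
    if (bound_idx < peak_idx + 1L) integer(0) else (peak_idx + 1L):bound_idx
  }
  rng <- rng[rng >= 1L & rng <= length(absv)]
  if (length(rng) == 0L) return(peak_idx)
  if (length(rng) == 1L) return(rng[1])
  a <- absv[rng]
  n <- length(a)
  # weak local minima within the valley (endpoints count)
  is_min <- c(a[1] <= a[2],
              if (n > 2L) a[2:(n - 1L)] <= a[1:(n - 2L)] & a[2:(n - 1L)] <= a[3:n],
              a[n] <= a[n - 1L])
  cand <- which(is_min & a < floor)
  if (length(cand)) return(rng[cand[1]])  # rng is ordered away from the peak
  rng[which.min(a)]
}

#' Locate the four task events around detected flight peaks
#'
#' For each positive (bricks-to-board) peak, the nearest local minimum of
#' the absolute signal before the peak marks Grasping End and the nearest
#' after it marks Initial Placing; for each negative (board-to-bricks)
#' peak, Placing End before and Initial Grasping after. Minima are sought
#' between the peak and its neighbouring peak (or the signal edge) and must
#' fall below `valley_floor_fraction` times the adjacent peak's absolute
#' amplitude, else the valley's global minimum is used. "Minima" are minima
#' of the absolute signal, i.e. near-stationary wrist instants between
#' movements (a signed minimum before a positive peak would be the previous
#' negative flight peak itself).
#'
#' With `trim = TRUE` (default) the sequence is cut to the task proper:
#' events before the first Initial Grasping (the initial reach from rest to
#' the brick pile) and after the last Placing End (the final return to rest)
#' are dropped.
#'
#' @param ts a filtered, sign-oriented `pb_target`.
#' @param peaks output of [detect_flight_peaks()].
#' @param params a [detection_params()] list.
#' @param trim drop events outside \[first Initial Grasping, last Placing End\].
#' @param strict error (rather than warn) when the resulting sequence
#'   breaks the event grammar.
#' @return A [pb_events()] sequence with `source = "algorithm"`.
#' @export
locate_events <- function(ts, peaks, params = detection_params(),
                          trim = TRUE, strict = FALSE) {
  stopifnot(inherits(ts, "pb_target"))
  if (nrow(peaks) == 0L) abort_pb("no peaks supplied", "pb_detection_error")
  absv <- abs(ts$values)
  fs <- ts$sample_rate
  n <- length(absv)
  kind <- character(0)
  idx <- integer(0)
  for (j in seq_len(nrow(peaks))) {
    p <- peaks$index[j]
    floor_j <- params$valley_floor_fraction * abs(peaks$amplitude[j])
    lo <- if (j > 1L) peaks$index[j - 1L] + 1L else 1L
    hi <- if (j < nrow(peaks)) peaks$index[j + 1L] - 1L else n
    before <- valley_event_index(absv, p, lo, -1L, floor_j)
    after <- valley_event_index(absv, p, hi, +1L, floor_j)
    if (peaks$amplitude[j] > 0) {
      kind <- c(kind, "GraspingEnd", "InitialPlacing")
    } else {
      kind <- c(kind, "PlacingEnd", "InitialGrasping")
    }
    idx <- c(idx, before, after)
  }
  time <- (idx - 1) / fs
  if (trim) {
    first_ig <- match("InitialGrasping", kind)
    last_pe <- length(kind) + 1L - match("PlacingEnd", rev(kind))
    if (is.na(first_ig) || is.na(last_pe) || first_ig > last_pe) {
      abort_pb("no complete task span (Initial Grasping ... Placing End) detected",
               "pb_detection_error")
    }
    keep <- seq(first_ig, last_pe)
    kind <- kind[keep]
    time <- time[keep]
  }
  ev <- withCallingHandlers(
    pb_events(kind, time, source = "algorithm", warn_grammar = !strict),
    warning = function(w) {
      if (grepl("not in time order", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  viol <- attr(ev, "grammar_violations")
  if (strict && nrow(viol)) {
    abort_pb(paste0("detected events break the task grammar at position(s) ",
                    paste(viol$position, collapse = ", ")),
             "pb_detection_error")
  }
  ev
}

#' Detect task events from a recording (full pipeline)
#'
#' Composition of [compute_target()], [lowpass()], [orient_sign()],
#' [detect_flight_peaks()] and [locate_events()]. Deterministic for a fixed
#' recording and parameter set.
#'
#' @param rec a [pb_recording()].
#' @param params a [detection_params()] list.
#' @param cutoff,order low-pass filter settings, see [lowpass()].
#' @param orient apply automatic sign orientation (default `TRUE`).
#' @inheritParams locate_events
#' @return A [pb_events()] sequence with `source = "algorithm"`.
#' @export
#' @examples
#' tr <- simulate_trial(trial_spec(n_bricks = 3, noise_sd = 0, seed = 1))
#' ev <- detect_events(tr$recording)
#' table(ev$kind)
detect_events <- function(rec, params = detection_params(), cutoff = 6,
                          order = 4, orient = TRUE, trim = TRUE,
                          strict = FALSE) {
  ts <- lowpass(compute_target(rec), cutoff = cutoff, order = order)
  if (orient) ts <- orient_sign(ts, params)
  peaks <- detect_flight_peaks(ts, params)
  locate_events(ts, peaks, params, trim = trim, strict = strict)
}
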