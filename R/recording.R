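#' Construct a wrist angular-velocity recording
#'
#' Container for one trial's tri-axial wrist gyroscope series. Axes follow
#' the anatomical convention: longitudinal (L), medio-lateral (ML) and
#' antero-posterior (AP). Samples are uniform; the time of sample `i`
#' (1-based) is `(i - 1) / sample_rate` seconds from recording start.
#'
#' @param omega_l,omega_ml,omega_ap numeric vectors of equal length (>= 2),
#'   angular velocity in deg/s around the L, ML and AP axes.
#' @param sample_rate sampling frequency in Hz (positive; nominally 128).
#' @param hand_side `"left"` or `"right"`: which wrist wore the sensor.
#' @param hand_role `"dominant"`, `"non_dominant"` or `NA`.
#' @param trial_id optional opaque label.
#'
#' @return An object of class `pb_recording`.
#' @export
#' @examples
#' rec <- pb_recording(sin(1:100), rnorm(100, sd = 0.1), cos(1:100), 128)
#' rec$sample_rate
pb_recording <- function(omega_l, omega_ml, omega_ap, sample_rate,
                         hand_side = "right", hand_role = NA_character_,
                         trial_id = NULL) {
  check_finite_numeric(omega_l, "omega_l")
  check_finite_numeric(omega_ml, "omega_ml")
  check_finite_numeric(omega_ap, "omega_ap")
  n <- length(omega_l)
  if (n < 2L) abort_pb("a recording needs at least 2 samples", "pb_input_error")
  if (length(omega_ml) != n || length(omega_ap) != n) {
    abort_pb("axis series must have identical length", "pb_input_error")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    abort_pb("`sample_rate` must be a positive number", "pb_parameter_error")
  }
  hand_side <- match.arg(hand_side, c("right", "left"))
  if (!is.na(hand_role)) {
    hand_role <- match.arg(hand_role, c("dominant", "non_dominant"))
  }
  structure(
    list(omega_l = as.numeric(omega_l), omega_ml = as.numeric(omega_ml),
         omega_ap = as.numeric(omega_ap), sample_rate = as.numeric(sample_rate),
         hand_side = hand_side, hand_role = hand_role,
         trial_id = trial_id),
    class = "pb_recording"
  )
}

#' @export
print.pb_recording <- function(x, ...) {
  n <- length(x$omega_l)
  cat(sprintf(
    "<pb_recording> %s%d samples at %g Hz (%.2f s), %s wrist%s\n",
    if (is.null(x$trial_id)) "" else paste0(x$trial_id, ": "),
    n, x$sample_rate, n / x$sample_rate, x$hand_side,
    if (is.na(x$hand_role)) "" else paste0(" (", x$hand_role, ")")
  ))
  invisible(x)
}

#' Sample times of a recording
#'
#' @param rec a [pb_recording()].
#' @return Numeric vector of times in seconds from recording start.
#' @export
recording_times <- function(rec) {
  stopifnot(inherits(rec, "pb_recording"))
  (seq_along(rec$omega_l) - 1) / rec$sample_rate
}

#' Read a recording from a delimited text file
#'
#' Expects a CSV with a header naming columns `gyro_l`, `gyro_ml`, `gyro_ap`
#' and optionally `time_s`. If `time_s` is present, the sampling rate is
#' inferred from the median step and sampling is required to be uniform
#' within 1% relative jitter; otherwise `sample_rate` must be supplied.
#'
#' @param path file path.
#' @param sample_rate sampling rate in Hz; ignored when the file has a
#'   `time_s` column.
#' @inheritParams pb_recording
#' @return A [pb_recording()].
#' @export
read_recording <- function(path, sample_rate = NULL, hand_side = "right",
                           hand_role = NA_character_, trial_id = NULL) {
  if (!file.exists(path)) abort_pb(paste0("no such file: ", path), "pb_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gyro_l", "gyro_ml", "gyro_ap")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_pb(paste0("missing required columns: ",
                    paste(missing_cols, collapse = ", ")), "pb_format_error")
  }
  if (nrow(df) < 2L) abort_pb("fewer than 2 samples", "pb_input_error")
  if ("time_s" %in% names(df)) {
    dt <- diff(df$time_s)
    if (any(dt <= 0)) abort_pb("time_s must be strictly increasing", "pb_sampling_error")
    step <- stats::median(dt)
    if (any(abs(dt - step) > 0.01 * step)) {
      abort_pb("non-uniform sampling: time steps deviate by more than 1%",
               "pb_sampling_error")
    }
    sample_rate <- 1 / step
  } else if (is.null(sample_rate)) {
    abort_pb("file has no time_s column and no `sample_rate` was given",
             "pb_parameter_error")
  }
  pb_recording(df$gyro_l, df$gyro_ml, df$gyro_ap, sample_rate,
               hand_side = hand_side, hand_role = hand_role,
               trial_id = trial_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a recording to a delimited text file
#'
#' Writes columns `time_s`, `gyro_l`, `gyro_ml`, `gyro_ap` as CSV.
#'
#' @param rec a [pb_recording()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pb_recording"))
  df <- data.frame(time_s = recording_times(rec), gyro_l = rec$omega_l,
                   gyro_ml = rec$omega_ml, gyro_ap = rec$omega_ap)
  tryCatch(utils::write.csv(df, path, row.names = FALSE),
           error = function(e) abort_pb(conditionMessage(e), "pb_io_error"))
  invisible(path)
}
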