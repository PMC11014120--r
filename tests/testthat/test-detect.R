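# A hand-built target with two flights around one contact phase, used to
# check peak picking and valley localisation geometrically.
two_flight_target <- function(fs = 128) {
  gap <- numeric(round(0.5 * fs))
  up <- 100 * sin(pi * (seq_len(round(0.45 * fs)) - 0.5) / round(0.45 * fs))^2
  down <- -up
  v <- c(gap, up, gap, down, gap)
  structure(list(values = v, sample_rate = fs, filtered = TRUE,
                 sign_flipped = FALSE), class = "pb_target")
}

test_that("detection_params validates its arguments", {
  p <- detection_params()
  expect_equal(p$min_peak_separation, 0.3)
  expect_equal(p$prominence_fraction, 0.2)
  expect_equal(p$valley_floor_fraction, 0.5)
  expect_error(detection_params(min_peak_separation = 0),
               class = "pb_parameter_error")
  expect_error(detection_params(prominence_fraction = 1),
               class = "pb_parameter_error")
  expect_error(detection_params(valley_floor_fraction = 0),
               class = "pb_parameter_error")
})

test_that("detect_flight_peaks finds signed alternating peaks", {
  ts <- two_flight_target()
  pk <- detect_flight_peaks(ts)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$direction, c("bricks_to_board", "board_to_bricks"))
  expect_equal(sign(pk$amplitude), c(1, -1))
  # peak times sit mid-pulse
  fs <- 128
  expect_equal(pk$index[1], round(0.5 * fs) + round(0.45 * fs / 2),
               tolerance = 1)
})

test_that("peak detection is invariant to positive rescaling", {
  tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 6))
  ts <- orient_sign(lowpass(compute_target(tr$recording)))
  pk1 <- detect_flight_peaks(ts)
  ts2 <- ts
  ts2$values <- 7.3 * ts$values
  pk2 <- detect_flight_peaks(ts2)
  expect_equal(pk1$index, pk2$index)
  expect_equal(pk2$amplitude, 7.3 * pk1$amplitude, tolerance = 1e-12)
})

test_that("same-sign secondary peaks are pruned to the larger one", {
  fs <- 128
  gap <- numeric(64)
  main <- 100 * sin(pi * (seq_len(58) - 0.5) / 58)^2
  second <- 60 * sin(pi * (seq_len(58) - 0.5) / 58)^2
  down <- -main
  ts <- structure(list(values = c(gap, main, gap, second, gap, down, gap),
                       sample_rate = fs, filtered = TRUE,
                       sign_flipped = FALSE), class = "pb_target")
  pk <- detect_flight_peaks(ts)
  expect_equal(pk$direction, c("bricks_to_board", "board_to_bricks"))
  expect_equal(max(pk$amplitude), 100, tolerance = 0.002)
})

test_that("detect_flight_peaks errors on a flat signal", {
  flat <- structure(list(values = numeric(500), sample_rate = 128,
                         filtered = TRUE, sign_flipped = FALSE),
                    class = "pb_target")
  expect_error(detect_flight_peaks(flat), class = "pb_detection_error")
})

test_that("locate_events reads the correct kinds off peak signs", {
  ts <- two_flight_target()
  pk <- detect_flight_peaks(ts)
  ev <- suppressWarnings(locate_events(ts, pk, trim = FALSE))
  expect_identical(ev$kind, c("GraspingEnd", "InitialPlacing",
                              "PlacingEnd", "InitialGrasping"))
  # the contact phase between the flights spans samples ~122..186
  fs <- 128
  ip <- ev$time[ev$kind == "InitialPlacing"]
  pe <- ev$time[ev$kind == "PlacingEnd"]
  expect_lt(ip, pe)
  expect_equal(pe - ip, 0.5, tolerance = 4 / fs)
})

test_that("trimming cuts the sequence to [first IG, last PE]", {
  tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 7))
  ev <- quiet_detect(tr$recording)
  expect_identical(ev$kind[1], "InitialGrasping")
  expect_identical(ev$kind[nrow(ev)], "PlacingEnd")
  expect_equal(nrow(ev), 72)
  expect_equal(as.integer(table(ev$kind)[event_kinds()]), rep(18L, 4))
})

test_that("detection is deterministic", {
  tr <- simulate_trial(trial_spec(seed = 8))
  e1 <- quiet_detect(tr$recording)
  e2 <- quiet_detect(tr$recording)
  expect_identical(e1$kind, e2$kind)
  expect_identical(e1$time, e2$time)
})

test_that("detection is invariant to sensor gain", {
  tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 9))
  rec <- tr$recording
  rec2 <- pb_recording(5 * rec$omega_l, 5 * rec$omega_ml, 5 * rec$omega_ap,
                       rec$sample_rate)
  e1 <- quiet_detect(rec)
  e2 <- quiet_detect(rec2)
  expect_identical(e1$time, e2$time)
})

test_that("trimming errors when no complete task span exists", {
  # a single positive flight yields only GraspingEnd / InitialPlacing:
  # no Initial Grasping ... Placing End span to trim to
  fs <- 128
  gap <- numeric(64)
  up <- 100 * sin(pi * (seq_len(58) - 0.5) / 58)^2
  ts <- structure(list(values = c(gap, up, gap), sample_rate = fs,
                       filtered = TRUE, sign_flipped = FALSE),
                  class = "pb_target")
  pk <- detect_flight_peaks(ts)
  expect_error(locate_events(ts, pk, trim = TRUE),
               class = "pb_detection_error")
  expect_error(locate_events(ts, pk[0, , drop = FALSE]),
               class = "pb_detection_error")
})

test_that("noise-free detection recovers truth within the sampling limit", {
  err <- detection_errors(simulate_trial(
    trial_spec(noise_sd = 0, residual_fraction = 0, seed = 10)))
  expect_equal(length(err), 72)
  expect_lte(max(abs(err)), 2)
})
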