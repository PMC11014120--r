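test_that("trial_spec validates its parameters", {
  expect_s3_class(trial_spec(), "pb_trial_spec")
  expect_error(trial_spec(n_bricks = 0), class = "pb_parameter_error")
  expect_error(trial_spec(medians = c(grasping = 0.25)),
               class = "pb_parameter_error")
  expect_error(trial_spec(noise_sd = -1), class = "pb_parameter_error")
  expect_error(trial_spec(peak_amplitude = 0), class = "pb_parameter_error")
  expect_error(trial_spec(adjustment_prob = 2), class = "pb_parameter_error")
})

test_that("a trial carries 4 x n_bricks ground-truth events in grammar order", {
  tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 1))
  expect_equal(nrow(tr$truth), 72)
  expect_equal(as.integer(table(tr$truth$kind)[event_kinds()]), rep(18L, 4))
  expect_equal(nrow(check_event_grammar(tr$truth)), 0)
  expect_identical(tr$truth$kind[1], "InitialGrasping")
  expect_identical(tr$truth$kind[72], "PlacingEnd")

  small <- simulate_trial(trial_spec(n_bricks = 3, seed = 2))
  expect_equal(nrow(small$truth), 12)
})

test_that("truth event times lie on the sampling grid", {
  tr <- simulate_trial(trial_spec(seed = 3))
  expect_equal(tr$truth$time * 128, round(tr$truth$time * 128),
               tolerance = 1e-9)
})

test_that("simulation is reproducible by seed and restores the RNG state", {
  a <- simulate_trial(trial_spec(seed = 7))
  b <- simulate_trial(trial_spec(seed = 7))
  expect_identical(a$recording$omega_l, b$recording$omega_l)
  expect_identical(a$truth$time, b$truth$time)
  c1 <- simulate_trial(trial_spec(seed = 8))
  expect_false(identical(a$truth$time, c1$truth$time))

  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(simulate_trial(trial_spec(n_bricks = 2, seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("the L/AP mixing split reconstructs the target exactly", {
  tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 9))
  expect_gt(tr$mixing, 0.2)
  expect_lt(tr$mixing, 0.8)
  target <- tr$recording$omega_l + tr$recording$omega_ap
  # outside flight pulses the target is only the tapered tremor residue
  rest <- seq_len(64)  # first half of the leading rest second
  expect_equal(max(abs(target[rest])), 0)
  # bell peaks reach the amplitude up to the sample-grid discretisation
  expect_gt(max(abs(target)), 99)
  expect_lte(max(abs(target)), 100)
})

test_that("a left-hand trial mirrors the axes but keeps the same truth", {
  r_spec <- trial_spec(noise_sd = 0, seed = 10, hand_side = "right")
  l_spec <- trial_spec(noise_sd = 0, seed = 10, hand_side = "left")
  tr_r <- simulate_trial(r_spec)
  tr_l <- simulate_trial(l_spec)
  expect_identical(tr_r$truth$time, tr_l$truth$time)
  expect_equal(tr_l$recording$omega_l, -tr_r$recording$omega_l,
               tolerance = 1e-12)
  expect_equal(tr_l$recording$omega_ap, -tr_r$recording$omega_ap,
               tolerance = 1e-12)
})

test_that("pooled truth phase durations reproduce the generative medians", {
  durs <- list(grasping_s = c(), bricks_to_board_s = c(),
               placing_s = c(), board_to_bricks_s = c())
  for (s in 1:60) {
    tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 300 + s))
    cyc <- segment_cycles(tr$truth)$cycles
    for (v in names(durs)) durs[[v]] <- c(durs[[v]], cyc[[v]])
  }
  target <- c(grasping_s = 0.25, bricks_to_board_s = 0.45,
              placing_s = 0.74, board_to_bricks_s = 0.37)
  for (v in names(durs)) {
    expect_lt(abs(median(durs[[v]]) / target[[v]] - 1), 0.05)
  }
})

test_that("noise control changes the recording, not the truth", {
  quiet <- simulate_trial(trial_spec(noise_sd = 0, seed = 12))
  noisy <- simulate_trial(trial_spec(noise_sd = 10, seed = 12))
  expect_identical(quiet$truth$time, noisy$truth$time)
  expect_false(identical(quiet$recording$omega_l, noisy$recording$omega_l))
  expect_equal(sd(noisy$recording$omega_ml), 10, tolerance = 0.5)
  expect_equal(sd(quiet$recording$omega_ml), 0)
})

test_that("placement-adjustment pulses do not break detection", {
  tr <- simulate_trial(trial_spec(noise_sd = 0, adjustment_prob = 1,
                                  seed = 13))
  ev <- quiet_detect(tr$recording)
  m <- match_events(ev, tr$truth)
  expect_gte(sensitivity(m), 95)
})

test_that("simulate_cohort produces the full design with derived seeds", {
  ch <- simulate_cohort(n_per_group = 2,
                        base_spec = trial_spec(n_bricks = 4, noise_sd = 0),
                        seed = 1)
  expect_equal(length(ch$trials), 8)  # 4 participants x 2 hands
  expect_equal(nrow(ch$design), 8)
  expect_setequal(ch$design$age_group, c("6YC", "7YC"))
  expect_setequal(ch$design$hand, c("dominant", "non_dominant"))
  expect_equal(as.integer(table(ch$design$participant_id)), rep(2L, 4))
  # reproducible from the master seed
  ch2 <- simulate_cohort(n_per_group = 2,
                         base_spec = trial_spec(n_bricks = 4, noise_sd = 0),
                         seed = 1)
  expect_identical(ch$trials[[3]]$truth$time, ch2$trials[[3]]$truth$time)
  expect_error(simulate_cohort(n_per_group = 1), class = "pb_parameter_error")
})

test_that("cohort group effects shift the phase medians as configured", {
  ch <- simulate_cohort(n_per_group = 3,
                        base_spec = trial_spec(n_bricks = 6, noise_sd = 0),
                        age_factor = 1.6, between_child_sd = 0,
                        seed = 2)
  med <- sapply(seq_along(ch$trials), function(i) {
    median(segment_cycles(ch$trials[[i]]$truth)$cycles$cycle_s)
  })
  young <- ch$design$age_group == "6YC"
  expect_gt(median(med[young]), median(med[!young]))
})
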