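test_that("matching windows span the midpoints to neighbouring events", {
  ref <- pb_events(c("InitialGrasping", "GraspingEnd", "InitialPlacing"),
                   c(1, 2, 3))
  # window for the GraspingEnd at t = 2 is [1.5, 2.5]
  det_in <- suppressWarnings(pb_events("GraspingEnd", 2.4,
                                       source = "algorithm"))
  det_out <- suppressWarnings(pb_events("GraspingEnd", 2.6,
                                        source = "algorithm"))
  m_in <- match_events(det_in, ref)
  m_out <- match_events(det_out, ref)
  expect_equal(m_in$per_kind$n_matched[m_in$per_kind$kind == "GraspingEnd"], 1)
  expect_equal(m_out$per_kind$n_matched[m_out$per_kind$kind == "GraspingEnd"], 0)
})

test_that("boundary events use recording start/end as missing neighbours", {
  ref <- pb_events("InitialGrasping", 2)
  # window is [(0 + 2)/2, (2 + t_end)/2]; with t_end = 6, [1, 4]
  det <- pb_events("InitialGrasping", 3.9, source = "algorithm")
  expect_equal(match_events(det, ref, t_end = 6)$per_kind$n_matched[1], 1)
  det2 <- pb_events("InitialGrasping", 0.9, source = "algorithm")
  expect_equal(match_events(det2, ref, t_end = 6)$per_kind$n_matched[1], 0)
})

test_that("matching is one-to-one and greedy by time difference", {
  ref <- suppressWarnings(pb_events(rep("InitialGrasping", 2), c(1, 3)))
  det <- suppressWarnings(pb_events(rep("InitialGrasping", 2), c(1.9, 1.1),
                                    source = "algorithm"))
  m <- match_events(det, ref, t_end = 5)
  # det 1.1 pairs with ref 1 (|0.1|), det 1.9 falls in ref-1's window
  # [0.5, 2] too but ref 1 is taken; ref 3's window is [2, 4], so det 1.9
  # stays unmatched
  expect_equal(m$per_kind$n_matched[1], 1)
  expect_equal(m$pairs$ref_time, 1)
  expect_equal(m$pairs$det_time, 1.1)
})

test_that("matching ignores kind mismatches inside the window", {
  ref <- pb_events(c("InitialGrasping", "GraspingEnd"), c(1, 2))
  det <- suppressWarnings(pb_events("GraspingEnd", 1.05,
                                    source = "algorithm"))
  m <- match_events(det, ref)
  expect_equal(sum(m$per_kind$n_matched), 0)
})

test_that("sensitivity and PPV are percentages of matched events", {
  ref <- suppressWarnings(pb_events(rep("InitialGrasping", 4), c(1, 3, 5, 7)))
  det <- suppressWarnings(pb_events(rep("InitialGrasping", 3), c(1.1, 3.2, 40),
                                    source = "algorithm"))
  m <- match_events(det, ref, t_end = 50)
  expect_equal(sensitivity(m, "InitialGrasping"), 100 * 2 / 4)
  expect_equal(ppv(m, "InitialGrasping"), 100 * 2 / 3)
  expect_equal(sensitivity(m), 50)  # pooled over kinds
  expect_error(sensitivity(m, "Bogus"), class = "pb_input_error")
})

test_that("bland_altman satisfies the frozen identities", {
  x <- c(1.2, 1.5, 1.9, 2.4)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_halfwidth, 0)
  expect_equal(ba0$outlier_pct, 0)

  ba_off <- bland_altman(x + 0.3, x)
  expect_equal(ba_off$mean_diff, 0.3, tolerance = 1e-12)
  expect_equal(ba_off$loa_halfwidth, 0, tolerance = 1e-12)

  expect_error(bland_altman(1:2, 1:2), class = "pb_input_error")
  expect_error(bland_altman(1:4, 1:3), class = "pb_input_error")
})

test_that("bland_altman swap negates the bias and keeps the limits", {
  set.seed(31)
  a <- rnorm(50, 1)
  b <- rnorm(50, 1)
  ab <- bland_altman(a, b)
  ba <- bland_altman(b, a)
  expect_equal(ab$mean_diff, -ba$mean_diff, tolerance = 1e-12)
  expect_equal(ab$loa_halfwidth, ba$loa_halfwidth, tolerance = 1e-12)
  expect_equal(ab$outlier_pct, ba$outlier_pct)
})

test_that("about 5% of normal differences fall outside the limits", {
  set.seed(32)
  d <- rnorm(100000)
  ba <- bland_altman(d, numeric(length(d)))
  expect_equal(ba$outlier_pct, 100 * 2 * pnorm(-1.96), tolerance = 0.1)
})

test_that("pearson_rho reproduces a hand-computed value", {
  expect_equal(pearson_rho(c(1, 2, 3), c(2, 1, 3)), 0.5, tolerance = 1e-12)
  expect_error(pearson_rho(c(1, 1, 1), c(1, 2, 3)), class = "pb_input_error")
  expect_error(pearson_rho(1:3, 1:2), class = "pb_input_error")
})

test_that("the reliability gate applies all three strict criteria", {
  # all three pass
  expect_true(reliability(bland_altman_stats(0.00, 0.19, rho = 0.99),
                          2.02)$reliable)
  # bias exactly at the 0.1 s boundary fails (strict inequality)
  v <- reliability(bland_altman_stats(0.1, 0.01, rho = 0.99), 2)
  expect_false(v$reliable)
  expect_match(v$reasons, "mean difference", all = FALSE)
  # limits width exactly 50% of the median fails
  v2 <- reliability(bland_altman_stats(0, 0.25, rho = 0.99), 1)
  expect_false(v2$reliable)
  expect_equal(v2$ci_pct, 50)
  # rho exactly 0.9 fails
  v3 <- reliability(bland_altman_stats(0, 0.01, rho = 0.9), 1)
  expect_false(v3$reliable)
  # missing rho fails rather than passes silently
  v4 <- reliability(bland_altman_stats(0, 0.01), 1)
  expect_false(v4$reliable)
  expect_error(reliability(bland_altman_stats(0, 0.1, rho = 1), 0),
               class = "pb_parameter_error")
})

test_that("validate_events on a noise-free trial gives perfect scores", {
  tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 11))
  v <- validate_events(quiet_detect(tr$recording), tr$truth)
  expect_s3_class(v, "pb_validation")
  expect_true(all(v$scores$sensitivity == 100))
  expect_true(all(v$scores$ppv == 100))
  expect_equal(v$n_cycles_paired, 17)
  expect_equal(v$n_cycles_excluded, 0)
  ag <- v$phases$cycle_s$agreement
  expect_lt(abs(ag$mean_diff), 0.05)
  expect_true(v$phases$cycle_s$verdict$reliable)
})

test_that("validate_events survives a detected sequence with gaps", {
  tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 12))
  det <- quiet_detect(tr$recording)
  # drop one anchor event: one fewer paired cycle, scores below 100
  keep <- !(det$kind == "InitialPlacing" &
              seq_len(nrow(det)) == which(det$kind == "InitialPlacing")[9])
  det2 <- suppressWarnings(pb_events(det$kind[keep], det$time[keep],
                                     source = "algorithm"))
  v <- validate_events(det2, tr$truth)
  ip <- v$scores[v$scores$kind == "InitialPlacing", ]
  expect_equal(ip$n_matched, 17)
  expect_equal(ip$sensitivity, 100 * 17 / 18)
  expect_lte(v$n_cycles_paired, 15)
})
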