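#' Specification of a simulated Placing Bricks trial
#'
#' Defines the generative model for one trial: per-cycle phase durations
#' are drawn from lognormal distributions parameterised by their median
#' and log-scale dispersion; each flight phase produces a bell-shaped
#' (squared-sine, minimum-jerk-like) angular-velocity pulse spanning the
#' phase, positive for bricks-to-board and negative for board-to-bricks;
#' contact phases (Grasping, Placing) carry low-amplitude tremor-band
#' wiggle; the trial is framed by rest, an initial reach from rest to the
#' brick pile (a negative pulse ending at the first Initial Grasping) and
#' a final return to rest after the last Placing End, as in the task
#' protocol (the child lifts the hand to grab the first brick, and parks
#' the hand at rest after the last placement).
#'
#' Default phase-duration medians are the video-measured values of a
#' complete trial: Grasping 0.25 s, bricks-to-board flight 0.45 s, Placing
#' 0.74 s, board-to-bricks flight 0.37 s.
#'
#' @param n_bricks number of bricks placed (default 18).
#' @param medians named numeric: median phase durations in seconds for
#'   `grasping`, `bricks_to_board`, `placing`, `board_to_bricks`.
#' @param dispersions named numeric: lognormal log-scale SDs for the same
#'   four phases.
#' @param peak_amplitude flight-pulse peak amplitude in deg/s (default 100).
#' @param residual_fraction contact-phase wiggle amplitude as a fraction of
#'   `peak_amplitude` (default 0.05).
#' @param tremor_hz frequency of the contact-phase wiggle (default 9 Hz,
#'   in the physiological tremor band and above the 6 Hz detection cutoff).
#' @param noise_sd white measurement-noise SD per axis, deg/s (default 5).
#' @param sample_rate sampling frequency in Hz (default 128).
#' @param hand_side `"right"` or `"left"`; for a left wrist the L and AP
#'   channels are negated (mirrored sensor orientation).
#' @param rest_s rest duration before and after the task (default 1 s).
#' @param adjustment_prob per-cycle probability of an extra small
#'   placement-adjustment pulse inside the Placing phase (default 0),
#'   for robustness testing of the one-peak-per-flight assumption.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `pb_trial_spec`.
#' @export
trial_spec <- function(n_bricks = 18,
                       medians = c(grasping = 0.25, bricks_to_board = 0.45,
                                   placing = 0.74, board_to_bricks = 0.37),
                       dispersions = c(grasping = 0.35, bricks_to_board = 0.15,
                                       placing = 0.30, board_to_bricks = 0.20),
                       peak_amplitude = 100,
                       residual_fraction = 0.05,
                       tremor_hz = 9,
                       noise_sd = 5,
                       sample_rate = 128,
                       hand_side = "right",
                       rest_s = 1,
                       adjustment_prob = 0,
                       seed = NULL) {
  phases <- c("grasping", "bricks_to_board", "placing", "board_to_bricks")
  if (!all(phases %in% names(medians)) || !all(phases %in% names(dispersions))) {
    abort_pb("`medians` and `dispersions` must name all four phases",
             "pb_parameter_error")
  }
  if (n_bricks < 1) abort_pb("`n_bricks` must be >= 1", "pb_parameter_error")
  if (any(medians <= 0) || any(dispersions < 0)) {
    abort_pb("phase medians must be positive and dispersions non-negative",
             "pb_parameter_error")
  }
  if (noise_sd < 0 || residual_fraction < 0 || peak_amplitude <= 0 ||
      sample_rate <= 0 || rest_s < 0 ||
      adjustment_prob < 0 || adjustment_prob > 1) {
    abort_pb("invalid trial parameter", "pb_parameter_error")
  }
  hand_side <- match.arg(hand_side, c("right", "left"))
  structure(list(n_bricks = as.integer(n_bricks),
                 medians = medians[phases], dispersions = dispersions[phases],
                 peak_amplitude = peak_amplitude,
                 residual_fraction = residual_fraction, tremor_hz = tremor_hz,
                 noise_sd = noise_sd, sample_rate = sample_rate,
                 hand_side = hand_side, rest_s = rest_s,
                 adjustment_prob = adjustment_prob, seed = seed),
            class = "pb_trial_spec")
}

# squared-sine bell over n samples (zero value and slope at both ends)
bell_pulse <- function(n, amp) amp * sin(pi * (seq_len(n) - 0.5) / n)^2

draw_phase_samples <- function(spec, phase, n) {
  d <- stats::rlnorm(n, meanlog = log(spec$medians[[phase]]),
                     sdlog = spec$dispersions[[phase]])
  pmax(2L, round(d * spec$sample_rate))
}

#' Simulate one Placing Bricks trial with ground-truth events
#'
#' Generates the target waveform described in [trial_spec()], splits it
#' between the L and AP axes with a random per-trial mixing ratio in
#' (0.2, 0.8) (their algebraic sum reconstructs the target exactly, so
#' ground truth does not depend on the split), fills the ML axis with
#' independent noise, adds white Gaussian measurement noise per axis, and
#' mirrors the sign for a left wrist. Ground-truth event times are the
#' exact phase boundaries.
#'
#' @param spec a [trial_spec()].
#' @param trial_id optional label stored on the recording.
#' @return A list of class `pb_trial`: `recording` ([pb_recording()]),
#'   `truth` ([pb_events()], 4 x `n_bricks` events), `spec`, `mixing`
#'   (L-axis share of the target).
#' @export
#' @examples
#' tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 42))
#' table(tr$truth$kind)
simulate_trial <- function(spec = trial_spec(), trial_id = NULL) {
  stopifnot(inherits(spec, "pb_trial_spec"))
  fs <- spec$sample_rate
  amp <- spec$peak_amplitude
  with_seed(spec$seed, {
    nb <- spec$n_bricks
    n_grasp <- draw_phase_samples(spec, "grasping", nb)
    n_fl <- draw_phase_samples(spec, "bricks_to_board", nb)
    n_pl <- draw_phase_samples(spec, "placing", nb)
    # board-to-bricks draws: initial reach, nb - 1 in-task returns, final return
    n_b2b <- draw_phase_samples(spec, "board_to_bricks", nb + 1L)
    n_rest <- max(2L, round(spec$rest_s * fs))
    adjust <- stats::runif(nb) < spec$adjustment_prob

    contact <- function(n) {
      # tremor-band wiggle, tapered so the phase boundaries are the
      # stationary (near-zero velocity) instants of the contact
      a <- spec$residual_fraction * amp * stats::runif(1, 0.5, 1)
      ph <- stats::runif(1, 0, 2 * pi)
      taper <- sin(pi * (seq_len(n) - 0.5) / n)
      a * taper * sin(2 * pi * spec$tremor_hz * seq_len(n) / fs + ph)
    }
    placing_seg <- function(n, adj) {
      seg <- contact(n)
      n_adj <- round(0.15 * fs)
      if (adj && n > 2L * n_adj) {
        at <- floor((n - n_adj) / 2)
        seg[at + seq_len(n_adj)] <- seg[at + seq_len(n_adj)] +
          bell_pulse(n_adj, 0.4 * amp)
      }
      seg
    }

    segs <- list(rep(0, n_rest), bell_pulse(n_b2b[1], -amp))
    truth_kind <- character(0)
    truth_at <- integer(0)  # cumulative samples at each event boundary
    csum <- n_rest + n_b2b[1]
    for (k in seq_len(nb)) {
      truth_kind <- c(truth_kind, "InitialGrasping")
      truth_at <- c(truth_at, csum)
      segs <- c(segs, list(contact(n_grasp[k])))
      csum <- csum + n_grasp[k]
      truth_kind <- c(truth_kind, "GraspingEnd")
      truth_at <- c(truth_at, csum)
      segs <- c(segs, list(bell_pulse(n_fl[k], amp)))
      csum <- csum + n_fl[k]
      truth_kind <- c(truth_kind, "InitialPlacing")
      truth_at <- c(truth_at, csum)
      segs <- c(segs, list(placing_seg(n_pl[k], adjust[k])))
      csum <- csum + n_pl[k]
      truth_kind <- c(truth_kind, "PlacingEnd")
      truth_at <- c(truth_at, csum)
      segs <- c(segs, list(bell_pulse(n_b2b[k + 1L], -amp)))
      csum <- csum + n_b2b[k + 1L]
    }
    segs <- c(segs, list(rep(0, n_rest)))
    target <- unlist(segs)
    n <- length(target)

    mixing <- stats::runif(1, 0.2, 0.8)
    omega_l <- mixing * target
    omega_ap <- (1 - mixing) * target
    omega_ml <- numeric(n)
    if (spec$noise_sd > 0) {
      omega_l <- omega_l + stats::rnorm(n, sd = spec$noise_sd)
      omega_ap <- omega_ap + stats::rnorm(n, sd = spec$noise_sd)
      omega_ml <- omega_ml + stats::rnorm(n, sd = spec$noise_sd)
    }
    if (spec$hand_side == "left") {
      omega_l <- -omega_l
      omega_ap <- -omega_ap
    }
    rec <- pb_recording(omega_l, omega_ml, omega_ap, fs,
                        hand_side = spec$hand_side, trial_id = trial_id)
    truth <- pb_events(truth_kind, truth_at / fs, source = "annotation")
    structure(list(recording = rec, truth = truth, spec = spec,
                   mixing = mixing),
              class = "pb_trial")
  })
}

#' @export
print.pb_trial <- function(x, ...) {
  cat(sprintf("<pb_trial> %d bricks, %.1f s at %g Hz, noise_sd=%g, %s hand\n",
              x$spec$n_bricks, length(x$recording$omega_l) / x$spec$sample_rate,
              x$spec$sample_rate, x$spec$noise_sd, x$spec$hand_side))
  invisible(x)
}

#' Simulate a two-hand cohort with configurable group effects
#'
#' Generates two trials (dominant and non-dominant hand) for each of
#' `n_per_group` participants in each of two age groups, with group
#' effects injected as multiplicative shifts on the phase-duration medians
#' and dispersions: the younger group and the non-dominant hand are slower
#' and more dispersed by the given factors. Each participant additionally
#' carries a lognormal overall speed factor (`between_child_sd` on the log
#' scale). Sex is assigned in balanced alternation and carries no effect.
#'
#' @param n_per_group participants per age group (>= 2).
#' @param base_spec a [trial_spec()] describing the reference condition
#'   (older group, dominant hand).
#' @param age_factor multiplier on phase medians for the younger group
#'   (default 1.2).
#' @param nondominant_factor multiplier on phase medians for the
#'   non-dominant hand (default 1.1).
#' @param age_dispersion_factor,nondominant_dispersion_factor multipliers
#'   on the phase dispersions (defaults 1.15 and 1.2).
#' @param between_child_sd log-scale SD of the per-participant speed
#'   factor (default 0.12).
#' @param prob_right_handed probability a participant's dominant hand is
#'   the right one (default 0.9).
#' @param seed master seed; per-trial seeds are derived from it.
#' @return A list of class `pb_cohort`: `trials` (list of `pb_trial`) and
#'   `design` (data frame: `trial_id`, `participant_id`, `age_group`,
#'   `sex`, `hand`, `hand_side`).
#' @export
simulate_cohort <- function(n_per_group = 27,
                            base_spec = trial_spec(),
                            age_factor = 1.2,
                            nondominant_factor = 1.1,
                            age_dispersion_factor = 1.15,
                            nondominant_dispersion_factor = 1.2,
                            between_child_sd = 0.12,
                            prob_right_handed = 0.9,
                            seed = NULL) {
  if (n_per_group < 2) abort_pb("need at least 2 participants per group",
                                "pb_parameter_error")
  if (age_factor <= 0 || nondominant_factor <= 0 ||
      age_dispersion_factor <= 0 || nondominant_dispersion_factor <= 0 ||
      between_child_sd < 0) {
    abort_pb("invalid effect configuration", "pb_parameter_error")
  }
  n_total <- 2L * n_per_group
  seeds <- derive_seeds(seed, 2L * n_total + n_total)
  trial_seeds <- seeds[seq_len(2L * n_total)]
  child_seeds <- seeds[2L * n_total + seq_len(n_total)]
  trials <- vector("list", 2L * n_total)
  design <- vector("list", 2L * n_total)
  t_i <- 0L
  for (p in seq_len(n_total)) {
    age_group <- if (p <= n_per_group) "6YC" else "7YC"
    child <- with_seed(child_seeds[p], list(
      speed = exp(stats::rnorm(1, sd = between_child_sd)),
      right_handed = stats::runif(1) < prob_right_handed))
    for (hand in c("dominant", "non_dominant")) {
      t_i <- t_i + 1L
      med <- base_spec$medians * child$speed
      disp <- base_spec$dispersions
      if (age_group == "6YC") {
        med <- med * age_factor
        disp <- disp * age_dispersion_factor
      }
      if (hand == "non_dominant") {
        med <- med * nondominant_factor
        disp <- disp * nondominant_dispersion_factor
      }
      side <- if (xor(hand == "dominant", child$right_handed)) "left" else "right"
      sp <- trial_spec(
        n_bricks = base_spec$n_bricks, medians = med, dispersions = disp,
        peak_amplitude = base_spec$peak_amplitude,
        residual_fraction = base_spec$residual_fraction,
        tremor_hz = base_spec$tremor_hz, noise_sd = base_spec$noise_sd,
        sample_rate = base_spec$sample_rate, hand_side = side,
        rest_s = base_spec$rest_s,
        adjustment_prob = base_spec$adjustment_prob,
        seed = trial_seeds[t_i])
      id <- sprintf("P%03d_%s", p, if (hand == "dominant") "Dh" else "NDh")
      trials[[t_i]] <- simulate_trial(sp, trial_id = id)
      design[[t_i]] <- data.frame(
        trial_id = id, participant_id = sprintf("P%03d", p),
        age_group = age_group, sex = if (p %% 2L) "F" else "M",
        hand = hand, hand_side = side)
    }
  }
  structure(list(trials = trials, design = do.call(rbind, design)),
            class = "pb_cohort")
}

#' @export
print.pb_cohort <- function(x, ...) {
  cat(sprintf("<pb_cohort> %d trials from %d participants\n",
              length(x$trials), length(unique(x$design$participant_id))))
  invisible(x)
}
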