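# Shared helpers for the test suite.

# Detection with bookkeeping warnings (grammar/coincidence) muffled; the
# tests that target those warnings construct sequences explicitly.
quiet_detect <- function(rec, ...) suppressWarnings(detect_events(rec, ...))

quiet_segment <- function(events, ...) suppressWarnings(segment_cycles(events, ...))

# Lock-in measurement of the zero-phase low-pass gain at frequency f:
# filter a pure sinusoid and demodulate its interior (edges discarded),
# so filter transients and windowing do not bias the estimate.
lockin_gain <- function(f, fs = 128, dur = 30, cutoff = 6, order = 4) {
  t <- (0:(dur * fs - 1)) / fs
  rec <- pb_recording(sin(2 * pi * f * t), numeric(length(t)),
                      numeric(length(t)), fs)
  y <- lowpass(compute_target(rec), cutoff = cutoff, order = order)$values
  keep <- t >= 5 & t < dur - 5
  s <- 2 * mean(y[keep] * sin(2 * pi * f * t[keep]))
  c2 <- 2 * mean(y[keep] * cos(2 * pi * f * t[keep]))
  sqrt(s^2 + c2^2)
}

# Analytic forward-backward magnitude responses of an order-n Butterworth
# low-pass: digital design (bilinear transform with cutoff prewarping, the
# filter actually implemented) and the continuous-time prototype.
butter_fb_gain_digital <- function(f, fs = 128, fc = 6, order = 4) {
  1 / (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * order))
}
butter_fb_gain_analog <- function(f, fc = 6, order = 4) {
  1 / (1 + (f / fc)^(2 * order))
}

# Brute-force Poincare-cloud oracle: project the lag-1 return map onto the
# directions perpendicular to (SD1) and along (SD2) the identity line and
# take the sample SD of each projection.
poincare_cloud <- function(x) {
  a <- x[-length(x)]
  b <- x[-1]
  list(sd1 = stats::sd((b - a) / sqrt(2)),
       sd2 = stats::sd((a + b) / sqrt(2)))
}

# Signed detection errors (in samples) of detected vs truth events,
# paired through the matching rule.
detection_errors <- function(trial, fs = trial$spec$sample_rate) {
  m <- match_events(quiet_detect(trial$recording), trial$truth)
  round((m$pairs$det_time - m$pairs$ref_time) * fs)
}
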