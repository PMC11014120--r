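#' Match detected task events against reference annotations
#'
#' A detected event is accepted as a correct identification of a reference
#' event when it falls in the second half of the phase immediately
#' preceding that reference event or the first half of the phase
#' immediately following it: for reference event at time r with previous
#' reference event p and next reference event f (of any kind), the
#' acceptance window is \[(p + r)/2, (r + f)/2\]. Boundary events use the
#' recording start / end as the missing neighbour. Matching is per kind,
#' one-to-one, greedy by smallest absolute time difference (ties broken by
#' earlier reference time), which makes the assignment deterministic and
#' order-independent.
#'
#' @param detected a [pb_events()] sequence from the algorithm.
#' @param reference a grammar-valid [pb_events()] reference sequence
#'   sharing the recording's time axis (e.g. video annotations).
#' @param t_start,t_end recording start and end used as missing
#'   neighbours; `t_end` defaults to the latest time in either sequence.
#' @return A `pb_match` object: list with `per_kind` (data frame: `kind`,
#'   `n_reference`, `n_detected`, `n_matched`) and `pairs` (data frame:
#'   `kind`, `ref_time`, `det_time`).
#' @export
match_events <- function(detected, reference, t_start = 0, t_end = NULL) {
  stopifnot(inherits(detected, "pb_events"), inherits(reference, "pb_events"))
  if (nrow(reference) == 0L) abort_pb("empty reference sequence", "pb_input_error")
  t_end <- t_end %||% max(c(detected$time, reference$time))
  rt <- reference$time
  prev <- c(t_start, rt[-length(rt)])
  nxt <- c(rt[-1], t_end)
  win_lo <- (prev + rt) / 2
  win_hi <- (rt + nxt) / 2
  pairs <- list()
  per_kind <- lapply(event_kinds(), function(k) {
    ri <- which(reference$kind == k)
    di <- which(detected$kind == k)
    n_ref <- length(ri)
    n_det <- length(di)
    cand <- expand.grid(i = ri, j = di)
    if (nrow(cand)) {
      cand$dt <- abs(reference$time[cand$i] - detected$time[cand$j])
      cand <- cand[detected$time[cand$j] >= win_lo[cand$i] &
                     detected$time[cand$j] <= win_hi[cand$i], , drop = FALSE]
      cand <- cand[order(cand$dt, reference$time[cand$i]), , drop = FALSE]
    }
    used_i <- used_j <- integer(0)
    sel <- integer(0)
    for (r in seq_len(nrow(cand))) {
      if (!(cand$i[r] %in% used_i) && !(cand$j[r] %in% used_j)) {
        sel <- c(sel, r)
        used_i <- c(used_i, cand$i[r])
        used_j <- c(used_j, cand$j[r])
      }
    }
    if (length(sel)) {
      pairs[[k]] <<- data.frame(kind = k,
                                ref_time = reference$time[cand$i[sel]],
                                det_time = detected$time[cand$j[sel]])
    }
    data.frame(kind = k, n_reference = n_ref, n_detected = n_det,
               n_matched = length(sel))
  })
  structure(list(per_kind = do.call(rbind, per_kind),
                 pairs = if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE))
                         else data.frame(kind = character(), ref_time = numeric(),
                                         det_time = numeric())),
            class = "pb_match")
}

#' @export
print.pb_match <- function(x, ...) {
  cat("<pb_match>\n")
  print.data.frame(x$per_kind, row.names = FALSE)
  invisible(x)
}

match_counts <- function(m, kind) {
  stopifnot(inherits(m, "pb_match"))
  pk <- m$per_kind
  if (!is.null(kind)) {
    pk <- pk[pk$kind %in% kind, , drop = FALSE]
    if (!nrow(pk)) abort_pb("unknown event kind", "pb_input_error")
  }
  colSums(pk[c("n_reference", "n_detected", "n_matched")])
}

#' Detection sensitivity
#'
#' `100 * matched / reference events`: the percentage of reference events
#' the algorithm correctly identified.
#'
#' @param m a [match_events()] result.
#' @param kind restrict to one event kind (default: all kinds pooled).
#' @return Sensitivity in percent.
#' @export
sensitivity <- function(m, kind = NULL) {
  cnt <- match_counts(m, kind)
  if (cnt["n_reference"] == 0) abort_pb("no reference events", "pb_input_error")
  unname(100 * cnt["n_matched"] / cnt["n_reference"])
}

#' Detection positive predictive value
#'
#' `100 * matched / detected events`: the percentage of the algorithm's
#' detections that correspond to a reference event.
#'
#' @inheritParams sensitivity
#' @return PPV in percent.
#' @export
ppv <- function(m, kind = NULL) {
  cnt <- match_counts(m, kind)
  if (cnt["n_detected"] == 0) abort_pb("no detected events", "pb_input_error")
  unname(100 * cnt["n_matched"] / cnt["n_detected"])
}

#' Bland-Altman agreement statistics
#'
#' For paired measurements of the same durations by two methods, computes
#' the mean difference (bias), the half-width of the 95% limits of
#' agreement (1.96 times the sample SD of the differences) and the
#' percentage of pairs falling outside those limits (about 5% under
#' normality).
#'
#' @param a,b numeric vectors of paired measurements (differences are
#'   `a - b`), at least 3 pairs.
#' @param rho optional Pearson correlation to store alongside (see
#'   [pearson_rho()]).
#' @return A `pb_agreement` list: `mean_diff`, `loa_halfwidth`,
#'   `outlier_pct`, `pearson_rho`, `n_pairs`.
#' @export
bland_altman <- function(a, b, rho = NA_real_) {
  check_finite_numeric(a, "a")
  check_finite_numeric(b, "b")
  if (length(a) != length(b)) abort_pb("`a` and `b` must be paired", "pb_input_error")
  if (length(a) < 3L) abort_pb("need at least 3 pairs", "pb_input_error")
  d <- a - b
  md <- mean(d)
  loa <- 1.96 * stats::sd(d)
  structure(list(mean_diff = md, loa_halfwidth = loa,
                 outlier_pct = 100 * mean(d < md - loa | d > md + loa),
                 pearson_rho = rho, n_pairs = length(d)),
            class = "pb_agreement")
}

#' @export
print.pb_agreement <- function(x, ...) {
  cat(sprintf("<pb_agreement> n=%d md=%.3f LoA=+/-%.3f outliers=%.1f%% rho=%s\n",
              x$n_pairs, x$mean_diff, x$loa_halfwidth, x$outlier_pct,
              ifelse(is.na(x$pearson_rho), "NA", sprintf("%.2f", x$pearson_rho))))
  invisible(x)
}

#' Pearson product-moment correlation of paired measurements
#'
#' @param a,b numeric vectors of paired measurements, at least 3 pairs,
#'   neither constant.
#' @return The correlation coefficient.
#' @export
pearson_rho <- function(a, b) {
  check_finite_numeric(a, "a")
  check_finite_numeric(b, "b")
  if (length(a) != length(b) || length(a) < 3L) {
    abort_pb("need at least 3 pairs", "pb_input_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_pb("correlation undefined for a constant margin", "pb_input_error")
  }
  stats::cor(a, b)
}

#' Reliability gate for a phase-duration measurement
#'
#' A phase duration estimated from the sensor is deemed reliable when all
#' three criteria hold (strict inequalities):
#' \itemize{
#'   \item absolute Bland-Altman mean difference below 0.1 s;
#'   \item the full width of the 95% limits of agreement
#'     (2 x 1.96 x SD of differences) below 50% of the median phase
#'     duration;
#'   \item Pearson correlation above 0.9 (very strong).
#' }
#'
#' @param stats a [bland_altman()] result (its `pearson_rho` field must be
#'   set, directly or via the `rho` argument there).
#' @param median_duration median duration of the phase, in seconds (> 0).
#' @return A `pb_verdict` list: `reliable` (logical), `reasons` (character
#'   vector of failed criteria, empty when reliable), `ci_pct` (limits of
#'   agreement width as % of the median).
#' @export
#' @examples
#' reliability(bland_altman_stats(0.00, 0.19, rho = 0.99), 2.02)$reliable
reliability <- function(stats, median_duration) {
  stopifnot(inherits(stats, "pb_agreement"))
  if (!is.numeric(median_duration) || median_duration <= 0) {
    abort_pb("`median_duration` must be positive", "pb_parameter_error")
  }
  ci_pct <- 100 * (2 * stats$loa_halfwidth) / median_duration
  reasons <- character(0)
  if (!(abs(stats$mean_diff) < 0.1)) {
    reasons <- c(reasons, "mean difference not below 0.1 s")
  }
  if (!(ci_pct < 50)) {
    reasons <- c(reasons, "95% limits of agreement not below 50% of the median duration")
  }
  if (is.na(stats$pearson_rho) || !(stats$pearson_rho > 0.9)) {
    reasons <- c(reasons, "Pearson correlation not above 0.9")
  }
  structure(list(reliable = length(reasons) == 0L, reasons = reasons,
                 ci_pct = ci_pct),
            class = "pb_verdict")
}

#' @export
print.pb_verdict <- function(x, ...) {
  cat(sprintf("<pb_verdict> %s (LoA width %.0f%% of median)\n",
              if (x$reliable) "reliable" else
                paste0("NOT reliable: ", paste(x$reasons, collapse = "; ")),
              x$ci_pct))
  invisible(x)
}

#' Assemble agreement statistics from already-computed numbers
#'
#' Builds a `pb_agreement` object directly from a mean difference, limits
#' half-width and correlation, e.g. when applying the [reliability()] gate
#' to published summary values rather than raw pairs.
#'
#' @param mean_diff mean difference in seconds.
#' @param loa_halfwidth half-width of the 95% limits of agreement (s).
#' @param rho Pearson correlation.
#' @param n_pairs optional pair count.
#' @return A `pb_agreement` object.
#' @export
bland_altman_stats <- function(mean_diff, loa_halfwidth, rho = NA_real_,
                               n_pairs = NA_integer_) {
  if (loa_halfwidth < 0) abort_pb("`loa_halfwidth` must be >= 0", "pb_parameter_error")
  structure(list(mean_diff = mean_diff, loa_halfwidth = loa_halfwidth,
                 outlier_pct = NA_real_, pearson_rho = rho, n_pairs = n_pairs),
            class = "pb_agreement")
}

#' Full validation of detected events against a reference annotation
#'
#' Runs [match_events()] and per-kind [sensitivity()] / [ppv()], segments
#' both sequences into cycles, pairs cycles whose anchor events were
#' matched to each other, and computes per-phase Bland-Altman agreement,
#' Pearson correlation and the [reliability()] verdict. Cycles present in
#' only one source are excluded from the duration pairing and counted.
#'
#' @inheritParams match_events
#' @param anchor cycle anchor kind, see [segment_cycles()].
#' @return A `pb_validation` list: `match`, `scores` (per-kind data frame
#'   with pooled row), `phases` (named list with `pairs_n`,
#'   `agreement`, `verdict` per phase), `n_cycles_excluded`.
#' @export
validate_events <- function(detected, reference, t_start = 0, t_end = NULL,
                            anchor = "InitialPlacing") {
  m <- match_events(detected, reference, t_start = t_start, t_end = t_end)
  scores <- m$per_kind
  scores$sensitivity <- ifelse(scores$n_reference > 0,
                               100 * scores$n_matched / scores$n_reference, NA)
  scores$ppv <- ifelse(scores$n_detected > 0,
                       100 * scores$n_matched / scores$n_detected, NA)
  pooled <- data.frame(kind = "all",
                       n_reference = sum(scores$n_reference),
                       n_detected = sum(scores$n_detected),
                       n_matched = sum(scores$n_matched))
  pooled$sensitivity <- 100 * pooled$n_matched / max(1, pooled$n_reference)
  pooled$ppv <- 100 * pooled$n_matched / max(1, pooled$n_detected)
  scores <- rbind(scores, pooled)

  seg_d <- suppressWarnings(segment_cycles(detected, anchor = anchor))
  seg_r <- suppressWarnings(segment_cycles(reference, anchor = anchor))
  anchor_pairs <- m$pairs[m$pairs$kind == anchor, , drop = FALSE]
  # pair cycles whose start AND end anchors are mutually matched
  key <- function(x) sprintf("%.9f", x)
  map <- stats::setNames(anchor_pairs$det_time, key(anchor_pairs$ref_time))
  pair_idx <- list()
  for (i in seq_len(nrow(seg_r$cycles))) {
    rs <- seg_r$cycles$start[i]
    re <- seg_r$cycles$end[i]
    ds <- map[key(rs)]
    de <- map[key(re)]
    if (is.na(ds) || is.na(de)) next
    j <- which(abs(seg_d$cycles$start - ds) < 1e-9 &
                 abs(seg_d$cycles$end - de) < 1e-9)
    if (length(j) == 1L) pair_idx[[length(pair_idx) + 1L]] <- c(i, j)
  }
  phases <- c("grasping_s", "bricks_to_board_s", "placing_s",
              "board_to_bricks_s", "cycle_s")
  phase_out <- stats::setNames(vector("list", length(phases)), phases)
  n_pairs <- length(pair_idx)
  if (n_pairs >= 3L) {
    ri <- vapply(pair_idx, `[`, integer(1), 1L)
    dj <- vapply(pair_idx, `[`, integer(1), 2L)
    for (ph in phases) {
      a <- seg_d$cycles[[ph]][dj]
      b <- seg_r$cycles[[ph]][ri]
      rho <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else NA_real_
      ag <- bland_altman(a, b, rho = rho)
      med <- stats::median(b)
      phase_out[[ph]] <- list(pairs_n = n_pairs, agreement = ag,
                              verdict = if (med > 0) reliability(ag, med) else NULL,
                              median_reference = med)
    }
  }
  structure(list(match = m, scores = scores, phases = phase_out,
                 n_cycles_paired = n_pairs,
                 n_cycles_excluded = nrow(seg_r$cycles) - n_pairs),
            class = "pb_validation")
}

#' @export
print.pb_validation <- function(x, ...) {
  cat("<pb_validation>\n")
  print.data.frame(x$scores, row.names = FALSE, digits = 4)
  cat(sprintf("cycles paired: %d (excluded: %d)\n",
              x$n_cycles_paired, x$n_cycles_excluded))
  invisible(x)
}
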