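#' Segment a task-event sequence into cycles and phases
#'
#' A cycle runs from one anchor event to the next event of the same kind.
#' The anchor defaults to Initial Placing, the event kind identified most
#' reliably; a complete 18-brick trial then yields exactly 17 full cycles.
#' Within each cycle the four phase durations are read off the intervening
#' events (the phase opened by an event is named after that event's kind:
#' Initial Grasping opens Grasping, Grasping End opens the bricks-to-board
#' flight, Initial Placing opens Placing, Placing End opens the
#' board-to-bricks flight), so the four phases sum exactly to the cycle
#' duration. Cycles containing a grammar break are dropped with a warning;
#' incomplete trailing cycles are discarded, never extrapolated.
#'
#' @param events a [pb_events()] sequence.
#' @param anchor event kind anchoring the cycles (default
#'   `"InitialPlacing"`).
#' @param total_duration optional recording duration in seconds, used to
#'   report the final rest phase.
#' @return An object of class `pb_segmentation`: list with
#'   \describe{
#'     \item{cycles}{data frame, one row per full cycle: `cycle`, `start`,
#'       `end`, the four phase durations (s), `cycle_s`, `placing_pct`.}
#'     \item{anchor}{the anchor kind.}
#'     \item{initial_phase_s}{recording start to first Initial Grasping.}
#'     \item{final_phase_s}{last Placing End to recording end (`NA` when
#'       `total_duration` is unknown).}
#'     \item{total_task_s}{first Initial Grasping to last Placing End.}
#'     \item{lead_in_s}{first Initial Grasping to first anchor.}
#'     \item{trailing_s}{last anchor to last Placing End.}
#'     \item{n_dropped}{cycles dropped for grammar breaks.}
#'   }
#' @export
#' @examples
#' tr <- simulate_trial(trial_spec(noise_sd = 0, seed = 1))
#' seg <- segment_cycles(tr$truth)
#' nrow(seg$cycles)  # 17 for a complete 18-brick trial
segment_cycles <- function(events, anchor = "InitialPlacing",
                           total_duration = NULL) {
  stopifnot(inherits(events, "pb_events"))
  anchor <- match.arg(anchor, event_kinds())
  kinds <- events$kind
  times <- events$time
  phase_cols <- c("grasping_s", "bricks_to_board_s", "placing_s",
                  "board_to_bricks_s")
  empty <- data.frame(cycle = integer(), start = numeric(), end = numeric(),
                      grasping_s = numeric(), bricks_to_board_s = numeric(),
                      placing_s = numeric(), board_to_bricks_s = numeric(),
                      cycle_s = numeric(), placing_pct = numeric())
  ig <- times[kinds == "InitialGrasping"]
  pe <- times[kinds == "PlacingEnd"]
  a_idx <- which(kinds == anchor)
  rows <- list()
  n_dropped <- 0L
  if (length(a_idx) < 2L) {
    warning("fewer than 2 anchor events: no full cycles", call. = FALSE)
  } else {
    for (k in seq_len(length(a_idx) - 1L)) {
      i0 <- a_idx[k]
      i1 <- a_idx[k + 1L]
      span <- seq(i0, i1)
      ok <- (i1 - i0 == 4L) &&
        all(kinds[span[-1]] == unname(.kind_successor[kinds[span[-5]]]))
      if (!ok) {
        n_dropped <- n_dropped + 1L
        next
      }
      durs <- diff(times[span])
      names(durs) <- paste0(unname(.kind_phase[kinds[span[-5]]]), "_s")
      cyc <- times[i1] - times[i0]
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = k, start = times[i0], end = times[i1],
        grasping_s = unname(durs["grasping_s"]),
        bricks_to_board_s = unname(durs["bricks_to_board_s"]),
        placing_s = unname(durs["placing_s"]),
        board_to_bricks_s = unname(durs["board_to_bricks_s"]),
        cycle_s = cyc,
        placing_pct = 100 * unname(durs["placing_s"]) / cyc)
    }
    if (n_dropped > 0L) {
      warning(sprintf("%d cycle(s) dropped for grammar breaks", n_dropped),
              call. = FALSE)
    }
  }
  cycles <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(cycles) <- NULL
  anchor_t <- times[a_idx]
  structure(list(
    cycles = cycles,
    anchor = anchor,
    initial_phase_s = if (length(ig)) ig[1] else NA_real_,
    final_phase_s = if (!is.null(total_duration) && length(pe)) {
      total_duration - pe[length(pe)]
    } else NA_real_,
    total_task_s = if (length(ig) && length(pe)) pe[length(pe)] - ig[1] else NA_real_,
    lead_in_s = if (length(ig) && length(anchor_t)) anchor_t[1] - ig[1] else NA_real_,
    trailing_s = if (length(pe) && length(anchor_t)) {
      pe[length(pe)] - anchor_t[length(anchor_t)]
    } else NA_real_,
    n_dropped = n_dropped
  ), class = "pb_segmentation")
}

#' @export
print.pb_segmentation <- function(x, ...) {
  cat(sprintf("<pb_segmentation> %d full cycle(s) anchored at %s, task %.2f s\n",
              nrow(x$cycles), x$anchor, x$total_task_s))
  invisible(x)
}

#' Per-cycle phase-duration table
#'
#' @param seg a [segment_cycles()] result.
#' @return Data frame with one row per full cycle: `cycle`, the four phase
#'   durations in seconds, `cycle_s`, `placing_pct` (Placing as % of its
#'   cycle) and `degenerate` (any zero-duration phase, kept but flagged).
#'   Zero rows for an empty segmentation.
#' @export
phase_table <- function(seg) {
  stopifnot(inherits(seg, "pb_segmentation"))
  cyc <- seg$cycles
  out <- cyc[, c("cycle", "grasping_s", "bricks_to_board_s", "placing_s",
                 "board_to_bricks_s", "cycle_s", "placing_pct")]
  out$degenerate <- with(cyc, grasping_s == 0 | bricks_to_board_s == 0 |
                           placing_s == 0 | board_to_bricks_s == 0)
  out
}
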