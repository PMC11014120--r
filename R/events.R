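#' The four Placing Bricks task-event kinds, in cycle order
#'
#' Initial Grasping opens the Grasping phase; Grasping End opens the
#' bricks-to-board flight; Initial Placing opens the Placing phase;
#' Placing End opens the board-to-bricks flight back to the pile.
#'
#' @return Character vector of the four kind labels.
#' @export
event_kinds <- function() {
  c("InitialGrasping", "GraspingEnd", "InitialPlacing", "PlacingEnd")
}

# kind that must follow each kind in a grammatical sequence
.kind_successor <- c(InitialGrasping = "GraspingEnd",
                     GraspingEnd = "InitialPlacing",
                     InitialPlacing = "PlacingEnd",
                     PlacingEnd = "InitialGrasping")

# phase name opened by each kind
.kind_phase <- c(InitialGrasping = "grasping",
                 GraspingEnd = "bricks_to_board",
                 InitialPlacing = "placing",
                 PlacingEnd = "board_to_bricks")

#' Construct a task-event sequence
#'
#' Events are stored time-sorted. A grammatical sequence follows the cyclic
#' order IG, GE, IP, PE, IG, ... starting at Initial Grasping; partial final
#' cycles are allowed. Grammar violations are reported (attribute
#' `"grammar_violations"`, plus a warning), never silently repaired.
#' Coincident times are allowed only for adjacent events (a zero-duration
#' contact phase from a degenerate valley) and are flagged with a warning.
#'
#' @param kind character vector of kinds, see [event_kinds()].
#' @param time numeric vector of event times in seconds (>= 0).
#' @param source `"algorithm"` or `"annotation"`.
#' @param warn_grammar warn when the kinds break the cyclic grammar.
#' @return A `pb_events` object: a data frame with columns `kind`, `time`,
#'   `source`.
#' @export
#' @examples
#' pb_events(c("InitialGrasping", "GraspingEnd"), c(0.5, 0.8))
pb_events <- function(kind, time, source = "annotation", warn_grammar = TRUE) {
  kind <- as.character(kind)
  bad <- setdiff(unique(kind), event_kinds())
  if (length(bad)) {
    abort_pb(paste0("unknown event kind(s): ", paste(bad, collapse = ", ")),
             "pb_format_error")
  }
  check_finite_numeric(time, "time")
  if (length(kind) != length(time)) {
    abort_pb("`kind` and `time` must have the same length", "pb_input_error")
  }
  if (any(time < 0)) abort_pb("event times must be >= 0", "pb_input_error")
  source <- match.arg(source, c("annotation", "algorithm"))
  ord <- order(time)
  if (is.unsorted(time)) {
    warning("events were not in time order; sorted", call. = FALSE)
  }
  ev <- data.frame(kind = kind[ord], time = time[ord],
                   source = rep(source, length(kind)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ev[c("kind", "time")])) {
    abort_pb("duplicate (kind, time) rows", "pb_format_error")
  }
  if (any(diff(ev$time) == 0)) {
    warning("coincident event times (zero-duration phase)", call. = FALSE)
  }
  viol <- check_event_grammar(ev)
  if (warn_grammar && nrow(viol)) {
    warning(sprintf("event sequence breaks the IG>GE>IP>PE grammar at %d position(s)",
                    nrow(viol)), call. = FALSE)
  }
  structure(ev, class = c("pb_events", "data.frame"),
            grammar_violations = viol)
}

#' Check the cyclic task-event grammar
#'
#' @param events a `pb_events` object or data frame with `kind` and `time`.
#' @return Data frame of violations with columns `position`, `kind`,
#'   `expected`; zero rows when the sequence is grammatical.
#' @export
check_event_grammar <- function(events) {
  kinds <- events$kind
  viol <- data.frame(position = integer(), kind = character(),
                     expected = character(), stringsAsFactors = FALSE)
  if (!length(kinds)) return(viol)
  if (kinds[1] != "InitialGrasping") {
    viol <- rbind(viol, data.frame(position = 1L, kind = kinds[1],
                                   expected = "InitialGrasping"))
  }
  if (length(kinds) > 1L) {
    expected <- unname(.kind_successor[kinds[-length(kinds)]])
    bad <- which(kinds[-1] != expected)
    if (length(bad)) {
      viol <- rbind(viol, data.frame(position = bad + 1L, kind = kinds[bad + 1L],
                                     expected = expected[bad]))
    }
  }
  viol
}

#' @export
print.pb_events <- function(x, ...) {
  nv <- nrow(attr(x, "grammar_violations") %||% data.frame())
  cat(sprintf("<pb_events> %d events (%s)%s\n", nrow(x),
              paste(unique(x$source), collapse = "+"),
              if (nv) sprintf(", %d grammar violation(s)", nv) else ""))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("... %d more\n", nrow(x) - 8))
  invisible(x)
}

#' Read task events from a delimited text file
#'
#' Expects a CSV with columns `event_kind` and `time_s`. Rows out of time
#' order are sorted with a warning; unknown kinds and duplicate
#' (kind, time) rows are errors.
#'
#' @param path file path.
#' @param source provenance label stored on the events.
#' @return A [pb_events()] sequence.
#' @export
read_events <- function(path, source = "annotation") {
  if (!file.exists(path)) abort_pb(paste0("no such file: ", path), "pb_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("event_kind", "time_s"), names(df))
  if (length(missing_cols)) {
    abort_pb(paste0("missing required columns: ",
                    paste(missing_cols, collapse = ", ")), "pb_format_error")
  }
  pb_events(df$event_kind, df$time_s, source = source)
}

#' Write task events to a delimited text file
#'
#' @param events a [pb_events()] sequence.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "pb_events"))
  df <- data.frame(event_kind = events$kind, time_s = events$time)
  tryCatch(utils::write.csv(df, path, row.names = FALSE),
           error = function(e) abort_pb(conditionMessage(e), "pb_io_error"))
  invisible(path)
}
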