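#' Write a per-cycle phase-duration table to CSV
#'
#' One row per cycle with the four phase durations, cycle duration and
#' Placing as % of cycle, written to 6 decimal places. An empty table
#' writes the header only, with a warning.
#'
#' @param tab a [phase_table()] data frame.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_cycles <- function(tab, path) {
  cols <- c("cycle", "grasping_s", "bricks_to_board_s", "placing_s",
            "board_to_bricks_s", "cycle_s", "placing_pct")
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols)) {
    abort_pb(paste0("not a cycle table; missing: ",
                    paste(missing_cols, collapse = ", ")), "pb_input_error")
  }
  if (nrow(tab) == 0L) warning("writing an empty cycle table", call. = FALSE)
  out <- tab[cols]
  num <- setdiff(cols, "cycle")
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) abort_pb(conditionMessage(e), "pb_io_error"))
  invisible(path)
}

#' Read a per-cycle phase-duration table from CSV
#'
#' @param path file path written by [write_cycles()].
#' @return Data frame with the cycle-table columns.
#' @export
read_cycles <- function(path) {
  if (!file.exists(path)) abort_pb(paste0("no such file: ", path), "pb_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("cycle", "grasping_s", "bricks_to_board_s", "placing_s",
            "board_to_bricks_s", "cycle_s", "placing_pct")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    abort_pb(paste0("not a cycle table; missing: ",
                    paste(missing_cols, collapse = ", ")), "pb_format_error")
  }
  df
}

# strip classes so jsonlite serialises plain lists/frames
as_plain <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  if (is.list(x)) return(lapply(unclass(x), as_plain))
  x
}

#' Write a summary, match, agreement or validation report as JSON
#'
#' Serialises any of the package's result objects (variability summaries,
#' match results, agreement statistics, reliability verdicts, comparison
#' results, validation bundles, or plain lists of them) to structured
#' JSON with all fields named as in the objects.
#'
#' @param report the result object.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  tryCatch(
    jsonlite::write_json(as_plain(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE),
    error = function(e) abort_pb(conditionMessage(e), "pb_io_error"))
  invisible(path)
}
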