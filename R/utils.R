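`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort_pb <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "pb_error"), call = call))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded
#' simulations do not perturb the global stream. With `seed = NULL` the
#' expression uses (and advances) the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a stream of sub-seeds from one master seed; keeps values in the
# 32-bit integer range expected by set.seed().
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_finite_numeric <- function(x, name, class = "pb_input_error") {
  if (!is.numeric(x)) abort_pb(sprintf("`%s` must be numeric", name), class)
  if (anyNA(x) || any(!is.finite(x))) {
    abort_pb(sprintf("`%s` contains non-finite values", name), class)
  }
  invisible(x)
}
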