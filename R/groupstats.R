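new_comparison <- function(variable, groups, test, statistic, p_value, alpha,
                           method) {
  structure(list(variable = variable, groups = groups, test = test,
                 statistic = statistic, p_value = p_value,
                 significant = p_value < alpha, alpha = alpha,
                 method = method),
            class = "pb_comparison")
}

#' @export
print.pb_comparison <- function(x, ...) {
  cat(sprintf("<pb_comparison> %s [%s]: %s, stat=%.4g, p=%.4g (%s at alpha=%g)\n",
              x$variable, paste(x$groups, collapse = " vs "), x$test,
              x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

# two-sided p from a null distribution sample/enumeration of a statistic
two_sided_p <- function(null_values, observed, tol = 1e-9) {
  p_le <- mean(null_values <= observed + tol)
  p_ge <- mean(null_values >= observed - tol)
  min(1, 2 * min(p_le, p_ge))
}

#' Normality screening (Kolmogorov-Smirnov)
#'
#' One-sample KS test of the series against a normal distribution with the
#' sample mean and SD. Used as a screening step only: the analysis pipeline
#' always proceeds with nonparametric tests regardless of the outcome, so
#' the result is a logged recommendation, not a gate. Because the normal
#' parameters are estimated from the same data, the plain KS p-value is
#' conservative (no Lilliefors correction is applied).
#'
#' @param x numeric vector, at least 4 finite, non-constant values.
#' @param alpha significance level (default 0.05).
#' @param variable label for reporting.
#' @return A `pb_comparison` with `test = "kolmogorov_smirnov"`;
#'   `significant = TRUE` recommends against assuming normality.
#' @export
normality_screen <- function(x, alpha = 0.05, variable = "x") {
  check_finite_numeric(x, "x")
  if (length(x) < 4L) abort_pb("need at least 4 values", "pb_input_error")
  if (stats::sd(x) == 0) abort_pb("constant series: test degenerate", "pb_input_error")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  new_comparison(variable, "sample vs normal", "kolmogorov_smirnov",
                 unname(kt$statistic), kt$p.value, alpha,
                 "one-sample KS against N(mean(x), sd(x)); screening only")
}

#' Mann-Whitney U test for two independent groups
#'
#' Two-sided rank-sum comparison (e.g. males vs females, or the two age
#' groups). For combined sample sizes up to `exact_max_n` the p-value is
#' computed by exact enumeration of all group assignments (which remains
#' valid in the presence of ties); above that, the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @param exact_max_n combined-size limit for the exact branch (default 20).
#' @param variable,groups labels for reporting.
#' @return A `pb_comparison` with the U statistic for `x`.
#' @export
#' @examples
#' compare_independent(c(1, 2), c(3, 4))$p_value  # exact: 1/3
compare_independent <- function(x, y, alpha = 0.05, exact_max_n = 20,
                                variable = "x", groups = c("x", "y")) {
  check_finite_numeric(x, "x")
  check_finite_numeric(y, "y")
  if (length(x) < 2L || length(y) < 2L) {
    abort_pb("each group needs at least 2 values", "pb_input_error")
  }
  nx <- length(x)
  ny <- length(y)
  if (nx + ny <= exact_max_n) {
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    combos <- utils::combn(nx + ny, nx)
    u_null <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- two_sided_p(u_null, u_obs)
    method <- "exact enumeration of group assignments"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    u_obs <- unname(wt$statistic)
    p <- wt$p.value
    method <- "normal approximation with tie and continuity correction"
  }
  new_comparison(variable, groups, "mann_whitney_u", u_obs, p, alpha, method)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired comparison (e.g. dominant vs non-dominant hand of the
#' same participants). Zero differences are dropped (standard signed-rank
#' convention). For up to `exact_enum_n` non-zero differences the p-value
#' is computed by exact enumeration of all sign patterns (valid with tied
#' absolute differences); between that and `exact_max_n` without ties the
#' exact signed-rank distribution is used; otherwise the normal
#' approximation with continuity correction.
#'
#' @param x,y paired numeric samples of equal length >= 2.
#' @param alpha significance level (default 0.05).
#' @param exact_enum_n limit for full sign-pattern enumeration (default 15).
#' @param exact_max_n limit for the exact signed-rank distribution
#'   (default 25).
#' @param variable,groups labels for reporting.
#' @return A `pb_comparison` with the signed-rank statistic V (sum of
#'   ranks of positive differences).
#' @export
#' @examples
#' compare_paired(c(1, 2, 3), c(2, 3, 4))$p_value  # exact: 0.25
compare_paired <- function(x, y, alpha = 0.05, exact_enum_n = 15,
                           exact_max_n = 25, variable = "x",
                           groups = c("x", "y")) {
  check_finite_numeric(x, "x")
  check_finite_numeric(y, "y")
  if (length(x) != length(y) || length(x) < 2L) {
    abort_pb("need paired samples of equal length >= 2", "pb_input_error")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort_pb("all differences are zero: no test possible", "pb_input_error")
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= exact_enum_n) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_null <- as.numeric(signs %*% r)
    p <- two_sided_p(v_null, v_obs)
    method <- "exact enumeration of sign patterns"
  } else if (n <= exact_max_n && !has_ties) {
    wt <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    v_obs <- unname(wt$statistic)
    p <- wt$p.value
    method <- "exact signed-rank distribution"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    v_obs <- unname(wt$statistic)
    p <- wt$p.value
    method <- "normal approximation with continuity correction"
  }
  new_comparison(variable, groups, "wilcoxon_signed_rank", v_obs, p, alpha,
                 method)
}

#' Group comparisons over per-participant summaries
#'
#' Applies the assessment's standard statistical workflow to a table of per-participant
#' measures: Mann-Whitney U for the independent factors (sex, age group)
#' and Wilcoxon signed-rank for hand dominance (participants paired with
#' themselves). No multiple-testing correction is applied by default,
#' matching a per-test alpha of 0.05; set `p_adjust = "holm"` to adjust
#' within each factor.
#'
#' @param summaries data frame with one row per trial: measurement columns
#'   plus `participant_id`, `age_group`, `sex`, `hand`
#'   (`"dominant"`/`"non_dominant"`).
#' @param variables measurement column names to compare.
#' @param alpha significance level.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Data frame with one row per (variable, factor) comparison.
#' @export
compare_groups <- function(summaries,
                           variables,
                           alpha = 0.05,
                           p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("participant_id", "age_group", "sex", "hand", variables)
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols)) {
    abort_pb(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
             "pb_input_error")
  }
  rows <- list()
  for (v in variables) {
    for (fac in c("sex", "age_group")) {
      lev <- sort(unique(summaries[[fac]]))
      if (length(lev) != 2L) next
      cmp <- compare_independent(summaries[[v]][summaries[[fac]] == lev[1]],
                                 summaries[[v]][summaries[[fac]] == lev[2]],
                                 alpha = alpha, variable = v, groups = lev)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, factor = fac, test = cmp$test,
        statistic = cmp$statistic, p_value = cmp$p_value)
    }
    wide <- merge(
      summaries[summaries$hand == "dominant", c("participant_id", v)],
      summaries[summaries$hand == "non_dominant", c("participant_id", v)],
      by = "participant_id", suffixes = c("_d", "_nd"))
    if (nrow(wide) >= 2L) {
      cmp <- compare_paired(wide[[paste0(v, "_d")]], wide[[paste0(v, "_nd")]],
                            alpha = alpha, variable = v,
                            groups = c("dominant", "non_dominant"))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, factor = "hand", test = cmp$test,
        statistic = cmp$statistic, p_value = cmp$p_value)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "holm") {
    out$p_value <- stats::ave(out$p_value, out$factor,
                              FUN = function(p) stats::p.adjust(p, "holm"))
  }
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}
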