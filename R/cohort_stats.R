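#' Two-sided Welch t-test between two groups
#'
#' Unequal-variance t statistic
#' \eqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' the t distribution. Implemented from the closed-form expressions;
#' agrees with `stats::t.test(var.equal = FALSE)`.
#'
#' @param a,b Numeric samples, each of size >= 2, not both constant.
#' @param label_a,label_b Group labels carried into the result.
#' @return A list of class `tcr_group_comparison` with `groups`, `means`,
#'   `ci95` (t-based per-group 95% CIs), `t_statistic`, `welch_df`,
#'   `p_two_sided`.
#' @export
welch_t <- function(a, b, label_a = "a", label_b = "b") {
  if (length(a) < 2L || length(b) < 2L) {
    stop("Each group needs at least 2 observations.", call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va + vb == 0) {
    stop("Welch test is undefined when both groups have zero variance.", call. = FALSE)
  }
  na <- length(a)
  nb <- length(b)
  se2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(
    list(
      groups = c(label_a, label_b),
      means = c(mean(a), mean(b)),
      ci95 = rbind(mean_ci(a)[2:3], mean_ci(b)[2:3]),
      t_statistic = t_stat,
      welch_df = df,
      p_two_sided = p
    ),
    class = "tcr_group_comparison"
  )
}

#' @export
print.tcr_group_comparison <- function(x, ...) {
  cat(sprintf("Welch t-test (%s vs %s): t = %.4f, df = %.4f, p = %.4g\n",
              x$groups[1], x$groups[2], x$t_statistic, x$welch_df, x$p_two_sided))
  invisible(x)
}

#' Mean with a t-based 95% confidence interval
#'
#' @param values Numeric vector, n >= 2.
#' @return Named numeric vector `c(mean, lower, upper)` with bounds
#'   `mean +/- t(0.975, n-1) * s / sqrt(n)`.
#' @export
mean_ci <- function(values) {
  n <- length(values)
  if (n < 2L) {
    stop("Need at least 2 values for a confidence interval.", call. = FALSE)
  }
  m <- mean(values)
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Ordinary least-squares fit with coefficient confidence intervals
#'
#' Simple linear regression `y ~ x` via `stats::lm`, returning slope and
#' intercept with their 95% confidence intervals and the coefficient of
#' determination.
#'
#' @param x,y Numeric vectors, n >= 3, `x` not constant.
#' @return A list of class `tcr_regression` with `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `r_squared`, and the underlying `fit`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("Need aligned x and y with at least 3 observations.", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("Singular design: `x` is constant.", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ci <- suppressWarnings(stats::confint(fit))
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      slope_ci = unname(ci[2, ]),
      intercept_ci = unname(ci[1, ]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      fit = fit
    ),
    class = "tcr_regression"
  )
}

#' @export
print.tcr_regression <- function(x, ...) {
  cat(sprintf("OLS fit: y = %.4g + %.4g x (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Group comparison table for a per-sample statistic
#'
#' Summarises a statistic by group (mean with 95% CI) and runs pairwise
#' two-sided Welch t-tests between all groups. Mirrors the cohort
#' reporting convention: significance threshold 0.05, no multiplicity
#' correction.
#'
#' @param values Numeric per-sample statistic.
#' @param groups Character group labels, same length.
#' @return A list with `summary` (tibble: group, n, mean, ci_lo, ci_hi)
#'   and `tests` (tibble: group_a, group_b, t, df, p).
#' @export
group_comparison <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  labs <- unique(groups)
  summary <- dplyr::bind_rows(lapply(labs, function(g) {
    v <- values[groups == g]
    ci <- if (length(v) >= 2L) mean_ci(v) else c(mean(v), NA_real_, NA_real_)
    tibble::tibble(group = g, n = length(v), mean = ci[[1]],
                   ci_lo = ci[[2]], ci_hi = ci[[3]])
  }))
  combos <- utils::combn(labs, 2, simplify = FALSE)
  tests <- dplyr::bind_rows(lapply(combos, function(gg) {
    w <- welch_t(values[groups == gg[1]], values[groups == gg[2]],
                 gg[1], gg[2])
    tibble::tibble(group_a = gg[1], group_b = gg[2], t = w$t_statistic,
                   df = w$welch_df, p = w$p_two_sided)
  }))
  list(summary = summary, tests = tests)
}
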