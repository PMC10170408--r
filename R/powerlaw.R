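# Discrete power-law fitting with KS-optimal xmin and a semiparametric
# bootstrap goodness-of-fit test (Clauset-Shalizi-Newman procedure).
# The pmf above xmin is p(x) = x^(-alpha) / zeta(alpha, xmin) with the
# Hurwitz zeta normalizer.

# negative log-likelihood of the tail sample at exponent a
#' @keywords internal
#' @noRd
pl_negll <- function(a, tail_x, xmin) {
  length(tail_x) * log(hurwitz_zeta(a, xmin)) + a * sum(log(tail_x))
}

# MLE of alpha for fixed xmin, plus the KS distance of the fitted tail
#' @keywords internal
#' @noRd
pl_fit_fixed_xmin <- function(x, xmin, alpha_range = c(1.01, 8)) {
  tail_x <- x[x >= xmin]
  opt <- stats::optimize(pl_negll, interval = alpha_range,
                         tail_x = tail_x, xmin = xmin, tol = 1e-4)
  alpha <- opt$minimum
  # KS distance between empirical and fitted CDFs on the tail support
  vals <- sort(unique(tail_x))
  z <- hurwitz_zeta(alpha, xmin)
  # fitted CDF at v: 1 - zeta(alpha, v + 1)/zeta(alpha, xmin)
  fit_cdf <- vapply(vals, function(v) 1 - hurwitz_zeta(alpha, v + 1) / z, numeric(1))
  emp_cdf <- cumsum(tabulate(factor(tail_x, levels = vals))) / length(tail_x)
  list(alpha = alpha, ks = max(abs(emp_cdf - fit_cdf)), n_tail = length(tail_x))
}

# Fit alpha and xmin by scanning candidate xmins and minimizing the KS
# distance. Candidates are the unique data values that leave at least
# `min_tail` observations and at least 2 distinct tail values; at most
# `max_candidates` are scanned (rank-uniform thinning).
#' @keywords internal
#' @noRd
pl_fit <- function(x, min_tail = 10L, max_candidates = 80L) {
  cands <- sort(unique(x))
  keep <- vapply(cands, function(v) {
    tl <- x[x >= v]
    length(tl) >= min_tail && length(unique(tl)) >= 2L
  }, logical(1))
  cands <- cands[keep]
  if (length(cands) == 0L) {
    stop("Too few positive degrees for a power-law fit.", call. = FALSE)
  }
  if (length(cands) > max_candidates) {
    cands <- cands[unique(round(seq(1, length(cands), length.out = max_candidates)))]
  }
  fits <- lapply(cands, function(v) pl_fit_fixed_xmin(x, v))
  ks <- vapply(fits, `[[`, numeric(1), "ks")
  best <- which.min(ks)
  c(fits[[best]], list(xmin = cands[best]))
}

#' Sample from a discrete power law
#'
#' Draws from the pmf \eqn{p(x) \propto x^{-\alpha}} on the integers
#' \eqn{x \ge x_{min}}, by inversion of the exact CDF (tabulated out to
#' the 1 - 1e-8 quantile; the far tail uses the standard continuous
#' approximation).
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param xmin Lower support bound (integer >= 1).
#' @return Integer vector of length `n`.
#' @export
rpl_discrete <- function(n, alpha, xmin = 1L) {
  if (alpha <= 1) stop("`alpha` must exceed 1.", call. = FALSE)
  if (xmin < 1) stop("`xmin` must be at least 1.", call. = FALSE)
  z <- hurwitz_zeta(alpha, xmin)
  # extend support until the tabulated CDF covers 1 - 1e-8
  cap <- xmin + 1023L
  repeat {
    vals <- seq.int(xmin, cap)
    cdf <- cumsum(vals^(-alpha)) / z
    if (cdf[length(cdf)] > 1 - 1e-8 || cap > 2e6) break
    cap <- cap * 4L
  }
  u <- stats::runif(n)
  out <- vals[findInterval(u, cdf) + 1L]
  beyond <- is.na(out)
  if (any(beyond)) {
    out[beyond] <- floor((xmin - 0.5) * (1 - u[beyond])^(-1 / (alpha - 1)) + 0.5)
  }
  as.integer(out)
}

#' Power-law fit and bootstrap goodness-of-fit for a degree distribution
#'
#' Fits a discrete power law to positive integer data (typically network
#' degrees; zero-degree nodes are excluded beforehand since the discrete
#' power law has support on x >= 1): the lower cutoff `xmin` is chosen by
#' Kolmogorov-Smirnov minimization, `alpha` by maximum likelihood above
#' `xmin`. The goodness-of-fit p-value comes from a semiparametric
#' bootstrap: each replicate resamples the body below `xmin` empirically
#' and draws the tail from the fitted model, is refitted from scratch,
#' and contributes its KS distance; `gof_p` is the fraction of replicates
#' whose KS distance is at least the observed one. A distribution with
#' `gof_p > 0.1` is considered a plausible power law.
#'
#' @param degrees Integer sample, all values >= 1; at least 50 values.
#' @param n_boot Bootstrap replicates (default 1000; 200 gives a faster,
#'   coarser p-value).
#' @param seed Optional RNG seed for the bootstrap.
#' @return An object of class `tcr_powerlaw`: list with `xmin`, `alpha`,
#'   `ks`, `gof_p`, `n_boot`, `plausible` (`gof_p > 0.1`), `n_tail`.
#' @export
powerlaw_gof <- function(degrees, n_boot = 1000L, seed = NULL) {
  x <- as.integer(degrees)
  if (any(x < 1L)) {
    stop("All degrees must be >= 1 (drop degree-0 nodes before fitting).",
         call. = FALSE)
  }
  if (length(x) < 50L) {
    stop("Need at least 50 positive degrees for a power-law fit.", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("Degenerate degree distribution: all values identical.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- pl_fit(x)
  n <- length(x)
  body <- x[x < fit$xmin]
  p_tail <- fit$n_tail / n
  ks_boot <- vapply(seq_len(n_boot), function(i) {
    from_tail <- stats::runif(n) < p_tail
    sim <- integer(n)
    n_t <- sum(from_tail)
    if (n_t > 0L) sim[from_tail] <- rpl_discrete(n_t, fit$alpha, fit$xmin)
    if (n_t < n) sim[!from_tail] <- sample(body, n - n_t, replace = TRUE)
    f <- tryCatch(pl_fit(sim), error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$ks
  }, numeric(1))
  ks_boot <- ks_boot[!is.na(ks_boot)]
  gof_p <- mean(ks_boot >= fit$ks)
  structure(
    list(xmin = fit$xmin, alpha = fit$alpha, ks = fit$ks,
         gof_p = gof_p, n_boot = length(ks_boot),
         plausible = gof_p > 0.1, n_tail = fit$n_tail),
    class = "tcr_powerlaw"
  )
}

#' @export
print.tcr_powerlaw <- function(x, ...) {
  cat(sprintf("Discrete power-law fit: alpha = %.3f above xmin = %d (tail n = %d)\n",
              x$alpha, x$xmin, x$n_tail))
  cat(sprintf("  KS = %.4f, bootstrap GOF p = %.3f (%d replicates) -> %s\n",
              x$ks, x$gof_p, x$n_boot,
              if (x$plausible) "plausible power law" else "rejected"))
  invisible(x)
}
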