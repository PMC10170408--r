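#' Hill diversity over a grid of diversity orders
#'
#' Computes the Hill diversity profile \eqn{D(q) = (\sum_i p_i^q)^{1/(1-q)}}
#' for a vector of clone frequencies. \eqn{D(0)} is the number of clones
#' (species richness), \eqn{D(1)} the exponential of the Shannon entropy
#' (taken as the limit \eqn{\exp(-\sum_i p_i \log p_i)}), and \eqn{D(2)}
#' the inverse Simpson index. \eqn{D(q)} is non-increasing in \eqn{q} and
#' bounded between 1 and the richness.
#'
#' @param p Numeric vector of clone proportions; all strictly positive and
#'   summing to 1 (checked to 1e-9).
#' @param q_grid Numeric vector of diversity orders, default
#'   `seq(0, 10, by = 0.2)`.
#'
#' @return Numeric vector of effective clone numbers, one per element of
#'   `q_grid`.
#' @seealso [evenness_profile()], [clonality_index()], [diversity_profile()]
#' @examples
#' hill_diversity(c(0.9, 0.1), q_grid = c(0, 1, 2))
#' @export
hill_diversity <- function(p, q_grid = seq(0, 10, by = 0.2)) {
  if (length(p) == 0L) {
    stop("Frequency vector is empty.", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("All clone frequencies must be finite and strictly positive.", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("Clone frequencies must sum to 1 (tolerance 1e-9).", call. = FALSE)
  }
  shannon <- -sum(p * log(p))
  vapply(q_grid, function(q) {
    if (abs(q - 1) < 1e-12) {
      exp(shannon)
    } else {
      sum(p^q)^(1 / (1 - q))
    }
  }, numeric(1))
}

#' Evenness profile from a Hill diversity profile
#'
#' Normalizes a Hill diversity profile by the species richness,
#' \eqn{E(q) = D(q) / SR} with \eqn{SR = D(0)}, giving a dimensionless
#' curve in (0, 1] with `E(0) = 1` for every repertoire.
#'
#' @param D Numeric vector of Hill diversities along a q grid, with the
#'   first element at q = 0.
#' @param SR Species richness; defaults to `D[1]`.
#' @return Numeric vector of evenness values in (0, 1].
#' @export
evenness_profile <- function(D, SR = D[1]) {
  if (length(D) == 0L || !is.finite(SR) || SR <= 0) {
    stop("Species richness must be a positive number.", call. = FALSE)
  }
  E <- D / SR
  E[1] <- 1
  E
}

#' Clonality index from an evenness profile
#'
#' The clonality index is 10 minus the area under the evenness curve over
#' q in \[0, 10\], integrated by composite Simpson's rule on the grid.
#' A perfectly even repertoire has evenness identically 1, area 10, and
#' clonality 0; increasingly oligoclonal repertoires approach 10.
#'
#' Note that a strictly monoclonal repertoire (a single clone, richness 1)
#' also has evenness identically 1 and therefore clonality 0; richness
#' below 2 should be flagged upstream (see [diversity_profile()]).
#'
#' @param E Numeric vector of evenness values on `q_grid`.
#' @param q_grid Evenly spaced grid with an even number of intervals,
#'   default `seq(0, 10, by = 0.2)`.
#' @param method `"simpson"` (default) or `"trapezoid"` for sensitivity
#'   checks.
#' @return Clonality index in \[0, 10).
#' @export
clonality_index <- function(E, q_grid = seq(0, 10, by = 0.2),
                            method = c("simpson", "trapezoid")) {
  method <- match.arg(method)
  if (length(E) != length(q_grid)) {
    stop("`E` and `q_grid` must have the same length.", call. = FALSE)
  }
  auc <- switch(method,
    simpson = simpson_auc(q_grid, E),
    trapezoid = sum(diff(q_grid) * (utils::head(E, -1) + utils::tail(E, -1)) / 2)
  )
  10 - auc
}

#' Per-repertoire diversity profile
#'
#' Computes the Hill diversity profile, evenness profile, richness, and
#' clonality index from clone template counts. Frequencies are template
#' proportions of productive clonotypes (templates are the T-cell proxy).
#'
#' @param counts Positive integer template counts, one per clonotype.
#' @param q_grid Diversity-order grid, default `seq(0, 10, by = 0.2)`.
#' @param method Integration rule for the clonality index.
#' @return An object of class `tcr_diversity`: a list with `q_grid`, `D`,
#'   `E`, `SR`, and `clonality`. Richness below 2 triggers a warning
#'   because the evenness normalization makes a monoclonal repertoire
#'   indistinguishable from a perfectly even one.
#' @examples
#' prof <- diversity_profile(c(500, 100, 10, 5, rep(1, 20)))
#' prof$clonality
#' @export
diversity_profile <- function(counts, q_grid = seq(0, 10, by = 0.2),
                              method = c("simpson", "trapezoid")) {
  method <- match.arg(method)
  if (length(counts) == 0L || any(counts <= 0)) {
    stop("`counts` must be a non-empty vector of positive template counts.",
         call. = FALSE)
  }
  if (length(counts) < 2L) {
    warning("Richness below 2: clonality is 0 by construction for a monoclonal repertoire.",
            call. = FALSE)
  }
  p <- counts / sum(counts)
  D <- hill_diversity(p, q_grid)
  E <- evenness_profile(D, SR = length(counts))
  auc <- switch(method,
    simpson = simpson_auc(q_grid, E),
    trapezoid = sum(diff(q_grid) * (utils::head(E, -1) + utils::tail(E, -1)) / 2)
  )
  structure(
    list(
      q_grid = q_grid,
      D = D,
      E = E,
      SR = length(counts),
      clonality = 10 - auc
    ),
    class = "tcr_diversity"
  )
}

#' @export
print.tcr_diversity <- function(x, ...) {
  cat("TCR diversity profile\n")
  cat(sprintf("  richness (D at q=0): %d\n", x$SR))
  cat(sprintf("  q grid: [%g, %g] in %d points\n",
              min(x$q_grid), max(x$q_grid), length(x$q_grid)))
  cat(sprintf("  clonality index (10 - AUC of evenness): %.3f\n", x$clonality))
  invisible(x)
}
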