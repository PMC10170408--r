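# Internal numerical and validation helpers.

# The 20 standard amino acids (one-letter codes).
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' @keywords internal
#' @noRd
is_valid_aa <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
}

# Hurwitz zeta sum_{k>=0} (q + k)^(-a) by direct summation with an
# Euler-Maclaurin tail correction; accurate to ~1e-12 for a > 1.
#' @keywords internal
#' @noRd
hurwitz_zeta <- function(a, q, n_direct = 1000L) {
  stopifnot(a > 1, q > 0)
  k <- seq.int(0L, n_direct - 1L)
  head_sum <- sum((q + k)^(-a))
  m <- q + n_direct
  tail_sum <- m^(1 - a) / (a - 1) + 0.5 * m^(-a) + a * m^(-a - 1) / 12 -
    a * (a + 1) * (a + 2) * m^(-a - 3) / 720
  head_sum + tail_sum
}

# Composite Simpson's rule on an evenly spaced grid with an even number
# of intervals.
#' @keywords internal
#' @noRd
simpson_auc <- function(x, y) {
  n <- length(x)
  if (n < 3L) {
    stop("Simpson integration needs at least 3 grid points.", call. = FALSE)
  }
  if (n %% 2L == 0L) {
    stop("Simpson integration needs an even number of intervals (odd number of points).",
         call. = FALSE)
  }
  h <- diff(x)
  if (max(h) - min(h) > 1e-8 * max(h)) {
    stop("Simpson integration requires an evenly spaced grid.", call. = FALSE)
  }
  h <- (x[n] - x[1]) / (n - 1L)
  w <- rep(c(4, 2), length.out = n - 2L)
  h / 3 * (y[1] + y[n] + sum(w * y[2:(n - 1L)]))
}

#' @keywords internal
#' @noRd
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number.", name), call. = FALSE)
  }
  invisible(x)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a label.
#' @keywords internal
#' @noRd
derive_seed <- function(master_seed, label) {
  codes <- utf8ToInt(as.character(label))
  h <- as.double(master_seed %% 2147483647)
  for (cc in codes) {
    h <- (h * 31 + cc) %% 2147483647
  }
  as.integer(h)
}
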