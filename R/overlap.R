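#' Morisita-Horn index between two count vectors
#'
#' Abundance-weighted clonal overlap,
#' \deqn{MH = \frac{2\sum_i x_i y_i}{(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2)\, X Y}}
#' with \eqn{X = \sum_i x_i}, \eqn{Y = \sum_i y_i}. The index lives in
#' \[0, 1\]: exactly 1 when the frequency vectors are proportional and 0
#' when the supports are disjoint; it is invariant under proportional
#' rescaling of either vector.
#'
#' @param x,y Nonnegative counts aligned on a shared clone axis, each
#'   with a positive total.
#' @return Overlap value in \[0, 1\].
#' @examples
#' morisita_horn(c(2, 1), c(1, 1)) # 18/19
#' @export
morisita_horn <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must be aligned on the same clone axis.", call. = FALSE)
  }
  X <- sum(x)
  Y <- sum(y)
  if (X <= 0 || Y <= 0) {
    stop("Each count vector must have a positive total.", call. = FALSE)
  }
  fx <- x / X
  fy <- y / Y
  num <- 2 * sum(fx * fy)
  den <- sum(fx^2) + sum(fy^2)
  num / den
}

#' Pairwise Morisita-Horn overlap over a cohort
#'
#' Computes the full symmetric MHI matrix from the cohort's combined
#' clone-by-sample template table (via one sparse cross-product on the
#' per-sample frequency matrix) and labels every unordered pair with its
#' comparison class from the manifest: `within_lesion_replicate` (same
#' patient, same lesion, different aliquot),
#' `within_patient_between_lesion` (same patient, different lesion), or
#' `between_patient`.
#'
#' @param cohort A `tcr_cohort` with at least 2 samples.
#' @return An object of class `tcr_overlap`: list with `mhi` (dense
#'   symmetric matrix, unit diagonal), `pairs` (long tibble: `sample_a`,
#'   `sample_b`, `mhi`, `comparison_class`), and `class_summary` (mean,
#'   min, max, n per class).
#' @export
pairwise_mhi <- function(cohort) {
  m <- cohort$manifest
  if (nrow(m) < 2L) {
    stop("Pairwise overlap needs at least 2 samples.", call. = FALSE)
  }
  freqs <- cohort$counts %*% Matrix::Diagonal(x = 1 / Matrix::colSums(cohort$counts))
  cross <- as.matrix(Matrix::crossprod(freqs)) # sum_i f_x f_y
  simpson <- diag(cross)                        # sum_i f^2 per sample
  denom <- outer(simpson, simpson, `+`)
  mhi <- 2 * cross / denom
  diag(mhi) <- 1
  dimnames(mhi) <- list(m$sample_id, m$sample_id)

  idx <- which(upper.tri(mhi), arr.ind = TRUE)
  a <- idx[, 1]
  b <- idx[, 2]
  same_patient <- m$patient_id[a] == m$patient_id[b]
  same_lesion <- same_patient & m$lesion_id[a] == m$lesion_id[b]
  cls <- ifelse(same_lesion, "within_lesion_replicate",
                ifelse(same_patient, "within_patient_between_lesion",
                       "between_patient"))
  pairs <- tibble::tibble(
    sample_a = m$sample_id[a],
    sample_b = m$sample_id[b],
    mhi = mhi[idx],
    comparison_class = cls
  )
  class_summary <- pairs |>
    dplyr::group_by(.data$comparison_class) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$mhi),
                     min = min(.data$mhi), max = max(.data$mhi),
                     .groups = "drop")
  structure(list(mhi = mhi, pairs = pairs, class_summary = class_summary),
            class = "tcr_overlap")
}

#' @export
print.tcr_overlap <- function(x, ...) {
  cat(sprintf("Pairwise Morisita-Horn overlap: %d samples, %d pairs\n",
              nrow(x$mhi), nrow(x$pairs)))
  print(as.data.frame(x$class_summary), row.names = FALSE)
  invisible(x)
}
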