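# Mean DNA content of a diploid human cell, picograms.
PG_PER_GENOME <- 6.6

#' T-cell fraction from template counts and input DNA mass
#'
#' Each rearranged DNA template is taken as a proxy for one T cell. The
#' number of nucleated cell equivalents ("genomes") in the sample is the
#' input DNA mass divided by 6.6 pg per diploid genome, and the T-cell
#' fraction is templates / genomes.
#'
#' @param total_templates Total productive template count (>= 0).
#' @param input_dna_ng Input DNA mass in nanograms (> 0).
#' @return The T-cell fraction as a proportion. Values above 1 are
#'   possible only with implausible inputs and trigger a warning.
#' @examples
#' t_cell_fraction(8100, 660) # 660 ng -> 100,000 genomes -> 0.081
#' @export
t_cell_fraction <- function(total_templates, input_dna_ng) {
  assert_scalar_number(total_templates, "total_templates")
  assert_scalar_number(input_dna_ng, "input_dna_ng")
  if (input_dna_ng <= 0) {
    stop("`input_dna_ng` must be positive.", call. = FALSE)
  }
  if (total_templates < 0) {
    stop("`total_templates` must be nonnegative.", call. = FALSE)
  }
  genomes <- input_dna_ng * 1000 / PG_PER_GENOME
  fraction <- total_templates / genomes
  if (fraction > 1) {
    warning(sprintf("T-cell fraction %.3f exceeds 1; check template counts and DNA mass.",
                    fraction), call. = FALSE)
  }
  fraction
}

#' Sequencing coverage (reads per template)
#'
#' @param total_reads Total read count (>= 0).
#' @param total_templates Total template count (> 0).
#' @return Reads per template.
#' @export
sequencing_coverage <- function(total_reads, total_templates) {
  assert_scalar_number(total_reads, "total_reads")
  assert_scalar_number(total_templates, "total_templates")
  if (total_templates <= 0) {
    stop("Coverage is undefined for zero templates.", call. = FALSE)
  }
  total_reads / total_templates
}

#' Per-sample quantification table
#'
#' Computes genomes, T-cell fraction and sequencing coverage for every
#' sample in a cohort, and flags samples below the coverage threshold.
#'
#' @param cohort A `tcr_cohort` (the manifest supplies input DNA mass and
#'   totals).
#' @param min_coverage Coverage threshold below which a sample is flagged
#'   for exclusion (default 5 reads per template).
#' @return A tibble with columns `sample_id`, `patient_id`, `group`,
#'   `total_templates`, `total_reads`, `genomes`, `t_cell_fraction`,
#'   `coverage`, `included`.
#' @export
quantify_samples <- function(cohort, min_coverage = 5) {
  m <- cohort$manifest
  genomes <- m$input_dna_ng * 1000 / PG_PER_GENOME
  coverage <- m$total_reads / m$total_templates
  tibble::tibble(
    sample_id = m$sample_id,
    patient_id = m$patient_id,
    group = m$group,
    total_templates = m$total_templates,
    total_reads = m$total_reads,
    genomes = genomes,
    t_cell_fraction = m$total_templates / genomes,
    coverage = coverage,
    included = coverage >= min_coverage
  )
}

#' Coverage-based cohort QC filter
#'
#' Removes samples whose sequencing coverage (reads per template) falls
#' below the threshold, to avoid bias from low-frequency clones, and
#' reports every exclusion. Retained samples' counts are untouched.
#'
#' @param cohort A `tcr_cohort`.
#' @param min_coverage Threshold, default 5.
#' @return A list with `cohort` (the retained `tcr_cohort`; empty cohort
#'   allowed) and `exclusions` (tibble of `sample_id`, `coverage`).
#' @export
qc_filter <- function(cohort, min_coverage = 5) {
  quant <- quantify_samples(cohort, min_coverage = min_coverage)
  excluded <- quant[!quant$included, c("sample_id", "coverage")]
  retained <- quant$sample_id[quant$included]
  list(
    cohort = subset_cohort(cohort, retained),
    exclusions = excluded
  )
}

#' Pick one dataset per patient
#'
#' For analyses that require one repertoire per patient (such as the
#' T-cell fraction comparison), selects for each patient the replicate
#' with the highest sequencing coverage; ties break on sample_id order
#' for determinism.
#'
#' @param cohort A `tcr_cohort`.
#' @return Character vector of selected sample_ids, one per patient.
#' @export
select_one_per_patient <- function(cohort) {
  quant <- quantify_samples(cohort)
  quant |>
    dplyr::arrange(.data$patient_id, dplyr::desc(.data$coverage), .data$sample_id) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::pull(.data$sample_id)
}
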