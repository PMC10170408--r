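#' Column dialect for rearrangement files
#'
#' Maps the logical columns the pipeline needs (CDR3 amino-acid sequence,
#' template count, read count, frame/productivity, V and J labels) onto
#' the header names of a particular vendor export. The default mirrors
#' immunoSEQ v2 rearrangement exports; unknown extra columns in a file
#' are ignored.
#'
#' @param cdr3_aa,templates,reads,frame,v_gene,j_gene Header names in the
#'   file. `cdr3_aa`, `templates` and `frame` are required at read time;
#'   the others fall back to defaults when absent.
#' @return A named list of class `tcr_dialect`.
#' @export
immunoseq_dialect <- function(cdr3_aa = "amino_acid",
                              templates = "templates",
                              reads = "seq_reads",
                              frame = "frame_type",
                              v_gene = "v_resolved",
                              j_gene = "j_resolved") {
  structure(
    list(cdr3_aa = cdr3_aa, templates = templates, reads = reads,
         frame = frame, v_gene = v_gene, j_gene = j_gene),
    class = "tcr_dialect"
  )
}

#' Collapse raw rearrangement rows into clonotype records
#'
#' Rows sharing one CDR3 amino-acid sequence are merged into a single
#' clonotype (identical sequence implies identical length): template and
#' read counts are summed and the V/J labels of the highest-template row
#' are kept. Collapsing is idempotent.
#'
#' @param rows A data frame with columns `cdr3_aa`, `templates`, `reads`,
#'   `productive`, and optionally `v_gene`, `j_gene`.
#' @return A tibble with one row per distinct `cdr3_aa`, ordered by
#'   decreasing templates then sequence.
#' @export
collapse_clonotypes <- function(rows) {
  rows <- tibble::as_tibble(rows)
  if (!all(c("cdr3_aa", "templates") %in% names(rows))) {
    stop("`rows` must have columns `cdr3_aa` and `templates`.", call. = FALSE)
  }
  if (!"reads" %in% names(rows)) rows$reads <- 0L
  if (!"productive" %in% names(rows)) rows$productive <- TRUE
  if (!"v_gene" %in% names(rows)) rows$v_gene <- NA_character_
  if (!"j_gene" %in% names(rows)) rows$j_gene <- NA_character_

  bad <- which(!is.finite(rows$templates) | rows$templates < 1)
  if (length(bad) > 0L) {
    stop(sprintf("Template count must be a positive integer (first offending row: %d).",
                 bad[1]), call. = FALSE)
  }
  if (any(!is.finite(rows$reads) | rows$reads < 0)) {
    stop("Read counts must be nonnegative.", call. = FALSE)
  }

  dt <- data.table::as.data.table(
    rows[, c("cdr3_aa", "templates", "reads", "productive", "v_gene", "j_gene")]
  )
  # order so that the first row of each group is the highest-template one
  data.table::setorderv(dt, c("cdr3_aa", "templates"), order = c(1L, -1L))
  agg <- dt[, list(templates = sum(templates), reads = sum(reads),
                   productive = all(productive),
                   v_gene = v_gene[1L], j_gene = j_gene[1L]),
            by = "cdr3_aa"]
  data.table::setorderv(agg, c("templates", "cdr3_aa"), order = c(-1L, 1L))
  tibble::as_tibble(agg)
}

#' Construct a repertoire object from clonotype records
#'
#' @param records Collapsed clonotype tibble (see [collapse_clonotypes()]).
#' @param sample_id,patient_id,lesion_id,aliquot_id Identifiers.
#' @param group NACT exposure group: one of `"no_nact"`,
#'   `"short_interval"`, `"long_interval"`, or `NA`.
#' @param input_dna_ng Input DNA mass in nanograms (optional until
#'   quantification).
#' @return An object of class `tcr_repertoire`.
#' @export
new_repertoire <- function(records, sample_id,
                           patient_id = NA_character_,
                           lesion_id = NA_character_,
                           aliquot_id = NA_character_,
                           group = NA_character_,
                           input_dna_ng = NA_real_) {
  if (anyDuplicated(records$cdr3_aa) > 0L) {
    stop("Clonotype sequences must be unique after collapsing.", call. = FALSE)
  }
  if (!is.na(group) && !group %in% c("no_nact", "short_interval", "long_interval")) {
    stop("`group` must be no_nact, short_interval or long_interval.", call. = FALSE)
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      patient_id = as.character(patient_id),
      lesion_id = as.character(lesion_id),
      aliquot_id = as.character(aliquot_id),
      group = group,
      input_dna_ng = input_dna_ng,
      records = tibble::as_tibble(records),
      total_templates = sum(records$templates),
      total_reads = sum(records$reads)
    ),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire '%s' (patient %s, group %s)\n",
              x$sample_id, x$patient_id, x$group))
  cat(sprintf("  %d clonotypes, %d templates, %d reads\n",
              nrow(x$records), x$total_templates, x$total_reads))
  invisible(x)
}

#' Read an immunoSEQ-style rearrangement file
#'
#' Parses one tab-separated rearrangement file into a [tcr_repertoire]
#' object: sequences are uppercased, any sequence containing characters
#' outside the 20-letter amino-acid alphabet (stop codons `*`, frameshift
#' marks, ambiguity codes) is marked nonproductive, rows are collapsed to
#' clonotypes, and totals recomputed. By default only productive
#' rearrangements (frame "In", no invalid characters) are retained, since
#' all downstream analyses operate on productive templates.
#'
#' @param path Path to the TSV file.
#' @param dialect Column-name mapping; see [immunoseq_dialect()].
#' @param productive_only Drop nonproductive rows (default `TRUE`).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @inheritParams new_repertoire
#' @return A `tcr_repertoire`.
#' @export
read_rearrangement_file <- function(path, dialect = immunoseq_dialect(),
                                    productive_only = TRUE,
                                    sample_id = NULL,
                                    patient_id = NA_character_,
                                    lesion_id = NA_character_,
                                    aliquot_id = NA_character_,
                                    group = NA_character_,
                                    input_dna_ng = NA_real_) {
  if (!file.exists(path)) {
    stop(sprintf("Rearrangement file not found: %s", path), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("cdr3_aa", "templates", "frame")) {
    if (!dialect[[col]] %in% names(raw)) {
      stop(sprintf("Required column '%s' (logical field '%s') missing from %s.",
                   dialect[[col]], col, path), call. = FALSE)
    }
  }
  rows <- tibble::tibble(
    cdr3_aa = toupper(as.character(raw[[dialect$cdr3_aa]])),
    templates = as.numeric(raw[[dialect$templates]]),
    reads = if (dialect$reads %in% names(raw)) as.numeric(raw[[dialect$reads]]) else 0,
    frame = as.character(raw[[dialect$frame]]),
    v_gene = if (dialect$v_gene %in% names(raw)) as.character(raw[[dialect$v_gene]]) else NA_character_,
    j_gene = if (dialect$j_gene %in% names(raw)) as.character(raw[[dialect$j_gene]]) else NA_character_
  )
  rows$productive <- rows$frame %in% c("In", "in", "IN") & is_valid_aa(rows$cdr3_aa)
  if (productive_only) {
    rows <- rows[rows$productive, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop(sprintf("No productive rearrangements in %s.", path), call. = FALSE)
    }
  }
  records <- collapse_clonotypes(rows[, c("cdr3_aa", "templates", "reads",
                                          "productive", "v_gene", "j_gene")])
  new_repertoire(records, sample_id = sample_id, patient_id = patient_id,
                 lesion_id = lesion_id, aliquot_id = aliquot_id,
                 group = group, input_dna_ng = input_dna_ng)
}

#' Write a repertoire back to a rearrangement TSV
#'
#' Emits the same dialect [read_rearrangement_file()] reads, one row per
#' collapsed clonotype, so that a read/write round trip preserves
#' clonotype counts exactly.
#'
#' @param repertoire A `tcr_repertoire`.
#' @param path Output file path.
#' @param dialect Column-name mapping.
#' @return `path`, invisibly.
#' @export
write_rearrangement_file <- function(repertoire, path,
                                     dialect = immunoseq_dialect()) {
  rec <- repertoire$records
  out <- tibble::tibble(
    a = rec$cdr3_aa,
    b = rec$templates,
    c = rec$reads,
    d = ifelse(rec$productive, "In", "Out"),
    e = rec$v_gene,
    f = rec$j_gene
  )
  names(out) <- unlist(dialect[c("cdr3_aa", "templates", "reads",
                                 "frame", "v_gene", "j_gene")])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample manifest CSV
#'
#' @param path CSV with columns `sample_id`, `patient_id`, `lesion_id`,
#'   `aliquot_id`, `group`, `input_dna_ng` and optionally `file`.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  manifest <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "patient_id", "lesion_id", "aliquot_id",
                "group", "input_dna_ng")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0L) {
    stop(sprintf("Manifest is missing columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$sample_id) > 0L) {
    stop("Manifest sample_ids must be unique.", call. = FALSE)
  }
  manifest
}

#' Combine repertoires into a cohort table
#'
#' Builds the combined rearrangement table: the union of all distinct
#' clonotype sequences as rows, one column of template counts per sample
#' (zero where a clone is absent), plus the per-sample manifest. Column
#' sums equal each repertoire's total productive templates.
#'
#' @param repertoires List of `tcr_repertoire` objects with unique
#'   `sample_id`s.
#' @return An object of class `tcr_cohort`: a list with `counts` (sparse
#'   clones-by-samples `dgCMatrix`), `clones` (character vector, row
#'   names), and `manifest` (per-sample tibble, including per-sample
#'   totals).
#' @export
build_cohort_table <- function(repertoires) {
  if (length(repertoires) == 0L) {
    stop("Need at least one repertoire.", call. = FALSE)
  }
  ids <- vapply(repertoires, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids) > 0L) {
    stop(sprintf("Duplicate sample_id: %s", ids[duplicated(ids)][1]), call. = FALSE)
  }
  long <- data.table::rbindlist(lapply(repertoires, function(r) {
    data.table::data.table(sample_id = r$sample_id,
                           cdr3_aa = r$records$cdr3_aa,
                           templates = r$records$templates)
  }))
  clones <- sort(unique(long$cdr3_aa))
  counts <- Matrix::sparseMatrix(
    i = match(long$cdr3_aa, clones),
    j = match(long$sample_id, ids),
    x = long$templates,
    dims = c(length(clones), length(ids)),
    dimnames = list(clones, ids)
  )
  manifest <- tibble::tibble(
    sample_id = ids,
    patient_id = vapply(repertoires, function(r) r$patient_id, character(1)),
    lesion_id = vapply(repertoires, function(r) r$lesion_id, character(1)),
    aliquot_id = vapply(repertoires, function(r) r$aliquot_id, character(1)),
    group = vapply(repertoires, function(r) as.character(r$group), character(1)),
    input_dna_ng = vapply(repertoires, function(r) r$input_dna_ng, numeric(1)),
    total_templates = vapply(repertoires, function(r) as.numeric(r$total_templates), numeric(1)),
    total_reads = vapply(repertoires, function(r) as.numeric(r$total_reads), numeric(1))
  )
  structure(
    list(counts = counts, clones = clones, manifest = manifest),
    class = "tcr_cohort"
  )
}

#' @export
print.tcr_cohort <- function(x, ...) {
  cat(sprintf("TCR cohort table: %d clones x %d samples (%d patients)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$manifest$patient_id))))
  invisible(x)
}

#' Subset a cohort table by sample
#'
#' Keeps the requested samples and drops clones absent from all of them.
#'
#' @param cohort A `tcr_cohort`.
#' @param sample_ids Samples to keep.
#' @return A `tcr_cohort`.
#' @export
subset_cohort <- function(cohort, sample_ids) {
  keep <- cohort$manifest$sample_id %in% sample_ids
  if (!any(keep)) {
    counts <- cohort$counts[, 0, drop = FALSE]
    return(structure(list(counts = counts[0, , drop = FALSE], clones = character(0),
                          manifest = cohort$manifest[keep, ]),
                     class = "tcr_cohort"))
  }
  counts <- cohort$counts[, keep, drop = FALSE]
  present <- Matrix::rowSums(counts) > 0
  structure(
    list(counts = counts[present, , drop = FALSE],
         clones = cohort$clones[present],
         manifest = cohort$manifest[keep, ]),
    class = "tcr_cohort"
  )
}

#' Write the combined cohort table as a wide TSV
#'
#' One row per clone, one template-count column per sample. Intended for
#' modest cohorts; large cohorts are better kept sparse in memory.
#'
#' @param cohort A `tcr_cohort`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  wide <- as.data.frame(as.matrix(cohort$counts))
  wide <- cbind(cdr3_aa = rownames(wide), wide)
  readr::write_tsv(tibble::as_tibble(wide), path, progress = FALSE)
  invisible(path)
}
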