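#' Load a cohort from rearrangement files and a manifest
#'
#' Reads every sample listed in the manifest (the `file` column is
#' resolved relative to the manifest's directory unless absolute) and
#' assembles the combined cohort table.
#'
#' @param manifest_path Manifest CSV path; see [read_manifest()]. Must
#'   also carry a `file` column naming each sample's rearrangement TSV.
#' @param dialect Column dialect for the rearrangement files.
#' @param productive_only Keep only productive rearrangements.
#' @return A `tcr_cohort`.
#' @export
load_cohort <- function(manifest_path, dialect = immunoseq_dialect(),
                        productive_only = TRUE) {
  manifest <- read_manifest(manifest_path)
  if (!"file" %in% names(manifest)) {
    stop("Manifest must carry a `file` column naming each rearrangement file.",
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  reps <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    path <- if (grepl("^/", m$file)) m$file else file.path(base, m$file)
    read_rearrangement_file(
      path, dialect = dialect, productive_only = productive_only,
      sample_id = m$sample_id, patient_id = m$patient_id,
      lesion_id = m$lesion_id, aliquot_id = m$aliquot_id,
      group = m$group, input_dna_ng = m$input_dna_ng
    )
  })
  build_cohort_table(reps)
}

#' Run the full repertoire analysis pipeline
#'
#' Orchestrates every stage on a cohort: per-sample quantification and
#' the coverage QC filter; diversity/evenness profiles and clonality on
#' the retained samples; per-sample LD=1 networks with power-law
#' goodness-of-fit; the cohort sharing index, degree-versus-sharing
#' table and public/private subsampled class connectivity; pairwise
#' Morisita-Horn overlap with comparison classes; group comparisons
#' (T-cell fraction on one dataset per patient, clonality on retained
#' samples) and the two regressions (clonality vs T-cell count,
#' connectivity fraction vs clone count); and, when a pathology database
#' is supplied, top-decile database matching. All outputs are written as
#' CSVs under `out_dir` and returned invisibly.
#'
#' @param cohort A `tcr_cohort` (e.g. from [load_cohort()] or
#'   [build_cohort_table()] on a synthetic cohort).
#' @param out_dir Output directory for the report bundle; `NULL` skips
#'   writing.
#' @param min_coverage Coverage threshold for the QC filter.
#' @param q_grid Diversity-order grid.
#' @param n_sub Class-connectivity subsample size.
#' @param n_boot Power-law bootstrap replicates per sample (0 skips the
#'   goodness-of-fit stage).
#' @param pathology_db Optional pathology database tibble from
#'   [read_pathology_db()]; skipped with a warning when `NULL`.
#' @param top_frac Decile fraction for pathology matching.
#' @param seed Master seed for subsampling and bootstrap stages;
#'   per-sample seeds are derived from it and the sample id.
#' @return Invisibly, a list of tibbles: `quantification`, `exclusions`,
#'   `clonality`, `diversity_profiles`, `network_summary`,
#'   `powerlaw_fits`, `sharing_summary`, `degree_vs_sharing`,
#'   `class_connectivity`, `pathology`, `mhi`, `group_tests`,
#'   `regressions`.
#' @export
run_repertoire_pipeline <- function(cohort, out_dir = NULL,
                                    min_coverage = 5,
                                    q_grid = seq(0, 10, by = 0.2),
                                    n_sub = 1000L,
                                    n_boot = 200L,
                                    pathology_db = NULL,
                                    top_frac = 0.10,
                                    seed = 1L) {
  # --- quantification (all samples; fraction analysis is one per patient)
  quant <- quantify_samples(cohort, min_coverage = min_coverage)
  qc <- qc_filter(cohort, min_coverage = min_coverage)
  retained <- qc$cohort
  if (nrow(retained$manifest) == 0L) {
    stop("QC filter removed every sample; nothing to analyze.", call. = FALSE)
  }

  one_per_patient <- select_one_per_patient(cohort)
  fraction_tbl <- quant[quant$sample_id %in% one_per_patient, ]

  # --- diversity / clonality on retained samples
  reps <- split_cohort(retained)
  clonality <- dplyr::bind_rows(lapply(reps, function(r) {
    prof <- diversity_profile(r$templates, q_grid = q_grid)
    tibble::tibble(sample_id = r$sample_id, group = r$group,
                   richness = prof$SR, total_templates = sum(r$templates),
                   clonality = prof$clonality)
  }))
  profiles <- dplyr::bind_rows(lapply(reps, function(r) {
    prof <- diversity_profile(r$templates, q_grid = q_grid)
    tibble::tibble(sample_id = r$sample_id, q = prof$q_grid,
                   D = prof$D, E = prof$E)
  }))

  # --- per-sample LD=1 networks
  networks <- lapply(reps, function(r) build_ld1_network(r$cdr3_aa))
  names(networks) <- vapply(reps, function(r) r$sample_id, character(1))
  network_summary <- dplyr::bind_rows(lapply(names(networks), function(sid) {
    net <- networks[[sid]]
    tibble::tibble(sample_id = sid, n_nodes = net$n_nodes,
                   n_edges = as.integer(net$n_edges),
                   connectivity_fraction = net$connectivity_fraction)
  }))

  powerlaw_fits <- tibble::tibble()
  if (n_boot > 0L) {
    powerlaw_fits <- dplyr::bind_rows(lapply(names(networks), function(sid) {
      deg <- networks[[sid]]$degree
      deg <- deg[deg >= 1]
      fit <- tryCatch(
        powerlaw_gof(deg, n_boot = n_boot, seed = derive_seed(seed, sid)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        tibble::tibble(sample_id = sid, xmin = NA_integer_, alpha = NA_real_,
                       ks = NA_real_, gof_p = NA_real_, plausible = NA)
      } else {
        tibble::tibble(sample_id = sid, xmin = fit$xmin, alpha = fit$alpha,
                       ks = fit$ks, gof_p = fit$gof_p, plausible = fit$plausible)
      }
    }))
  }

  # --- sharing and public/private stratification
  sharing <- sharing_index(retained)
  sharing_summary <- tibble::tibble(
    n_clones = nrow(sharing),
    n_public = sum(sharing$public),
    pct_public = 100 * mean(sharing$public),
    pct_private = 100 * mean(!sharing$public)
  )
  dvs <- degree_vs_sharing(networks, sharing)
  class_conn <- dplyr::bind_rows(lapply(reps, function(r) {
    rep_obj <- new_repertoire(
      tibble::tibble(cdr3_aa = r$cdr3_aa, templates = r$templates,
                     reads = 0L, productive = TRUE,
                     v_gene = NA_character_, j_gene = NA_character_),
      sample_id = r$sample_id, group = r$group
    )
    cc <- class_connectivity(rep_obj, sharing, n_sub = n_sub,
                             seed = derive_seed(seed, r$sample_id))
    dplyr::mutate(cc, sample_id = r$sample_id, .before = 1)
  }))

  # --- pathology matching (optional)
  pathology <- NULL
  if (!is.null(pathology_db)) {
    pathology <- dplyr::bind_rows(lapply(reps, function(r) {
      rep_obj <- new_repertoire(
        tibble::tibble(cdr3_aa = r$cdr3_aa, templates = r$templates,
                       reads = 0L, productive = TRUE,
                       v_gene = NA_character_, j_gene = NA_character_),
        sample_id = r$sample_id, group = r$group
      )
      pm <- pathology_match(rep_obj, networks[[r$sample_id]], sharing,
                            pathology_db, top_frac = top_frac)
      tibble::tibble(sample_id = r$sample_id,
                     connected_public_fraction = pm$connected_public_fraction,
                     expanded_fraction = pm$expanded_fraction,
                     n_connected_public = pm$n_connected_public,
                     n_expanded = pm$n_expanded)
    }))
  } else {
    warning("No pathology database supplied; skipping database matching.",
            call. = FALSE)
  }

  # --- overlap
  overlap <- pairwise_mhi(retained)

  # --- cohort statistics
  frac_cmp <- group_comparison(fraction_tbl$t_cell_fraction, fraction_tbl$group)
  clon_cmp <- group_comparison(clonality$clonality, clonality$group)
  group_tests <- dplyr::bind_rows(
    dplyr::mutate(frac_cmp$tests, statistic = "t_cell_fraction", .before = 1),
    dplyr::mutate(clon_cmp$tests, statistic = "clonality", .before = 1)
  )
  group_summaries <- dplyr::bind_rows(
    dplyr::mutate(frac_cmp$summary, statistic = "t_cell_fraction", .before = 1),
    dplyr::mutate(clon_cmp$summary, statistic = "clonality", .before = 1)
  )
  reg1 <- ols_fit(clonality$total_templates, clonality$clonality)
  conn_tbl <- dplyr::inner_join(network_summary, clonality, by = "sample_id")
  reg2 <- ols_fit(conn_tbl$richness, conn_tbl$connectivity_fraction)
  regressions <- tibble::tibble(
    model = c("clonality_vs_t_cells", "connectivity_vs_clones"),
    slope = c(reg1$slope, reg2$slope),
    intercept = c(reg1$intercept, reg2$intercept),
    slope_lo = c(reg1$slope_ci[1], reg2$slope_ci[1]),
    slope_hi = c(reg1$slope_ci[2], reg2$slope_ci[2]),
    r_squared = c(reg1$r_squared, reg2$r_squared)
  )

  results <- list(
    quantification = quant,
    fraction_one_per_patient = fraction_tbl,
    exclusions = qc$exclusions,
    clonality = clonality,
    diversity_profiles = profiles,
    network_summary = network_summary,
    powerlaw_fits = powerlaw_fits,
    sharing_summary = sharing_summary,
    degree_vs_sharing = dvs,
    class_connectivity = class_conn,
    pathology = pathology,
    mhi_pairs = overlap$pairs,
    mhi_class_summary = overlap$class_summary,
    group_summaries = group_summaries,
    group_tests = group_tests,
    regressions = regressions
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(results)) {
      tbl <- results[[nm]]
      if (!is.null(tbl) && is.data.frame(tbl) && ncol(tbl) > 0) {
        readr::write_csv(tbl, file.path(out_dir, paste0(nm, ".csv")),
                         progress = FALSE)
      }
    }
    cfg <- list(min_coverage = min_coverage, q_grid = range(q_grid),
                q_step = diff(q_grid)[1], n_sub = n_sub, n_boot = n_boot,
                top_frac = top_frac, seed = seed)
    writeLines(
      paste(names(cfg), vapply(cfg, function(v) paste(v, collapse = ","),
                               character(1)), sep = "="),
      file.path(out_dir, "run_config.txt")
    )
  }
  invisible(results)
}

# Split a cohort table back into lightweight per-sample clone lists.
#' @keywords internal
#' @noRd
split_cohort <- function(cohort) {
  tm <- Matrix::summary(cohort$counts)
  dt <- data.table::data.table(i = tm$i, j = tm$j, x = tm$x)
  data.table::setorder(dt, j, i)
  m <- cohort$manifest
  lapply(seq_len(nrow(m)), function(jj) {
    sub <- dt[dt$j == jj]
    list(sample_id = m$sample_id[jj], group = m$group[jj],
         patient_id = m$patient_id[jj],
         cdr3_aa = cohort$clones[sub$i], templates = sub$x)
  })
}
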