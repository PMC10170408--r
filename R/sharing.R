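#' Cohort-wide clonotype sharing index
#'
#' For every clonotype detected anywhere in the cohort, counts the number
#' of distinct patients in whom it was detected (the sharing level);
#' replicate aliquots and multiple lesions of one patient count once. A
#' clone is "public" when detected in more than one patient and "private"
#' otherwise.
#'
#' @param cohort A `tcr_cohort` whose manifest provides `patient_id`.
#' @return A tibble with columns `cdr3_aa`, `sharing_level`, `public`,
#'   ordered by decreasing sharing level.
#' @export
sharing_index <- function(cohort) {
  cm <- cohort$counts
  patient <- cohort$manifest$patient_id
  tm <- Matrix::summary(cm) # i (clone), j (sample), x (templates)
  dt <- data.table::data.table(clone = tm$i, patient = patient[tm$j])
  sh <- dt[, list(sharing_level = data.table::uniqueN(patient)), by = "clone"]
  out <- tibble::tibble(
    cdr3_aa = cohort$clones[sh$clone],
    sharing_level = sh$sharing_level,
    public = sh$sharing_level > 1L
  )
  out[order(-out$sharing_level, out$cdr3_aa), ]
}

#' Mean network degree by sharing level
#'
#' Joins each clone's degree in its home repertoire's LD=1 network with
#' its cohort-wide sharing level, then summarises mean degree with a
#' t-based 95% confidence interval per sharing level. A clone present in
#' several repertoires contributes one observation per repertoire.
#'
#' @param networks Named list of `tcr_network`, one per sample (names are
#'   sample_ids).
#' @param sharing Sharing-index tibble from [sharing_index()].
#' @return A tibble with `sharing_level`, `n`, `mean_degree`, `ci_lo`,
#'   `ci_hi` (CI is `NA` when a level has a single observation).
#' @export
degree_vs_sharing <- function(networks, sharing) {
  if (length(networks) == 0L) {
    return(tibble::tibble(sharing_level = integer(0), n = integer(0),
                          mean_degree = numeric(0), ci_lo = numeric(0),
                          ci_hi = numeric(0)))
  }
  deg <- data.table::rbindlist(lapply(networks, function(net) {
    data.table::data.table(cdr3_aa = names(net$degree), degree = as.numeric(net$degree))
  }))
  sh <- data.table::as.data.table(sharing[, c("cdr3_aa", "sharing_level")])
  deg <- merge(deg, sh, by = "cdr3_aa")
  agg <- deg[, list(n = .N, mean_degree = mean(degree), sd_degree = stats::sd(degree)),
             by = "sharing_level"][order(sharing_level)]
  half <- ifelse(agg$n > 1,
                 stats::qt(0.975, agg$n - 1) * agg$sd_degree / sqrt(agg$n),
                 NA_real_)
  tibble::tibble(
    sharing_level = agg$sharing_level,
    n = agg$n,
    mean_degree = agg$mean_degree,
    ci_lo = agg$mean_degree - half,
    ci_hi = agg$mean_degree + half
  )
}

#' Public vs private connectivity on subsampled class networks
#'
#' Splits one repertoire's clones into public and private by the cohort
#' sharing index, subsamples each class to `n_sub` clones (uniformly,
#' without replacement; the whole class is used with a flag when it is
#' smaller), builds an LD=1 network within each class sample, and returns
#' the class connectivity fractions. Subsampling compensates for the
#' numerical overrepresentation of private clones.
#'
#' @param repertoire A `tcr_repertoire`.
#' @param sharing Sharing-index tibble from [sharing_index()].
#' @param n_sub Clones per class (default 1000).
#' @param seed Optional RNG seed; identical seeds reproduce the sample.
#' @return A tibble with one row per class: `class`, `n_clones` (class
#'   size), `n_used`, `subsampled` (flag), `n_edges`,
#'   `connectivity_fraction` (`NA` for an empty class).
#' @export
class_connectivity <- function(repertoire, sharing, n_sub = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pub_set <- sharing$cdr3_aa[sharing$public]
  seqs <- repertoire$records$cdr3_aa
  classes <- list(public = seqs[seqs %in% pub_set],
                  private = seqs[!seqs %in% pub_set])
  rows <- lapply(names(classes), function(cl) {
    members <- classes[[cl]]
    if (length(members) == 0L) {
      return(tibble::tibble(class = cl, n_clones = 0L, n_used = 0L,
                            subsampled = FALSE, n_edges = NA_integer_,
                            connectivity_fraction = NA_real_))
    }
    subsampled <- length(members) > n_sub
    used <- if (subsampled) sample(members, n_sub) else members
    net <- build_ld1_network(used)
    tibble::tibble(class = cl, n_clones = length(members),
                   n_used = length(used), subsampled = subsampled,
                   n_edges = as.integer(net$n_edges),
                   connectivity_fraction = net$connectivity_fraction)
  })
  dplyr::bind_rows(rows)
}

#' Read a pathology-associated TCR database
#'
#' Expects a McPAS-like CSV with at least a CDR3 beta-chain column, a
#' species column, and a pathology column; rows are filtered to human
#' TCR-beta entries with valid amino-acid sequences.
#'
#' @param path CSV path.
#' @param cdr3_col,species_col,pathology_col Column names (McPAS-like
#'   defaults).
#' @param species Value of the species column to retain (default
#'   `"Human"`; set `NULL` to keep all).
#' @return A tibble with columns `cdr3_aa`, `pathology`.
#' @export
read_pathology_db <- function(path, cdr3_col = "CDR3.beta.aa",
                              species_col = "Species",
                              pathology_col = "Pathology",
                              species = "Human") {
  db <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(cdr3_col, pathology_col)) {
    if (!col %in% names(db)) {
      stop(sprintf("Pathology database is missing column '%s'.", col), call. = FALSE)
    }
  }
  out <- tibble::tibble(
    cdr3_aa = toupper(as.character(db[[cdr3_col]])),
    pathology = as.character(db[[pathology_col]])
  )
  if (!is.null(species) && species_col %in% names(db)) {
    out <- out[db[[species_col]] %in% species, ]
  }
  out <- out[is_valid_aa(out$cdr3_aa), ]
  out <- unique(out)
  if (nrow(out) == 0L) {
    stop("Pathology database is empty after filtering.", call. = FALSE)
  }
  out
}

#' Match top clones against a pathology-associated TCR database
#'
#' Defines two clone sets within a repertoire: set A, the union of the
#' top decile by network degree and the top decile by sharing level
#' ("highest connectivity and/or sharing"), and set B, the top decile by
#' template count (most clonally expanded). Each set is matched against
#' the database at exact sequence identity (LD = 0). Decile ranks break
#' ties by lexicographic sequence order for reproducibility.
#'
#' @param repertoire A `tcr_repertoire`.
#' @param network The repertoire's `tcr_network`.
#' @param sharing Sharing-index tibble from [sharing_index()].
#' @param db Pathology database tibble from [read_pathology_db()].
#' @param top_frac Decile fraction (default 0.10).
#' @return A list with `connected_public_fraction`, `expanded_fraction`
#'   (matched fractions of sets A and B), `n_connected_public`,
#'   `n_expanded` (set sizes), and `pathology_counts` (tibble of
#'   pathology tallies among set-A matches).
#' @export
pathology_match <- function(repertoire, network, sharing, db, top_frac = 0.10) {
  if (nrow(db) == 0L) {
    stop("Pathology database is empty.", call. = FALSE)
  }
  rec <- repertoire$records
  deg <- network$degree[rec$cdr3_aa]
  deg[is.na(deg)] <- 0
  sh <- sharing$sharing_level[match(rec$cdr3_aa, sharing$cdr3_aa)]
  sh[is.na(sh)] <- 1L

  top_by <- function(score) {
    k <- max(1L, ceiling(top_frac * nrow(rec)))
    ord <- order(-score, rec$cdr3_aa)
    rec$cdr3_aa[ord[seq_len(k)]]
  }
  set_a <- union(top_by(deg), top_by(sh))
  set_b <- top_by(rec$templates)

  db_seqs <- unique(db$cdr3_aa)
  match_a <- set_a[set_a %in% db_seqs]
  match_b <- set_b[set_b %in% db_seqs]
  tallies <- db[db$cdr3_aa %in% match_a, ] |>
    dplyr::count(.data$pathology, name = "n", sort = TRUE)
  list(
    connected_public_fraction = length(match_a) / length(set_a),
    expanded_fraction = length(match_b) / length(set_b),
    n_connected_public = length(set_a),
    n_expanded = length(set_b),
    pathology_counts = tallies
  )
}
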