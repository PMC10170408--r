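# Synthetic cohort generator. Emulates the group structure of a
# three-arm NACT cohort of colorectal liver metastases: per-group T-cell
# fractions, power-law clone abundances tuned per group so the evenness
# clonality separates NACT from no-NACT arms, a shared public clone pool
# organised in LD=1 motif clusters, and replicate aliquot / second-lesion
# samples for overlap calibration. Every emitted clone is traceable to a
# provenance record (public pool cluster or private).

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the emulated study conditions: 35/35/15 samples in the
#' no-NACT, short-interval and long-interval groups; log-normal per-group
#' T-cell fraction distributions with means 6.3%, 10.6% and 6.2%;
#' per-group discrete power-law clone-abundance exponents calibrated so
#' that mean evenness clonality is about 5.0 in the no-NACT arm and 5.7
#' to 5.8 in the NACT arms; per-sample richness uniform on 1,500-20,000
#' clones; a cohort-wide public pool of LD=1 motif clusters sized so that
#' roughly 5-10% of detected cohort clones are public; CDR3 lengths
#' normal(15, 2) truncated to 8-25; log-normal reads-per-template with
#' median 9 so that a handful of samples in a cohort of this size fall
#' below the coverage-5 QC threshold; and a replicate plan of 3 aliquot
#' pairs and 4 second-lesion pairs.
#'
#' @param n_per_group Named sample counts per group.
#' @param fraction_mean Named per-group mean T-cell fractions.
#' @param fraction_sdlog Log-scale SD of the per-sample fraction draw.
#' @param abundance_exponent Named per-group discrete power-law exponents
#'   for clone template counts (smaller = heavier tail = more clonal).
#' @param abundance_xmin Lower bound of the clone template-count power
#'   law; 5 templates per clone keeps per-sample template depth and
#'   replicate reproducibility in a realistic range.
#' @param richness_range Per-sample unique-clone range (uniform draw).
#' @param pool_clusters,cluster_size Public pool geometry: number of
#'   motif clusters and sequences per cluster (one seed plus
#'   single-substitution mutants).
#' @param public_rate Fraction of a sample's clones drawn from the
#'   public pool.
#' @param member_prob Probability that each member of a sampled cluster
#'   enters the repertoire (controls within-sample cluster co-occurrence
#'   and hence public connectivity).
#' @param cdr3_length_mean,cdr3_length_sd,cdr3_length_range CDR3
#'   amino-acid length distribution (truncated normal; bounds must lie in
#'   8-25).
#' @param reads_meanlog,reads_sdlog Log-normal reads-per-template draw.
#' @param n_aliquot_pairs Patients with a second aliquot of one lesion.
#' @param n_lesion_pairs Patients with a second, partially shared lesion.
#' @param lesion_share Fraction of the first lesion's clones carried into
#'   the second lesion (with their template counts).
#' @param seed Master RNG seed; identical configs and seeds reproduce
#'   byte-identical cohorts.
#' @return A list of class `tcr_sim_config`.
#' @export
cohort_config <- function(n_per_group = c(no_nact = 35, short_interval = 35,
                                          long_interval = 15),
                          fraction_mean = c(no_nact = 0.063,
                                            short_interval = 0.106,
                                            long_interval = 0.062),
                          fraction_sdlog = 0.4,
                          abundance_exponent = c(no_nact = 4.53,
                                                 short_interval = 4.08,
                                                 long_interval = 4.14),
                          abundance_xmin = 5L,
                          richness_range = c(1500, 20000),
                          pool_clusters = 20000L,
                          cluster_size = 5L,
                          public_rate = 0.22,
                          member_prob = 0.5,
                          cdr3_length_mean = 15,
                          cdr3_length_sd = 2,
                          cdr3_length_range = c(8, 25),
                          reads_meanlog = log(9),
                          reads_sdlog = 0.45,
                          n_aliquot_pairs = 3L,
                          n_lesion_pairs = 4L,
                          lesion_share = 0.5,
                          seed = 20220501L) {
  groups <- c("no_nact", "short_interval", "long_interval")
  stopifnot(
    all(groups %in% names(n_per_group)),
    all(groups %in% names(fraction_mean)),
    all(groups %in% names(abundance_exponent)),
    all(n_per_group > 0),
    all(fraction_mean > 0 & fraction_mean < 1),
    all(abundance_exponent > 1),
    abundance_xmin >= 1,
    richness_range[1] >= 2, richness_range[2] >= richness_range[1],
    cluster_size >= 2,
    public_rate >= 0, public_rate <= 1,
    member_prob > 0, member_prob <= 1,
    lesion_share >= 0, lesion_share <= 1
  )
  if (cdr3_length_range[1] < 8 || cdr3_length_range[2] > 25 ||
      cdr3_length_range[1] > cdr3_length_range[2]) {
    stop("CDR3 length bounds must lie within [8, 25].", call. = FALSE)
  }
  structure(
    list(
      n_per_group = n_per_group[groups],
      fraction_mean = fraction_mean[groups],
      fraction_sdlog = fraction_sdlog,
      abundance_exponent = abundance_exponent[groups],
      abundance_xmin = as.integer(abundance_xmin),
      richness_range = richness_range,
      pool_clusters = as.integer(pool_clusters),
      cluster_size = as.integer(cluster_size),
      public_rate = public_rate,
      member_prob = member_prob,
      cdr3_length_mean = cdr3_length_mean,
      cdr3_length_sd = cdr3_length_sd,
      cdr3_length_range = cdr3_length_range,
      reads_meanlog = reads_meanlog,
      reads_sdlog = reads_sdlog,
      n_aliquot_pairs = as.integer(n_aliquot_pairs),
      n_lesion_pairs = as.integer(n_lesion_pairs),
      lesion_share = lesion_share,
      seed = as.integer(seed)
    ),
    class = "tcr_sim_config"
  )
}

#' Generate random CDR3 beta-chain amino-acid sequences
#'
#' Sequence lengths follow a normal distribution truncated to the
#' configured bounds (redrawn until in range); the first residue is
#' always C and the last always F per the CDR3-beta convention, with the
#' interior uniform over the 20-letter alphabet. Uses the current RNG
#' stream.
#'
#' @param n Number of sequences.
#' @param length_mean,length_sd,length_range Length distribution.
#' @return Character vector of length `n` (not deduplicated).
#' @export
generate_cdr3 <- function(n, length_mean = 15, length_sd = 2,
                          length_range = c(8, 25)) {
  if (length_range[1] < 8 || length_range[2] > 25 ||
      length_range[1] > length_range[2]) {
    stop("CDR3 length bounds must lie within [8, 25].", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  lens <- round(stats::rnorm(n, length_mean, length_sd))
  bad <- which(lens < length_range[1] | lens > length_range[2])
  while (length(bad) > 0L) {
    lens[bad] <- round(stats::rnorm(length(bad), length_mean, length_sd))
    bad <- bad[lens[bad] < length_range[1] | lens[bad] > length_range[2]]
  }
  out <- character(n)
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    interior <- L - 2L
    if (interior > 0L) {
      letters_mat <- matrix(sample(AA_ALPHABET, length(idx) * interior, replace = TRUE),
                            nrow = length(idx))
      body <- do.call(paste0, as.data.frame(letters_mat, stringsAsFactors = FALSE))
    } else {
      body <- rep("", length(idx))
    }
    out[idx] <- paste0("C", body, "F")
  }
  out
}

#' Generate the public clone pool as LD=1 motif clusters
#'
#' Each cluster is one seed CDR3 sequence plus `cluster_size - 1`
#' single-substitution mutants at interior positions, so seed-to-mutant
#' distance is exactly 1 and mutants are pairwise within distance 2.
#' Sequences colliding across clusters are dropped (keeping the first
#' occurrence), so occasional clusters are one short. Uses the current
#' RNG stream.
#'
#' @param config A `tcr_sim_config`.
#' @return A tibble with `cdr3_aa` and `cluster_id`.
#' @export
generate_public_pool <- function(config) {
  n_clusters <- config$pool_clusters
  k <- config$cluster_size - 1L
  seeds <- unique(generate_cdr3(n_clusters,
                                config$cdr3_length_mean,
                                config$cdr3_length_sd,
                                config$cdr3_length_range))
  while (length(seeds) < n_clusters) {
    seeds <- unique(c(seeds, generate_cdr3(n_clusters - length(seeds),
                                           config$cdr3_length_mean,
                                           config$cdr3_length_sd,
                                           config$cdr3_length_range)))
  }
  lens <- nchar(seeds)
  if (any(lens - 2L < k)) {
    # interiors shorter than the mutant count would force duplicate
    # positions; with bounds >= 8 and default cluster size this is
    # unreachable, but guard anyway
    stop("Cluster size too large for the configured CDR3 lengths.", call. = FALSE)
  }
  seed_rep <- rep(seeds, each = k)
  len_rep <- rep(lens, each = k)
  # one mutant per distinct interior position per cluster: positions
  # 2..L-1, sampled without replacement within each cluster
  pos <- unlist(lapply(lens, function(L) sample(2:(L - 1L), k)), use.names = FALSE)
  old <- substr(seed_rep, pos, pos)
  # replacement letter differs from the original: draw an offset 1..19
  # within the alphabet excluding the original letter
  old_idx <- match(old, AA_ALPHABET)
  new_idx <- 1L + ((old_idx - 1L + sample.int(19L, length(old_idx), replace = TRUE)) %% 20L)
  mutants <- paste0(substr(seed_rep, 1L, pos - 1L),
                    AA_ALPHABET[new_idx],
                    substr(seed_rep, pos + 1L, len_rep))
  pool <- tibble::tibble(
    cdr3_aa = c(seeds, mutants),
    cluster_id = c(seq_len(n_clusters), rep(seq_len(n_clusters), each = k))
  )
  pool <- pool[order(pool$cluster_id), ]
  pool[!duplicated(pool$cdr3_aa), ]
}

# Draw a sample's public clones: clusters enter in random order and each
# member joins with `member_prob`, until `n_public` members are taken.
#' @keywords internal
#' @noRd
draw_pool_members <- function(pool, n_public, member_prob) {
  if (n_public == 0L) return(character(0))
  cluster_ids <- unique(pool$cluster_id)
  order_ids <- sample(cluster_ids)
  taken <- character(0)
  chunk <- 256L
  i <- 1L
  while (length(taken) < n_public && i <= length(order_ids)) {
    ids <- order_ids[i:min(i + chunk - 1L, length(order_ids))]
    members <- pool$cdr3_aa[pool$cluster_id %in% ids]
    # preserve cluster blocks but randomize membership
    keep <- stats::runif(length(members)) < member_prob
    taken <- c(taken, members[keep])
    i <- i + chunk
  }
  taken[seq_len(min(n_public, length(taken)))]
}

# Build one repertoire's records from a clone list and abundance model.
#' @keywords internal
#' @noRd
make_records <- function(cdr3, templates, reads_per_template) {
  reads <- pmax(round(templates * reads_per_template), 0)
  collapse_clonotypes(tibble::tibble(
    cdr3_aa = cdr3,
    templates = templates,
    reads = reads,
    productive = TRUE,
    v_gene = NA_character_,
    j_gene = NA_character_
  ))
}

#' Generate one synthetic repertoire
#'
#' Draws richness from the configured range, splits clones between the
#' public pool and fresh private sequences, assigns template counts from
#' the group's discrete power-law abundance model, sets per-clone reads
#' from the sample's reads-per-template draw, and inverts the T-cell
#' fraction formula to choose the input DNA mass that realizes the
#' sample's true fraction exactly. Uses the current RNG stream.
#'
#' @param sample_id,patient_id,lesion_id,aliquot_id,group Identifiers.
#' @param config A `tcr_sim_config`.
#' @param pool Public pool tibble from [generate_public_pool()].
#' @param true_fraction The sample's true T-cell fraction (must be < 1).
#' @return A list with `repertoire` (a `tcr_repertoire`), `truth`
#'   (one-row tibble of sample-level ground truth), and `provenance`
#'   (tibble `cdr3_aa`, `source` in pool cluster id or `"private"`).
#' @export
generate_repertoire <- function(sample_id, patient_id, lesion_id, aliquot_id,
                                group, config, pool, true_fraction) {
  if (true_fraction >= 1 || true_fraction <= 0) {
    stop("True T-cell fraction must lie in (0, 1).", call. = FALSE)
  }
  richness <- round(stats::runif(1, config$richness_range[1], config$richness_range[2]))
  n_public <- round(config$public_rate * richness)
  pub <- draw_pool_members(pool, n_public, config$member_prob)
  n_private <- richness - length(pub)
  priv <- character(0)
  while (length(priv) < n_private) {
    cand <- generate_cdr3(n_private - length(priv),
                          config$cdr3_length_mean, config$cdr3_length_sd,
                          config$cdr3_length_range)
    priv <- unique(c(priv, setdiff(cand, pub)))
  }
  cdr3 <- c(pub, priv)
  exponent <- config$abundance_exponent[[group]]
  templates <- rpl_discrete(length(cdr3), exponent, config$abundance_xmin)
  rpt <- stats::rlnorm(1, config$reads_meanlog, config$reads_sdlog)
  records <- make_records(cdr3, templates, rpt)
  total <- sum(records$templates)
  dna_ng <- total * PG_PER_GENOME / (1000 * true_fraction)
  rep <- new_repertoire(records, sample_id = sample_id, patient_id = patient_id,
                        lesion_id = lesion_id, aliquot_id = aliquot_id,
                        group = group, input_dna_ng = dna_ng)
  cluster_of <- pool$cluster_id[match(cdr3, pool$cdr3_aa)]
  list(
    repertoire = rep,
    truth = tibble::tibble(
      sample_id = sample_id, patient_id = patient_id, group = group,
      true_fraction = true_fraction, abundance_exponent = exponent,
      richness = length(cdr3), reads_per_template = rpt,
      n_public_planted = length(pub)
    ),
    provenance = tibble::tibble(
      cdr3_aa = cdr3,
      source = ifelse(is.na(cluster_of), "private", paste0("cluster_", cluster_of))
    )
  )
}

# Derived repertoire: multinomial template resample of an existing one
# (aliquot replicate) at full depth.
#' @keywords internal
#' @noRd
resample_repertoire <- function(parent, sample_id, aliquot_id, config,
                                true_fraction) {
  rec <- parent$records
  counts <- as.vector(stats::rmultinom(1, size = sum(rec$templates),
                                       prob = rec$templates))
  keep <- counts > 0
  rpt <- stats::rlnorm(1, config$reads_meanlog, config$reads_sdlog)
  records <- make_records(rec$cdr3_aa[keep], counts[keep], rpt)
  dna_ng <- sum(records$templates) * PG_PER_GENOME / (1000 * true_fraction)
  new_repertoire(records, sample_id = sample_id, patient_id = parent$patient_id,
                 lesion_id = parent$lesion_id, aliquot_id = aliquot_id,
                 group = parent$group, input_dna_ng = dna_ng)
}

# Derived repertoire: second lesion sharing `lesion_share` of the parent
# lesion's clones (with their template counts) plus fresh private clones.
#' @keywords internal
#' @noRd
second_lesion_repertoire <- function(parent, sample_id, lesion_id, config,
                                     pool, true_fraction) {
  rec <- parent$records
  n_shared <- round(config$lesion_share * nrow(rec))
  shared_idx <- sample(nrow(rec), n_shared)
  n_new <- nrow(rec) - n_shared
  new_seqs <- character(0)
  while (length(new_seqs) < n_new) {
    cand <- generate_cdr3(n_new - length(new_seqs),
                          config$cdr3_length_mean, config$cdr3_length_sd,
                          config$cdr3_length_range)
    new_seqs <- unique(c(new_seqs, setdiff(cand, rec$cdr3_aa)))
  }
  exponent <- config$abundance_exponent[[parent$group]]
  new_templates <- rpl_discrete(length(new_seqs), exponent, config$abundance_xmin)
  rpt <- stats::rlnorm(1, config$reads_meanlog, config$reads_sdlog)
  records <- make_records(
    c(rec$cdr3_aa[shared_idx], new_seqs),
    c(rec$templates[shared_idx], new_templates),
    rpt
  )
  dna_ng <- sum(records$templates) * PG_PER_GENOME / (1000 * true_fraction)
  new_repertoire(records, sample_id = sample_id, patient_id = parent$patient_id,
                 lesion_id = lesion_id, aliquot_id = "a1",
                 group = parent$group, input_dna_ng = dna_ng)
}

#' Generate a full synthetic cohort
#'
#' Generates one repertoire per patient across the three NACT groups,
#' adds aliquot-replicate samples (multinomial template resamples of one
#' underlying clone distribution) for `n_aliquot_pairs` patients and
#' second-lesion samples (sharing `lesion_share` of the patient's clone
#' pool) for `n_lesion_pairs` patients, and optionally writes the
#' rearrangement TSVs, manifest CSV, pool CSV and sample-level
#' ground-truth CSV to a directory.
#'
#' @param config A `tcr_sim_config`.
#' @param dir Optional output directory; created if missing.
#' @return A list of class `tcr_sim_cohort`: `repertoires` (named list of
#'   `tcr_repertoire`), `manifest` (tibble), `pool` (public pool tibble),
#'   `truth` (sample-level ground truth), `provenance` (clone provenance,
#'   one row per primary-sample clone), and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  set.seed(config$seed)
  pool <- generate_public_pool(config)

  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n_pat <- length(groups)
  patient_ids <- sprintf("P%03d", seq_len(n_pat))
  # deterministic draw of replicate patients (after pool generation)
  special <- sample(n_pat, config$n_aliquot_pairs + config$n_lesion_pairs)
  aliquot_patients <- patient_ids[special[seq_len(config$n_aliquot_pairs)]]
  lesion_patients <- patient_ids[special[config$n_aliquot_pairs +
                                           seq_len(config$n_lesion_pairs)]]

  repertoires <- list()
  truth <- list()
  provenance <- list()
  for (i in seq_len(n_pat)) {
    pid <- patient_ids[i]
    grp <- groups[i]
    mu <- log(config$fraction_mean[[grp]]) - config$fraction_sdlog^2 / 2
    f <- min(stats::rlnorm(1, mu, config$fraction_sdlog), 0.9)
    sid <- sprintf("%s_L1_a1", pid)
    gen <- generate_repertoire(sid, pid, lesion_id = paste0(pid, "_L1"),
                               aliquot_id = "a1", group = grp,
                               config = config, pool = pool, true_fraction = f)
    repertoires[[sid]] <- gen$repertoire
    truth[[sid]] <- gen$truth
    provenance[[sid]] <- dplyr::mutate(gen$provenance, sample_id = sid)

    if (pid %in% aliquot_patients) {
      sid2 <- sprintf("%s_L1_a2", pid)
      repertoires[[sid2]] <- resample_repertoire(gen$repertoire, sid2, "a2",
                                                 config, f)
      truth[[sid2]] <- dplyr::mutate(gen$truth, sample_id = sid2)
    }
    if (pid %in% lesion_patients) {
      sid2 <- sprintf("%s_L2_a1", pid)
      f2 <- min(stats::rlnorm(1, mu, config$fraction_sdlog), 0.9)
      repertoires[[sid2]] <- second_lesion_repertoire(
        gen$repertoire, sid2, lesion_id = paste0(pid, "_L2"),
        config = config, pool = pool, true_fraction = f2)
      truth[[sid2]] <- dplyr::mutate(gen$truth, sample_id = sid2,
                                     true_fraction = f2)
    }
  }

  manifest <- tibble::tibble(
    sample_id = names(repertoires),
    patient_id = vapply(repertoires, function(r) r$patient_id, character(1)),
    lesion_id = vapply(repertoires, function(r) r$lesion_id, character(1)),
    aliquot_id = vapply(repertoires, function(r) r$aliquot_id, character(1)),
    group = vapply(repertoires, function(r) r$group, character(1)),
    input_dna_ng = vapply(repertoires, function(r) r$input_dna_ng, numeric(1)),
    total_reads = vapply(repertoires, function(r) as.numeric(r$total_reads), numeric(1))
  )
  out <- structure(
    list(
      repertoires = repertoires,
      manifest = manifest,
      pool = pool,
      truth = dplyr::bind_rows(truth),
      provenance = dplyr::bind_rows(provenance),
      config = config
    ),
    class = "tcr_sim_cohort"
  )
  if (!is.null(dir)) {
    write_sim_cohort(out, dir)
  }
  out
}

#' @export
print.tcr_sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TCR cohort: %d samples, %d patients (seed %d)\n",
              length(x$repertoires),
              length(unique(x$manifest$patient_id)),
              x$config$seed))
  print(table(x$manifest$group))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one rearrangement TSV per sample (same dialect
#' [read_rearrangement_file()] reads), `manifest.csv`,
#' `public_pool.csv`, and `ground_truth.csv`.
#'
#' @param cohort A `tcr_sim_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(cohort$repertoires))
  for (i in seq_along(cohort$repertoires)) {
    r <- cohort$repertoires[[i]]
    files[i] <- file.path(dir, paste0(r$sample_id, ".tsv"))
    write_rearrangement_file(r, files[i])
  }
  manifest <- dplyr::mutate(cohort$manifest, file = basename(files))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  readr::write_csv(cohort$pool, file.path(dir, "public_pool.csv"), progress = FALSE)
  readr::write_csv(cohort$truth, file.path(dir, "ground_truth.csv"), progress = FALSE)
  invisible(dir)
}
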