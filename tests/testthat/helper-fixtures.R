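# Shared fixtures: all built in code at test time.

# three-row toy rearrangement file: CASSF(5) + CASSF(2) + CASTF(1)
write_toy_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "amino_acid\ttemplates\tseq_reads\tframe_type\tv_resolved\tj_resolved",
    "CASSF\t5\t50\tIn\tTCRBV05-01\tTCRBJ02-01",
    "CASSF\t2\t18\tIn\tTCRBV06-01\tTCRBJ02-01",
    "CASTF\t1\t9\tIn\tTCRBV05-01\tTCRBJ02-07"
  ), path)
  path
}

# minimal repertoire straight from counts
toy_repertoire <- function(cdr3, templates, sample_id = "S1",
                           patient_id = "P1", group = "no_nact",
                           reads = templates * 10) {
  new_repertoire(
    collapse_clonotypes(tibble::tibble(
      cdr3_aa = cdr3, templates = templates, reads = reads,
      productive = TRUE, v_gene = NA_character_, j_gene = NA_character_
    )),
    sample_id = sample_id, patient_id = patient_id,
    lesion_id = paste0(patient_id, "_L1"), aliquot_id = "a1",
    group = group, input_dna_ng = 660
  )
}

# scaled-down generator configuration for fast unit tests (the default
# configuration is exercised in the acceptance suite)
small_sim_config <- function(seed = 11L, ...) {
  cohort_config(
    n_per_group = c(no_nact = 4, short_interval = 4, long_interval = 2),
    richness_range = c(300, 700),
    pool_clusters = 600L,
    n_aliquot_pairs = 1L,
    n_lesion_pairs = 1L,
    seed = seed,
    ...
  )
}

# brute-force LD=1 pair oracle via the C edit-distance in utils::adist
ld1_pairs_oracle <- function(seqs) {
  d <- utils::adist(seqs)
  hits <- which(d == 1 & upper.tri(d), arr.ind = TRUE)
  m <- cbind(pmin(hits[, 1], hits[, 2]), pmax(hits[, 1], hits[, 2]))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  unname(m)
}

sort_pairs <- function(m) {
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  unname(m[order(m[, 1], m[, 2]), , drop = FALSE])
}
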