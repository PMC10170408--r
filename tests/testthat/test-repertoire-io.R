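test_that("parsing collapses clonotypes and recomputes totals deterministically", {
  path <- write_toy_tsv()
  rep1 <- read_rearrangement_file(path)
  expect_s3_class(rep1, "tcr_repertoire")
  expect_equal(nrow(rep1$records), 2L)
  expect_equal(rep1$records$templates[rep1$records$cdr3_aa == "CASSF"], 7)
  expect_equal(rep1$records$templates[rep1$records$cdr3_aa == "CASTF"], 1)
  expect_equal(rep1$total_templates, 8)
  expect_equal(rep1$total_reads, 77)
  # V/J kept from the highest-template row
  expect_equal(rep1$records$v_gene[rep1$records$cdr3_aa == "CASSF"], "TCRBV05-01")
  # deterministic parse
  rep2 <- read_rearrangement_file(path)
  expect_identical(rep1$records, rep2$records)
})

test_that("productivity filtering and error paths behave as specified", {
  # all rows out of frame -> explicit empty-repertoire error
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "amino_acid\ttemplates\tseq_reads\tframe_type",
    "CASSF\t5\t50\tOut",
    "CAX*F\t2\t18\tStop"
  ), path)
  expect_error(read_rearrangement_file(path), "No productive")
  # retained in storage when productive_only = FALSE, marked nonproductive
  rep <- read_rearrangement_file(path, productive_only = FALSE)
  expect_false(any(rep$records$productive))

  # missing required column named in the error
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("amino_acid\tseq_reads\tframe_type", "CASSF\t50\tIn"), path2)
  expect_error(read_rearrangement_file(path2), "templates")

  # nonpositive template count reported with row number
  path3 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "amino_acid\ttemplates\tseq_reads\tframe_type",
    "CASSF\t5\t50\tIn",
    "CASTF\t0\t9\tIn"
  ), path3)
  expect_error(read_rearrangement_file(path3), "row: 2")

  # invalid characters mark a row nonproductive even when frame is In
  path4 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "amino_acid\ttemplates\tseq_reads\tframe_type",
    "CASSF\t5\t50\tIn",
    "CAS*F\t3\t30\tIn"
  ), path4)
  rep4 <- read_rearrangement_file(path4)
  expect_equal(rep4$records$cdr3_aa, "CASSF")
})

test_that("collapsing conserves counts, is idempotent, and keeps distinct rows", {
  expect_equal(
    collapse_clonotypes(tibble::tibble(cdr3_aa = c("CASSF", "CASSF"),
                                       templates = c(5, 2)))$templates,
    7
  )
  distinct <- tibble::tibble(cdr3_aa = c("CASSF", "CASTF"), templates = c(1, 2))
  expect_equal(nrow(collapse_clonotypes(distinct)), 2L)

  set.seed(42)
  seqs <- paste0("C", replicate(100, paste(sample(LETTERS[1:20], 8, TRUE), collapse = "")), "F")
  rows <- tibble::tibble(
    cdr3_aa = sample(seqs, 1000, replace = TRUE),
    templates = sample(1:20, 1000, replace = TRUE),
    reads = sample(0:100, 1000, replace = TRUE)
  )
  collapsed <- collapse_clonotypes(rows)
  expect_equal(nrow(collapsed), length(unique(rows$cdr3_aa)))
  expect_equal(sum(collapsed$templates), sum(rows$templates))
  expect_equal(sum(collapsed$reads), sum(rows$reads))
  # brute-force grouping oracle
  oracle <- tapply(rows$templates, rows$cdr3_aa, sum)
  expect_equal(collapsed$templates[match(names(oracle), collapsed$cdr3_aa)],
               as.vector(oracle))
  # idempotent
  expect_equal(collapse_clonotypes(collapsed), collapsed)
})

test_that("cohort table takes the clone union, zero-fills, and conserves totals", {
  r1 <- toy_repertoire(c("CASSF", "CASTF"), c(7, 1), "S1", "P1")
  r2 <- toy_repertoire(c("CASSF", "CAKKF"), c(3, 4), "S2", "P2")
  cohort <- build_cohort_table(list(r1, r2))
  expect_equal(nrow(cohort$counts), 3L) # n1 + n2 - 1
  expect_equal(unname(Matrix::colSums(cohort$counts)), c(8, 7))
  expect_equal(cohort$counts["CAKKF", "S1"], 0)
  expect_equal(cohort$counts["CASSF", "S2"], 3)

  # single repertoire: column equals its record counts
  c1 <- build_cohort_table(list(r1))
  expect_equal(unname(c1$counts[r1$records$cdr3_aa, "S1"]), r1$records$templates)

  # duplicate sample ids rejected
  expect_error(build_cohort_table(list(r1, r1)), "Duplicate sample_id")

  # conservation across three synthetic repertoires
  sim <- generate_cohort(small_sim_config())
  reps <- sim$repertoires[1:3]
  c3 <- build_cohort_table(reps)
  expect_equal(unname(Matrix::colSums(c3$counts)),
               unname(vapply(reps, function(r) as.numeric(r$total_templates),
                             numeric(1))))
})

test_that("write/read round trip preserves collapsed clonotype counts exactly", {
  path <- write_toy_tsv()
  rep1 <- read_rearrangement_file(path)
  out <- tempfile(fileext = ".tsv")
  write_rearrangement_file(rep1, out)
  rep2 <- read_rearrangement_file(out, sample_id = rep1$sample_id)
  expect_equal(rep1$records[, c("cdr3_aa", "templates", "reads")],
               rep2$records[, c("cdr3_aa", "templates", "reads")])
})

test_that("manifest validation catches missing columns and duplicate samples", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,patient_id,group", "S1,P1,no_nact"), path)
  expect_error(read_manifest(path), "missing columns")
  path2 <- tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,patient_id,lesion_id,aliquot_id,group,input_dna_ng",
    "S1,P1,L1,a1,no_nact,660",
    "S1,P1,L1,a2,no_nact,660"
  ), path2)
  expect_error(read_manifest(path2), "unique")
})
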