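test_that("generated CDR3 sequences obey the convention and length model", {
  set.seed(1)
  s8 <- generate_cdr3(50, length_mean = 8, length_sd = 0.01, length_range = c(8, 8))
  expect_true(all(nchar(s8) == 8))
  expect_true(all(grepl("^C[A-Z]{6}F$", s8)))
  expect_error(generate_cdr3(5, length_range = c(4, 30)), "within \\[8, 25\\]")

  set.seed(2)
  s <- generate_cdr3(10000)
  expect_true(all(substr(s, 1, 1) == "C"))
  expect_true(all(substr(s, nchar(s), nchar(s)) == "F"))
  expect_equal(mean(nchar(s)), 15, tolerance = 0.1 / 15)
  expect_true(all(nchar(s) >= 8 & nchar(s) <= 25))

  set.seed(7); a <- generate_cdr3(100)
  set.seed(7); b <- generate_cdr3(100)
  expect_identical(a, b)
})

test_that("public pool clusters are LD=1 stars with no cross-cluster edges", {
  cfg <- small_sim_config()
  set.seed(3)
  pool <- generate_public_pool(cfg)
  expect_true(all(table(pool$cluster_id) <= cfg$cluster_size))
  expect_false(any(duplicated(pool$cdr3_aa)))

  # one full cluster: seed at LD 1 from every mutant, mutants within LD 2
  cl1 <- pool[pool$cluster_id == pool$cluster_id[1], ]
  d <- utils::adist(cl1$cdr3_aa)
  expect_true(all(d[1, -1] == 1))
  expect_true(all(d <= 2))
  net <- build_ld1_network(cl1$cdr3_aa)
  expect_gte(net$n_edges, nrow(cl1) - 1)

  # two clusters with distant seeds stay disconnected
  c1 <- pool$cdr3_aa[pool$cluster_id == pool$cluster_id[1]]
  other <- pool[abs(nchar(pool$cdr3_aa) - nchar(c1[1])) >= 3, ] # LD >= 3 by length
  c2 <- other$cdr3_aa[other$cluster_id == other$cluster_id[1]]
  oracle <- utils::adist(c(c1, c2))
  cross <- oracle[seq_along(c1), length(c1) + seq_along(c2)]
  expect_true(all(cross > 1))
  net2 <- build_ld1_network(c(c1, c2))
  comp <- igraph::components(net2$graph)
  expect_true(all(comp$membership[seq_along(c1)] !=
                  comp$membership[length(c1) + seq_along(c2)]))
})

test_that("repertoire generation inverts the T-cell fraction formula exactly", {
  cfg <- small_sim_config()
  set.seed(4)
  pool <- generate_public_pool(cfg)
  gen <- generate_repertoire("S1", "P1", "L1", "a1", "no_nact", cfg, pool, 0.08)
  r <- gen$repertoire
  # written DNA mass realizes the true fraction exactly
  expect_equal(t_cell_fraction(r$total_templates, r$input_dna_ng), 0.08,
               tolerance = 1e-12)
  # worked example: 10,000 templates at fraction 0.08 -> 825 ng
  expect_equal(10000 * 6.6 / (0.08 * 1000), 825)
  # every clone traces to a provenance record
  expect_setequal(gen$provenance$cdr3_aa, r$records$cdr3_aa)
  pool_members <- gen$provenance$cdr3_aa[gen$provenance$source != "private"]
  expect_true(all(pool_members %in% pool$cdr3_aa))
  expect_error(
    generate_repertoire("S", "P", "L", "a", "no_nact", cfg, pool, 1.2),
    "in \\(0, 1\\)"
  )
})

test_that("public sampling rate zero yields a pool-free repertoire", {
  cfg <- small_sim_config(public_rate = 0)
  set.seed(5)
  pool <- generate_public_pool(cfg)
  gen <- generate_repertoire("S1", "P1", "L1", "a1", "no_nact", cfg, pool, 0.05)
  expect_false(any(gen$repertoire$records$cdr3_aa %in% pool$cdr3_aa))
  expect_true(all(gen$provenance$source == "private"))
})

test_that("cohort generation follows the sample plan and is byte-deterministic", {
  cfg <- small_sim_config()
  sim <- generate_cohort(cfg)
  m <- sim$manifest
  expect_equal(length(unique(m$patient_id)), 10L)
  expect_equal(nrow(m), 10L + cfg$n_aliquot_pairs + cfg$n_lesion_pairs)
  expect_equal(sum(table(m$patient_id, m$aliquot_id)[, "a2"]), cfg$n_aliquot_pairs)
  lesions_per_patient <- tapply(m$lesion_id, m$patient_id,
                                function(x) length(unique(x)))
  expect_equal(sum(lesions_per_patient == 2), cfg$n_lesion_pairs)
  primary <- m[m$aliquot_id == "a1" & grepl("_L1_", m$sample_id), ]
  expect_equal(unname(c(table(primary$group)[names(cfg$n_per_group)])),
               unname(cfg$n_per_group))

  dir1 <- file.path(tempdir(), "simA")
  dir2 <- file.path(tempdir(), "simB")
  write_sim_cohort(sim, dir1)
  write_sim_cohort(generate_cohort(cfg), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     label = f)
  }
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("default cohort plan matches the emulated study design", {
  cfg <- cohort_config()
  expect_equal(unname(cfg$n_per_group), c(35, 35, 15))
  expect_equal(cfg$n_aliquot_pairs, 3L)
  expect_equal(cfg$n_lesion_pairs, 4L)
  expect_equal(unname(cfg$fraction_mean), c(0.063, 0.106, 0.062))
})

test_that("aliquot replicates overlap strongly; unshared lesions do not", {
  sim <- generate_cohort(small_sim_config())
  cohort <- build_cohort_table(sim$repertoires)
  ov <- pairwise_mhi(cohort)
  rep_mhi <- ov$pairs$mhi[ov$pairs$comparison_class == "within_lesion_replicate"]
  expect_true(all(rep_mhi >= 0.85))
  lesion_mhi <- ov$pairs$mhi[ov$pairs$comparison_class == "within_patient_between_lesion"]
  between <- ov$pairs$mhi[ov$pairs$comparison_class == "between_patient"]
  expect_true(all(lesion_mhi > max(between)))
  expect_true(all(lesion_mhi < min(rep_mhi)))

  # share fraction zero drops lesion overlap to the between-patient level
  sim0 <- generate_cohort(small_sim_config(seed = 21L, lesion_share = 0))
  ov0 <- pairwise_mhi(build_cohort_table(sim0$repertoires))
  lesion0 <- ov0$pairs$mhi[ov0$pairs$comparison_class == "within_patient_between_lesion"]
  expect_lt(max(lesion0), 0.05)
})

test_that("sample-level ground truth is recovered by quantification", {
  sim <- generate_cohort(small_sim_config())
  cohort <- build_cohort_table(sim$repertoires)
  quant <- quantify_samples(cohort)
  truth <- sim$truth[match(quant$sample_id, sim$truth$sample_id), ]
  expect_equal(unname(quant$t_cell_fraction), truth$true_fraction,
               tolerance = 1e-10)
})
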