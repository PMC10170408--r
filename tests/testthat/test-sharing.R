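test_that("sharing level counts patients, not samples", {
  reps <- list(
    toy_repertoire(c("CAAAF", "CBBBF"), c(5, 5), "S1", "P1"),
    toy_repertoire(c("CAAAF"), 3, "S2", "P1"),          # same patient again
    toy_repertoire(c("CBBBF", "CCCCF"), c(2, 2), "S3", "P2"),
    toy_repertoire(c("CBBBF"), 9, "S4", "P3")
  )
  cohort <- build_cohort_table(reps)
  sh <- sharing_index(cohort)
  lev <- setNames(sh$sharing_level, sh$cdr3_aa)
  expect_equal(unname(lev["CAAAF"]), 1L) # two samples, one patient -> private
  expect_equal(unname(lev["CBBBF"]), 3L) # three patients -> public
  expect_equal(unname(lev["CCCCF"]), 1L)
  expect_equal(sh$public, sh$sharing_level > 1)
})

test_that("sharing is invariant to splitting a patient's sample into replicates", {
  whole <- list(
    toy_repertoire(c("CAAAF", "CBBBF"), c(6, 4), "S1", "P1"),
    toy_repertoire(c("CAAAF"), 5, "S2", "P2")
  )
  split_reps <- list(
    toy_repertoire(c("CAAAF", "CBBBF"), c(3, 2), "S1a", "P1"),
    toy_repertoire(c("CAAAF", "CBBBF"), c(3, 2), "S1b", "P1"),
    toy_repertoire(c("CAAAF"), 5, "S2", "P2")
  )
  sh1 <- sharing_index(build_cohort_table(whole))
  sh2 <- sharing_index(build_cohort_table(split_reps))
  expect_equal(sh1[order(sh1$cdr3_aa), ], sh2[order(sh2$cdr3_aa), ])
})

test_that("planted public pool clones are recovered as the public set", {
  sim <- generate_cohort(small_sim_config())
  cohort <- build_cohort_table(sim$repertoires)
  sh <- sharing_index(cohort)
  recovered <- sh$cdr3_aa[sh$public]
  # public clones trace to the pool (up to rare random collisions of
  # private sequences across patients)
  expect_gte(mean(recovered %in% sim$pool$cdr3_aa), 0.99)
  # independent recomputation: pool members detected in >= 2 patients
  detected <- cohort$counts[rownames(cohort$counts) %in% sim$pool$cdr3_aa, ] > 0
  pat <- cohort$manifest$patient_id
  per_patient <- t(rowsum((t(as.matrix(detected))) * 1, pat)) > 0
  planted_public <- rownames(per_patient)[rowSums(per_patient) >= 2]
  expect_setequal(intersect(recovered, sim$pool$cdr3_aa), planted_public)
})

test_that("mean degree rises with sharing level in a planted cohort", {
  sim <- generate_cohort(small_sim_config())
  cohort <- build_cohort_table(sim$repertoires)
  sh <- sharing_index(cohort)
  reps_split <- split(seq_len(nrow(cohort$manifest)), cohort$manifest$sample_id)
  networks <- lapply(cohort$manifest$sample_id, function(sid) {
    j <- match(sid, cohort$manifest$sample_id)
    present <- cohort$counts[, j] > 0
    build_ld1_network(cohort$clones[present])
  })
  names(networks) <- cohort$manifest$sample_id
  dvs <- degree_vs_sharing(networks, sh)
  expect_true(all(diff(dvs$sharing_level) > 0))
  # private clones sit below well-shared clones
  lo <- dvs$mean_degree[dvs$sharing_level == 1]
  hi <- dvs$mean_degree[dvs$sharing_level >= 3]
  expect_true(all(hi > lo))
  # regression of mean degree on sharing level has positive slope
  fit <- ols_fit(dvs$sharing_level, dvs$mean_degree)
  expect_gt(fit$slope, 0)
  # empty input gives an empty table
  empty <- degree_vs_sharing(list(), sh)
  expect_equal(nrow(empty), 0L)
})

test_that("class connectivity separates planted public clusters from private clones", {
  sim <- generate_cohort(small_sim_config())
  cohort <- build_cohort_table(sim$repertoires)
  sh <- sharing_index(cohort)
  rep1 <- sim$repertoires[[1]]
  cc <- class_connectivity(rep1, sh, n_sub = 100L, seed = 5)
  pub <- cc[cc$class == "public", ]
  priv <- cc[cc$class == "private", ]
  expect_gte(pub$connectivity_fraction, 10 * max(priv$connectivity_fraction, 1e-3))
  # n_sub larger than the class uses the whole class, flagged
  cc_all <- class_connectivity(rep1, sh, n_sub = 10^6, seed = 5)
  expect_true(all(!cc_all$subsampled))
  expect_equal(cc_all$n_used, cc_all$n_clones)
  # determinism under a fixed seed
  cc2 <- class_connectivity(rep1, sh, n_sub = 100L, seed = 5)
  expect_identical(cc, cc2)
  # empty class reported as missing, not zero
  sh_none <- sh
  sh_none$public <- FALSE
  cc3 <- class_connectivity(rep1, sh_none, n_sub = 100L, seed = 5)
  expect_true(is.na(cc3$connectivity_fraction[cc3$class == "public"]))
})

test_that("pathology matching fractions are exact on a toy repertoire", {
  # ten clones: one big expanded clone in the db, nothing else matches
  seqs <- paste0("C", c("A", "C", "D", "E", "G", "H", "I", "K", "L", "M"),
                 "AAAAF") # 10 distinct
  rep1 <- toy_repertoire(seqs, c(100, rep(1, 9)), "S1", "P1")
  net <- build_ld1_network(seqs)
  sh <- tibble::tibble(cdr3_aa = seqs, sharing_level = 1L, public = FALSE)
  db <- tibble::tibble(cdr3_aa = seqs[1], pathology = "Influenza")
  pm <- pathology_match(rep1, net, sh, db, top_frac = 0.10)
  # top decile of 10 clones is 1 clone; the expanded one is in the db
  expect_equal(pm$n_expanded, 1L)
  expect_equal(pm$expanded_fraction, 1)
  expect_equal(pm$n_connected_public, 1L)
  # empty intersection gives zero fractions
  db2 <- tibble::tibble(cdr3_aa = "CWWWWWWF", pathology = "CMV")
  pm2 <- pathology_match(rep1, net, sh, db2)
  expect_equal(pm2$expanded_fraction, 0)
  expect_equal(pm2$connected_public_fraction, 0)
  # whole repertoire in the db gives fraction 1 for both sets
  db3 <- tibble::tibble(cdr3_aa = seqs, pathology = "CMV")
  pm3 <- pathology_match(rep1, net, sh, db3)
  expect_equal(pm3$expanded_fraction, 1)
  expect_equal(pm3$connected_public_fraction, 1)
})

test_that("pathology database reading filters species and bad sequences", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "CDR3.beta.aa,Species,Pathology",
    "CASSF,Human,Influenza",
    "CASTF,Mouse,Influenza",
    "casgf,Human,CMV",
    "CAS*F,Human,EBV"
  ), path)
  db <- read_pathology_db(path)
  expect_setequal(db$cdr3_aa, c("CASSF", "CASGF")) # human + uppercased, star dropped
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("CDR3.beta.aa,Species,Pathology", "CASSF,Mouse,Influenza"), path2)
  expect_error(read_pathology_db(path2), "empty after filtering")
  path3 <- tempfile(fileext = ".csv")
  writeLines(c("seq,Species,Pathology", "CASSF,Human,Influenza"), path3)
  expect_error(read_pathology_db(path3), "missing column")
})
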