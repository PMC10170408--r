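test_that("Hill diversity matches its closed forms at q = 0, 1, 2", {
  # worked two-clone example
  p <- c(0.9, 0.1)
  D <- hill_diversity(p, c(0, 1, 2))
  expect_equal(D[1], 2)
  expect_equal(D[2], exp(-(0.9 * log(0.9) + 0.1 * log(0.1))))
  expect_equal(D[3], 1 / (0.9^2 + 0.1^2))

  # uniform and degenerate limits
  expect_equal(hill_diversity(rep(0.01, 100)), rep(100, 51), tolerance = 1e-9)
  expect_equal(hill_diversity(1), rep(1, 51), tolerance = 1e-12)

  # random vectors against richness / Shannon / inverse-Simpson oracles
  set.seed(5)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    p <- as.vector(rexp(n))
    p <- p / sum(p)
    D <- hill_diversity(p, c(0, 1, 2))
    expect_equal(D[1], n, tolerance = 1e-9)
    expect_equal(D[2], exp(-sum(p * log(p))), tolerance = 1e-9)
    expect_equal(D[3], 1 / sum(p^2), tolerance = 1e-9)
  }
})

test_that("Hill diversity rejects invalid frequency vectors", {
  expect_error(hill_diversity(numeric(0)), "empty")
  expect_error(hill_diversity(c(0.5, 0.5, 0)), "positive")
  expect_error(hill_diversity(c(0.7, 0.2)), "sum to 1")
})

test_that("diversity is non-increasing in q and bounded by richness", {
  set.seed(8)
  for (i in 1:20) {
    p <- rexp(sample(5:500, 1))
    p <- p / sum(p)
    D <- hill_diversity(p)
    expect_true(all(diff(D) <= 1e-9))
    expect_true(all(D >= 1 - 1e-9 & D <= length(p) + 1e-9))
  }
})

test_that("evenness is the richness-normalized profile with E(0) = 1", {
  p <- c(0.9, 0.1)
  D <- hill_diversity(p)
  E <- evenness_profile(D)
  expect_equal(E[1], 1)
  expect_equal(E[11], (1 / 0.82) / 2, tolerance = 1e-9) # q = 2
  expect_true(all(E > 0 & E <= 1))
  expect_equal(evenness_profile(hill_diversity(rep(0.1, 10))), rep(1, 51),
               tolerance = 1e-9)
})

test_that("clonality index integrates the evenness curve as specified", {
  q <- seq(0, 10, by = 0.2)
  # flat curve: Simpson is exact, clonality 0
  expect_equal(clonality_index(rep(1, 51), q), 0, tolerance = 1e-12)
  # analytic integral of exp(-q) over [0, 10]
  expect_equal(clonality_index(exp(-q), q), 10 - (1 - exp(-10)), tolerance = 1e-4)
  # grid validation
  expect_error(clonality_index(c(1, 1), c(0, 10)), "3 grid points")
  expect_error(clonality_index(rep(1, 4), seq(0, 9, by = 3)), "even number")
})

test_that("profile on template counts flags monoclonal repertoires", {
  expect_warning(prof <- diversity_profile(5), "Richness below 2")
  expect_equal(prof$clonality, 0, tolerance = 1e-9)
  expect_error(diversity_profile(integer(0)), "positive template counts")
})

test_that("clonality never decreases under mass transfer to a larger clone", {
  set.seed(13)
  for (i in 1:60) {
    counts <- sample(1:50, sample(5:40, 1), replace = TRUE)
    cl0 <- diversity_profile(counts)$clonality
    ord <- order(counts)
    small <- ord[1]
    large <- ord[length(ord)]
    if (counts[small] < 2) next # keep all counts positive after transfer
    counts2 <- counts
    counts2[small] <- counts2[small] - 1
    counts2[large] <- counts2[large] + 1
    cl1 <- diversity_profile(counts2)$clonality
    expect_gte(cl1, cl0 - 1e-9)
  }
})

test_that("clonality is invariant to rescaling template counts", {
  set.seed(21)
  for (i in 1:20) {
    counts <- sample(1:100, 30, replace = TRUE)
    k <- sample(2:50, 1)
    expect_equal(diversity_profile(counts)$clonality,
                 diversity_profile(counts * k)$clonality,
                 tolerance = 1e-9)
  }
})

test_that("Simpson and trapezoid integration agree closely on smooth profiles", {
  counts <- c(500, 200, 100, rep(5, 50), rep(1, 200))
  cs <- diversity_profile(counts, method = "simpson")$clonality
  ct <- diversity_profile(counts, method = "trapezoid")$clonality
  expect_equal(cs, ct, tolerance = 1e-3)
})
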