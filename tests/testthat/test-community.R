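make_ct <- function(counts, groups = NULL, totals = NULL) {
  if (is.null(groups)) {
    groups <- setNames(rep("other", ncol(counts)), colnames(counts))
  }
  community_table(counts, taxon_groups = groups, total_copies = totals)
}

test_that("relative_abundances normalises rows and drops empty samples", {
  m <- matrix(c(8, 2, 0, 0, 3, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("t1", "t2")))
  expect_warning(ra <- relative_abundances(m), "s2")
  expect_equal(unname(ra["s1", ]), c(0.8, 0.2))
  expect_equal(unname(rowSums(ra)), rep(1, 2), tolerance = 1e-12)
  single <- matrix(5, 1, 1, dimnames = list("s", "t"))
  expect_equal(unname(relative_abundances(single)[1, 1]), 1)

  set.seed(31)
  big <- matrix(rpois(200, 10), 20, 10,
                dimnames = list(paste0("s", 1:20), paste0("t", 1:10)))
  expect_equal(unname(rowSums(relative_abundances(big))), rep(1, 20),
               tolerance = 1e-12)
})

test_that("partitioning totals conserves them and validates input", {
  fr <- matrix(c(0.05, 0.95, 0.4, 0.6), 2, 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("g1", "g2")))
  totals <- c(s1 = 1e9, s2 = 2e8)
  est <- partition_total_abundance(fr, totals)
  expect_equal(est["s1", "g1"], 5e7)           # 0.05 * 1e9
  expect_equal(unname(rowSums(est)), unname(totals), tolerance = 1e-9)
  expect_equal(partition_total_abundance(matrix(0, 1, 1,
    dimnames = list("s1", "g")), totals["s1"])[1, 1], 0)
  expect_error(partition_total_abundance(fr * 2, totals), "\\[0, 1\\]")
  expect_warning(partition_total_abundance(fr, totals["s1"]), "s2")
})

test_that("bray_curtis matches the hand formula and its invariants", {
  counts <- matrix(c(10, 0, 0, 10, 5, 5), 3, 2, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  d <- bray_curtis(counts)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_equal(d["a", "b"], 1)                 # disjoint taxa
  expect_equal(d["a", "a"], 0)                 # identical samples
  ra <- sweep(counts, 1, rowSums(counts), "/")
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(d[i, j], bray_oracle(ra[i, ], ra[j, ]))
  }
  # invariant to per-sample rescaling (computed on fractions)
  scaled <- counts * c(10, 1, 100)
  expect_equal(bray_curtis(scaled), d)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("ANOSIM extremes: separated groups give R = 1, flat distances R = 0", {
  d <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["c", "d"] <- d["d", "c"] <- 0.2
  g <- c("g1", "g1", "g2", "g2")
  res <- anosim(d, g, n_permutations = 99, seed = 1)
  expect_equal(res$r_statistic, 1)
  flat <- matrix(0.5, 4, 4, dimnames = dimnames(d))
  diag(flat) <- 0
  expect_equal(anosim(flat, g, n_permutations = 99, seed = 1)$r_statistic, 0)
  expect_error(anosim(d, c("g1", "g1", "g2", "g3")), "single sample")
})

test_that("ANOSIM R and exhaustive p match enumeration oracles on 6 samples", {
  set.seed(32)
  counts <- matrix(rpois(6 * 8, 15), 6, 8,
                   dimnames = list(paste0("s", 1:6), paste0("t", 1:8)))
  counts[1:3, 1:4] <- counts[1:3, 1:4] + 20    # group structure
  d <- bray_curtis(counts)
  g <- rep(c("x", "y"), each = 3)
  res <- anosim(d, g, exhaustive = TRUE)
  expect_equal(res$r_statistic, anosim_r_oracle(d, g), tolerance = 1e-12)
  expect_equal(res$p_value, anosim_exact_p_oracle(d, g), tolerance = 1e-12)
  # independent reference implementation agrees on the statistic
  ref <- vegan::anosim(stats::as.dist(d), factor(g), permutations = 0)
  expect_equal(res$r_statistic, unname(ref$statistic), tolerance = 1e-12)
  # seeded runs are reproducible
  a1 <- anosim(d, g, n_permutations = 199, seed = 7)
  a2 <- anosim(d, g, n_permutations = 199, seed = 7)
  expect_identical(a1$p_value, a2$p_value)
  expect_true(a1$p_value >= 1 / 200)
})

test_that("fraction_vs_age_regression handles signal, constants and errors", {
  age <- seq(10, 100, by = 10)
  res <- fraction_vs_age_regression(0.001 * age, age)
  expect_equal(res$r_squared, 1)
  expect_gt(res$slope, 0)
  expect_lt(res$p_value, 1e-6)
  cst <- fraction_vs_age_regression(rep(0.3, 10), age)
  expect_equal(cst$slope, 0)
  expect_equal(cst$p_value, 1)
  expect_error(fraction_vs_age_regression(runif(5), rep(1, 5)),
               "zero variance in age")
})

test_that("community_table validates groups and totals", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("t1", "t2")))
  expect_error(community_table(m, taxon_groups = c(t1 = "g")), "t2")
  expect_error(make_ct(m, totals = c(1e9, 2e9)), "named")
  ct <- make_ct(m, groups = c(t1 = "diatom", t2 = "green_alga"),
                totals = c(s1 = 1e9, s2 = 2e9))
  gf <- group_fractions(ct)
  expect_equal(unname(rowSums(gf)), c(1, 1), tolerance = 1e-12)
  est <- partition_total_abundance(ct)
  expect_equal(unname(rowSums(est)), c(1e9, 2e9), tolerance = 1e-9 * 1e9)
})
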