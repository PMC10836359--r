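test_that("subgroup permutation test is seeded and handles degenerate input", {
  v <- rep(5, 30)
  res <- subgroup_permutation_test(v, 1:5, 6:10, n_permutations = 99, seed = 1)
  expect_equal(res$observed_median_difference, 0)
  expect_equal(res$p_one_sided, 1)

  set.seed(2); v2 <- rnorm(40)
  r1 <- subgroup_permutation_test(v2, 1:10, 11:20, n_permutations = 500, seed = 7)
  r2 <- subgroup_permutation_test(v2, 1:10, 11:20, n_permutations = 500, seed = 7)
  expect_identical(r1, r2)
  expect_gte(r1$p_one_sided, 1 / 501)

  expect_error(subgroup_permutation_test(v2, 1:5, 5:9, n_permutations = 9), "disjoint")
  expect_error(subgroup_permutation_test(v2, 1:5, 6:10, pool = 1:9), "pool")
  expect_error(subgroup_permutation_test(v2, 1:5, 6:9, n_permutations = 9), "same size")
})

test_that("named sample ids resolve into indices", {
  v <- setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  res <- subgroup_permutation_test(v, c("s1", "s2"), c("s5", "s6"),
                                   n_permutations = 200, seed = 3)
  expect_equal(res$observed_median_difference, 4)
})

test_that("label-permutation null restricts draws to the selected samples", {
  set.seed(5); v <- rnorm(30)
  res <- subgroup_permutation_test(v, 1:4, 5:8, n_permutations = 300, seed = 2,
                                   null = "labels")
  expect_equal(res$null, "labels")
  expect_gte(res$p_one_sided, 1 / 301)
})

test_that("pairwise comparisons against control share the BH code path", {
  set.seed(11)
  values <- c(rnorm(30), rnorm(10), rnorm(10, mean = 3), rnorm(10))
  groups <- rep(c("control", "g1", "g2", "g3"), c(30, 10, 10, 10))
  res <- pairwise_vs_control(values, groups)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_bh, qmprof:::adjust_bh(res$p_raw))
  expect_equal(res$group[which.min(res$p_bh)], "g2")
  expect_error(pairwise_vs_control(values, rep("x", 60)), "absent")
})

test_that("a strongly shifted group attains the smallest adjusted p", {
  hits <- 0
  for (r in 1:20) {
    withr::with_seed(100 + r, {
      values <- c(rnorm(20), rnorm(10), rnorm(10, mean = 5))
      groups <- rep(c("control", "g1", "g2"), c(20, 10, 10))
      res <- pairwise_vs_control(values, groups)
      hits <- hits + (res$group[which.min(res$p_raw)] == "g2")
    })
  }
  expect_gte(hits, 19)
})

test_that("Kruskal-Wallis reproduces the worked three-group example", {
  res <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(res$statistic, 7.2)
  expect_equal(res$df, 2)

  # two-group case agrees with the rank-sum normal approximation
  set.seed(3)
  v <- rnorm(24)
  g <- rep(c("a", "b"), each = 12)
  kw <- kruskal_wallis(v, g)
  wt <- wilcox.test(v[g == "a"], v[g == "b"], exact = FALSE, correct = FALSE)
  expect_equal(kw$p, wt$p.value, tolerance = 1e-10)

  expect_equal(kruskal_wallis(rep(1, 10), rep(c("a", "b"), 5))$p, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two groups")
})

test_that("Monte-Carlo Fisher test approximates the exact test", {
  tab <- matrix(c(3, 1, 1, 3), 2)
  res <- contingency_test(tab, "fisher_mc", n_mc = 50000, seed = 1)
  exact <- fisher.test(tab)$p.value # 0.4857
  expect_equal(res$p, exact, tolerance = 0.02)

  # invariant to an all-zero category
  tab3 <- rbind(tab, c(0, 0))
  res3 <- contingency_test(tab3, "fisher_mc", n_mc = 50000, seed = 1)
  expect_equal(res3$p, res$p)

  chi <- contingency_test(matrix(c(20, 10, 10, 25), 2), "chi2")
  ref <- chisq.test(matrix(c(20, 10, 10, 25), 2), correct = FALSE)
  expect_equal(chi$p, ref$p.value)

  expect_error(contingency_test(matrix(c(5, 5, 0, 0), 2), "chi2"), "non-empty")
  expect_error(contingency_test(matrix(c(1.5, 1, 2, 1), 2)), "integers")
})
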