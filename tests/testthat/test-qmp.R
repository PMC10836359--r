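test_that("copy-number correction divides counts by copy numbers", {
  m <- named_counts(matrix(c(40, 60), 2, 1))
  corr <- copy_number_correct(m, c(t01 = 2, t02 = 3))
  expect_equal(unname(corr[, 1]), c(20, 20))
  expect_equal(colSums(corr), c(s01 = 40))

  expect_equal(copy_number_correct(m, c(t01 = 1, t02 = 1)), m)
  z <- named_counts(matrix(c(0, 5), 2, 1))
  expect_equal(copy_number_correct(z, c(t01 = 7.3, t02 = 5))[1, 1], 0)
  expect_error(copy_number_correct(m, c(t01 = 2)), "t02")
})

test_that("sampling depth is corrected depth over load", {
  expect_equal(sampling_depth(40, 1e9), 4e-8)
  expect_equal(sampling_depth(40, 2e9), 2e-8)
  expect_equal(sampling_depth(0, 1e9), 0)
  expect_error(sampling_depth(40, 0), "positive")
})

test_that("QMP columns rescale to the microbial loads", {
  # one-taxon samples with equal sampling depths: no downsizing beyond rounding
  counts <- named_counts(matrix(c(500, 5000), 1, 2))
  cn <- c(t01 = 1)
  loads <- c(s01 = 1e9, s02 = 1e10)
  q <- qmp_transform(counts, cn, loads, seed = 3)
  expect_equal(q$even_sampling_depth, 5e-7)
  expect_equal(unname(q$target_reads), c(500, 5000))
  expect_equal(colSums(q$cells_per_gram), loads)
  expect_equal(nrow(q$excluded_samples), 0)

  # identical samples with equal loads are bit-identical under a fixed seed
  m <- named_counts(matrix(rep(c(100L, 50L, 30L), 2), nrow = 3))
  q2 <- qmp_transform(m, c(t01 = 1, t02 = 1, t03 = 1),
                      c(s01 = 1e9, s02 = 1e9), seed = 9)
  q3 <- qmp_transform(m, c(t01 = 1, t02 = 1, t03 = 1),
                      c(s01 = 1e9, s02 = 1e9), seed = 9)
  expect_identical(q2$cells_per_gram, q3$cells_per_gram)
})

test_that("shallow samples are excluded and the transform is stable", {
  # sample s03's corrected depth is 100 < 150: it must be excluded
  counts <- named_counts(cbind(c(4000, 3000, 3000), c(2000, 1500, 1500),
                               c(40, 30, 30)))
  cn <- c(t01 = 1, t02 = 1, t03 = 1)
  loads <- c(s01 = 1e10, s02 = 1e10, s03 = 1e10)
  q <- qmp_transform(counts, cn, loads, min_rarefied_reads = 150, seed = 4)
  expect_equal(q$excluded_samples$sample_id, "s03")
  expect_match(q$excluded_samples$reason, "rarefied depth < 150")
  expect_setequal(colnames(q$cells_per_gram), c("s01", "s02"))

  # re-running on the retained set reproduces the result (fixed point)
  q_again <- qmp_transform(counts[, c("s01", "s02")], cn,
                           loads[c("s01", "s02")], seed = 4)
  expect_equal(q_again$cells_per_gram, q$cells_per_gram)
  expect_equal(q_again$even_sampling_depth, q$even_sampling_depth)

  expect_error(qmp_transform(counts[, 3, drop = FALSE], cn, loads[3], seed = 1),
               "all samples excluded")
})

test_that("QMP conservation and even depth hold on a simulated cohort", {
  cohort <- simulate_cohort(tiny_sim_config(seed = 21))
  q <- qmp_transform(cohort$counts, cohort$copy_numbers, cohort$loads, seed = 2)
  loads <- cohort$loads[colnames(q$cells_per_gram)]
  expect_true(all(abs(colSums(q$cells_per_gram) - loads) / loads < 0.005))
  # T_i / L_i constant across retained samples up to rounding of T_i and of
  # the integer urn (half a read per taxon at worst)
  slack <- 0.5 + nrow(cohort$counts) / 2
  expect_true(all(abs(q$target_reads - q$even_sampling_depth * loads) <= slack))
})

test_that("relative profiles are proportions", {
  m <- named_counts(matrix(c(2, 2, 1, 3), 2, 2))
  r <- to_relative(m)
  expect_equal(unname(r[, 1]), c(0.5, 0.5))
  expect_equal(unname(r[, 2]), c(0.25, 0.75))
  expect_equal(to_relative(m * 10), r)
  expect_true(all(abs(colSums(r) - 1) < 1e-12))
  bad <- named_counts(matrix(c(1, 1, 0, 0), 2, 2))
  expect_error(to_relative(bad), "s02")
})

test_that("taxonomic aggregation preserves per-sample totals", {
  m <- named_counts(matrix(c(3, 4, 5, 1, 2, 3), 3, 2))
  tax <- tibble::tibble(taxon_id = c("t01", "t02", "t03"),
                        family = c("F1", "F1", NA),
                        genus = c("G1", "G1", "G2"))
  g <- aggregate_taxa(m, tax, "genus")
  expect_equal(g["G1", ], m["t01", ] + m["t02", ])
  expect_equal(colSums(g), colSums(m))
  f <- aggregate_taxa(m, tax, "family")
  expect_true("unclassified_family" %in% rownames(f))
  expect_equal(f["unclassified_family", ], m["t03", ])
  expect_error(aggregate_taxa(m, tax[1:2, ], "genus"), "absent")
})
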