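test_that("single-component fit matches a direct DM optimiser", {
  dat <- make_block_dmm(n = 40, s = 5, k = 1, depth = 500, seed = 2)
  fit <- dmm_fit(dat$counts, k = 1, seed = 3, n_restarts = 1,
                 max_iter = 2000, tol = 1e-10)
  # independent oracle: BFGS on log-concentrations of the one-component DM
  x <- t(dat$counts)
  lmc <- lgamma(rowSums(x) + 1) - rowSums(lgamma(x + 1))
  nll <- function(la) {
    a <- exp(la)
    -(sum(lgamma(sum(a)) - lgamma(rowSums(x) + sum(a)) +
            rowSums(lgamma(sweep(x, 2, a, `+`))) - sum(lgamma(a)) + lmc))
  }
  start <- log(10 * colMeans(x / rowSums(x))) # moment-matched start
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-6)
})

test_that("duplicating every sample doubles the log-likelihood", {
  dat <- make_block_dmm(n = 30, s = 6, k = 1, depth = 400, seed = 5)
  fit1 <- dmm_fit(dat$counts, 1, seed = 1, n_restarts = 1, max_iter = 1000, tol = 1e-9)
  dup <- cbind(dat$counts, dat$counts)
  colnames(dup) <- sprintf("d%03d", seq_len(ncol(dup)))
  fit2 <- dmm_fit(dup, 1, seed = 1, n_restarts = 1, max_iter = 1000, tol = 1e-9)
  expect_equal(fit2$log_likelihood, 2 * fit1$log_likelihood, tolerance = 1e-4)
  expect_equal(unname(fit2$alpha), unname(fit1$alpha), tolerance = 1e-3)
})

test_that("well-separated two-component data is recovered", {
  dat <- make_block_dmm(n = 200, s = 20, k = 2, depth = 2000, seed = 11)
  fit <- dmm_fit(dat$counts, 2, seed = 4, n_restarts = 2, max_iter = 200, tol = 1e-5)
  hard <- max.col(fit$responsibilities)
  acc <- max(mean(hard == dat$z), mean(hard == 3 - dat$z))
  expect_gte(acc, 0.95)
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-9))
  expect_true(all(fit$alpha > 0))

  # likelihood is non-decreasing in K (best of restarts, within noise)
  fit1 <- dmm_fit(dat$counts, 1, seed = 4, n_restarts = 1, max_iter = 200, tol = 1e-5)
  expect_gte(fit$log_likelihood, fit1$log_likelihood - 1e-6)
})

test_that("model selection prefers K = 1 when only one K is offered", {
  dat <- make_block_dmm(n = 25, s = 5, k = 1, depth = 300, seed = 6)
  sel <- dmm_select(dat$counts, k_range = 1, seed = 2, n_restarts = 1,
                    max_iter = 200, tol = 1e-5)
  expect_equal(sel$best_k, 1)
  expect_equal(nrow(sel$scores), 1)
  # BIC definition: nu = (K-1) + K*S
  g <- glance(sel$best_model)
  expect_equal(g$n_parameters, 0 + 1 * 5)
  expect_equal(g$bic, -2 * g$log_likelihood + 5 * log(25))
})

test_that("assignment is consistent, label-symmetric and flags empty samples", {
  dat <- make_block_dmm(n = 120, s = 12, k = 2, depth = 2000, seed = 9)
  fit <- dmm_fit(dat$counts, 2, seed = 2, n_restarts = 2, max_iter = 200, tol = 1e-5)
  # a deep draw from component 2's concentration lands in component 2
  withr::with_seed(33, {
    p <- qmprof:::rdirichlet_one(fit$alpha[, 2])
    new <- matrix(rmultinom(1, 20000, p)[, 1], ncol = 1,
                  dimnames = list(rownames(dat$counts), "new1"))
  })
  asn <- assign_enterotypes(fit, new)
  expect_equal(asn$component, 2L)

  zero <- matrix(0L, nrow(dat$counts), 1,
                 dimnames = list(rownames(dat$counts), "empty"))
  asn0 <- assign_enterotypes(fit, zero)
  expect_true(is.na(asn0$component))
  expect_equal(asn0$label, "unassigned")

  # permuting the label map permutes labels, not assignments
  a1 <- assign_enterotypes(fit, dat$counts, label_map = c(`1` = "A", `2` = "B"))
  a2 <- assign_enterotypes(fit, dat$counts, label_map = c(`1` = "B", `2` = "A"))
  expect_equal(a1$component, a2$component)
  expect_equal(a1$label == "A", a2$label == "B")
})

test_that("enterotype labels derive from dominant genera", {
  panel <- make_enterotype_panel(250, n_taxa = 24, depth = 4000, seed = 13)
  fit <- dmm_fit(panel$counts, 4, seed = 5, n_restarts = 2, max_iter = 150, tol = 1e-4)
  labels <- derive_enterotype_labels(fit)
  expect_setequal(unname(labels), c("Bact1", "Bact2", "Prev", "Rum"))
  asn <- assign_enterotypes(fit, panel$counts)
  truth <- c("Bact1", "Bact2", "Prev", "Rum")[panel$enterotype]
  expect_gte(mean(asn$label == truth), 0.9)
})

test_that("rarefied genus richness counts surviving genera", {
  m <- matrix(0L, 21, 3, dimnames = list(sprintf("g%02d", 1:21),
                                         c("exact", "uniform", "shallow")))
  m[1:4, "exact"] <- c(4000L, 3000L, 2000L, 1000L)  # exactly 10000 reads
  m[1:20, "uniform"] <- 5000L                        # uniform over 20 genera
  m[1:3, "shallow"] <- c(5000L, 4000L, 999L)         # 9999 reads
  r <- rarefied_genus_richness(m, depth = 10000, seed = 7)
  expect_equal(r$richness[r$sample_id == "exact"], 4L)
  expect_equal(r$richness[r$sample_id == "uniform"], 20L)
  expect_true(is.na(r$richness[r$sample_id == "shallow"]))
  expect_true(r$excluded[r$sample_id == "shallow"])
})

test_that("DMM rejects invalid inputs", {
  m <- named_counts(matrix(c(1.5, 2, 3, 4), 2, 2))
  expect_error(dmm_fit(m, 1, seed = 1), "integer")
  good <- named_counts(matrix(rpois(8, 20), 2, 4))
  expect_error(dmm_fit(good, 5, seed = 1), "more samples")
})
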