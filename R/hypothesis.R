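#' Permutation test on subgroup median differences
#'
#' Compares the median abundance between two selected subgroups of size `k`
#' against a null built by repeatedly drawing two disjoint random size-`k`
#' groups from the whole cohort and recomputing the median difference. The
#' one-sided p-value counts null differences at least as extreme as observed,
#' with the observed statistic included in the null set
#' (\eqn{p = (1 + \#\{\Delta^\pi \ge \Delta\})/(1 + n_{perm})}).
#'
#' @param values Per-sample abundances over the whole cohort (named or
#'   positional).
#' @param idx_a,idx_b Disjoint index (or sample-id) sets of equal size `k`;
#'   the observed statistic is `median(values[idx_b]) - median(values[idx_a])`.
#' @param pool Indices eligible for the null draws (default: all of `values`).
#' @param n_permutations Number of permutation samples (default 10000).
#' @param seed Integer seed.
#' @param direction `"greater"` (default; alternative: b exceeds a),
#'   `"less"`, or `"two.sided"`.
#' @param null `"redraw"` (default: both null groups redrawn from `pool`) or
#'   `"labels"` (labels permuted within the 2k selected samples only).
#' @return Object of class `permutation_test_result` (also a tibble):
#'   `observed_median_difference`, `p_one_sided`, `n_permutations`,
#'   `group_size`, `direction`, `null`, `seed`.
#' @export
subgroup_permutation_test <- function(values, idx_a, idx_b,
                                      pool = seq_along(values),
                                      n_permutations = 10000L, seed = NULL,
                                      direction = c("greater", "less", "two.sided"),
                                      null = c("redraw", "labels")) {
  direction <- match.arg(direction)
  null <- match.arg(null)
  if (is.character(idx_a)) idx_a <- match(idx_a, names(values))
  if (is.character(idx_b)) idx_b <- match(idx_b, names(values))
  if (is.character(pool)) pool <- match(pool, names(values))
  if (anyNA(c(idx_a, idx_b, pool))) abort("unknown sample ids in index sets")
  k <- length(idx_a)
  if (length(idx_b) != k) abort("`idx_a` and `idx_b` must have the same size")
  if (length(intersect(idx_a, idx_b))) abort("`idx_a` and `idx_b` must be disjoint")
  if (!all(c(idx_a, idx_b) %in% pool)) abort("`pool` must contain both index sets")
  if (length(pool) < 2 * k) abort("`pool` must hold at least 2k samples")

  observed <- median(values[idx_b]) - median(values[idx_a])
  null_diff <- with_seed_maybe(seed, {
    vapply(seq_len(n_permutations), function(i) {
      if (null == "redraw") {
        draw <- sample(pool, 2L * k)
      } else {
        draw <- sample(c(idx_a, idx_b))
      }
      median(values[draw[(k + 1L):(2L * k)]]) - median(values[draw[seq_len(k)]])
    }, numeric(1))
  })
  count <- switch(direction,
    greater = sum(null_diff >= observed),
    less = sum(null_diff <= observed),
    two.sided = sum(abs(null_diff) >= abs(observed))
  )
  p <- (1 + count) / (1 + n_permutations)
  structure(tibble::tibble(
    observed_median_difference = observed,
    p_one_sided = p,
    n_permutations = as.integer(n_permutations),
    group_size = as.integer(k),
    direction = direction,
    null = null,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = c("permutation_test_result", class(tibble::tibble())))
}

#' Pairwise rank-sum tests of each group against the control group
#'
#' Unpaired two-sided Wilcoxon rank-sum test of every non-control group
#' against the control group, Benjamini-Hochberg adjusted across the
#' comparisons. Groups with fewer than two members are skipped with a
#' warning.
#'
#' @param values Numeric vector (e.g. calprotectin, taxon abundance).
#' @param groups Group label per value.
#' @param control_label Reference group (default `"control"`).
#' @return Tibble `group`, `n`, `statistic`, `p_raw`, `p_bh`, `method`.
#' @export
pairwise_vs_control <- function(values, groups, control_label = "control") {
  groups <- as.character(groups)
  if (!control_label %in% groups) abort(sprintf("control group '%s' absent", control_label))
  ref <- values[groups == control_label]
  others <- setdiff(unique(groups), control_label)
  rows <- purrr::map(others, function(g) {
    v <- values[groups == g]
    if (length(v) < 2L) {
      warn(sprintf("group '%s' has fewer than 2 members; comparison skipped", g))
      return(NULL)
    }
    wt <- suppressWarnings(wilcox.test(v, ref, exact = FALSE))
    tibble::tibble(group = g, n = length(v), statistic = unname(wt$statistic),
                   p_raw = wt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- adjust_bh(out$p_raw)
  out$method <- "wilcoxon_rank_sum_vs_control"
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic against the chi-square reference; a fully tied
#' input returns p = 1 by convention.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 groups of >= 2 values).
#' @return Tibble `statistic`, `df`, `p`, `method`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) abort("need at least two groups")
  if (any(table(droplevels(groups)) < 2L)) abort("every group needs at least two values")
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(statistic = 0, df = nlevels(droplevels(groups)) - 1L,
                          p = 1, method = "kruskal_wallis"))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, method = "kruskal_wallis")
}

#' Contingency-table test (Monte-Carlo Fisher or chi-square)
#'
#' `fisher_mc` draws `n_mc` tables with the observed margins (Patefield
#' algorithm via [stats::r2dtable()]) and reports
#' \eqn{p = (1 + \#\{P(T^\pi) \le P(T_{obs})\})/(1 + n_{mc})}, i.e. the exact
#' two-sided test estimated by simulation. `chi2` is the Pearson statistic
#' against the chi-square reference.
#'
#' @param table r x c matrix of non-negative integer counts with positive
#'   margins (all-zero rows/columns are dropped first).
#' @param method `"fisher_mc"` or `"chi2"`.
#' @param n_mc Monte-Carlo table count (default 1e5).
#' @param seed Integer seed.
#' @return Tibble `statistic`, `p`, `method`, `n_mc`.
#' @export
contingency_test <- function(table, method = c("fisher_mc", "chi2"),
                             n_mc = 100000L, seed = NULL) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("contingency tables must hold non-negative integers")
  }
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2L || ncol(table) < 2L) {
    abort("contingency test needs at least 2 non-empty rows and columns")
  }
  if (method == "chi2") {
    ct <- suppressWarnings(chisq.test(table, correct = FALSE))
    return(tibble::tibble(statistic = unname(ct$statistic), p = ct$p.value,
                          method = "chi2", n_mc = NA_integer_))
  }
  log_prob <- function(tab) {
    sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
      lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
  }
  lp_obs <- log_prob(table)
  p <- with_seed_maybe(seed, {
    sims <- r2dtable(n_mc, rowSums(table), colSums(table))
    lp <- vapply(sims, function(tab) -sum(lgamma(tab + 1)), numeric(1))
    lp_obs_cells <- -sum(lgamma(table + 1)) # margins are fixed: compare cell terms
    (1 + sum(lp <= lp_obs_cells + 1e-7)) / (1 + n_mc)
  })
  tibble::tibble(statistic = lp_obs, p = p, method = "fisher_mc",
                 n_mc = as.integer(n_mc))
}
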