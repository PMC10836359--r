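#' Prevalence filter for count matrices
#'
#' Retains taxa observed with at least `min_count` reads in at least
#' `ceiling(min_fraction * n)` samples (default: at least 10 reads in 5% of
#' samples).
#'
#' @param counts Taxa x samples integer matrix (or wide data frame).
#' @param min_count Minimum per-sample count for a sample to qualify.
#' @param min_fraction Minimum fraction of qualifying samples.
#' @return Filtered matrix with attribute `removed_taxa`.
#' @export
prevalence_filter <- function(counts, min_count = 10L, min_fraction = 0.05) {
  counts <- as_count_matrix(counts)
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  if (!any(keep)) abort("prevalence filter removed every taxon")
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed_taxa") <- rownames(counts)[!keep]
  out
}

#' Monte-Carlo centred log-ratio instances
#'
#' For each sample, draws `n_mc` compositions from a
#' Dirichlet(counts + prior) posterior and maps each to centred log-ratio
#' coordinates (`log x - mean(log x)`), yielding `n_mc` CLR matrices that
#' propagate the count uncertainty of compositional data.
#'
#' @param counts Filtered taxa x samples integer matrix.
#' @param n_mc Number of Monte-Carlo instances (default 128).
#' @param prior Dirichlet prior added to every count (default 0.5).
#' @param seed Integer seed.
#' @return A taxa x samples x n_mc array of CLR values.
#' @export
clr_instances <- function(counts, n_mc = 128L, prior = 0.5, seed = NULL) {
  counts <- as_count_matrix(counts)
  s <- nrow(counts); n <- ncol(counts)
  with_seed_maybe(seed, {
    out <- array(NA_real_, dim = c(s, n, n_mc),
                 dimnames = list(rownames(counts), colnames(counts), NULL))
    shape <- counts + prior
    for (m in seq_len(n_mc)) {
      g <- matrix(rgamma(s * n, shape = shape, rate = 1), s, n)
      lg <- log(g) - log(rep(colSums(g), each = s)) # log proportions
      out[, , m] <- lg - rep(colMeans(lg), each = s)
    }
    out
  })
}

# Vectorised rank tests across the rows (taxa) of a values matrix.
# Two groups: Wilcoxon rank-sum, normal approximation with tie correction and
# continuity correction, two-sided. More groups: Kruskal-Wallis with tie
# correction against the chi-square reference.
rank_test_rows <- function(values, groups) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  groups <- as.factor(groups)
  g <- nlevels(groups)
  n <- ncol(values)
  apply(values, 1L, function(v) {
    if (length(unique(v)) == 1L) return(1) # constant vector: p = 1 by convention
    r <- rank(v)
    ties <- table(r)
    if (g == 2L) {
      idx <- groups == levels(groups)[1L]
      n1 <- sum(idx); n2 <- n - n1
      w <- sum(r[idx]) - n1 * (n1 + 1) / 2
      mu <- n1 * n2 / 2
      sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      if (sigma2 <= 0) return(1)
      z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
      2 * stats::pnorm(-max(z, 0))
    } else {
      rbar <- tapply(r, groups, mean)
      ng <- tabulate(groups)
      h <- 12 / (n * (n + 1)) * sum(ng * (rbar - (n + 1) / 2)^2)
      h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
      stats::pchisq(h, df = g - 1, lower.tail = FALSE)
    }
  })
}

#' Per-taxon differential abundance over CLR instances
#'
#' Applies a nonparametric test (Wilcoxon rank-sum for two groups,
#' Kruskal-Wallis otherwise) to each taxon within every CLR instance, reports
#' the expected p-value over instances as the raw p, Benjamini-Hochberg
#' adjusts across taxa, and summarises the effect size as the median (over
#' instances) of the between-group difference in median CLR (for two groups;
#' the range of group medians otherwise).
#'
#' @param clr Array from [clr_instances()] (taxa x samples x instances).
#' @param groups Group label per sample.
#' @param p_summary `"mean"` (expected p, default) or `"median"`.
#' @return Tibble `taxon`, `effect_size`, `p_raw`, `p_bh`, `n_mc`.
#' @export
test_per_taxon <- function(clr, groups, p_summary = c("mean", "median")) {
  p_summary <- match.arg(p_summary)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) abort("need at least two groups")
  n_mc <- dim(clr)[3L]
  taxa <- dimnames(clr)[[1L]]
  pmat <- vapply(seq_len(n_mc), function(m) rank_test_rows(clr[, , m], groups),
                 numeric(length(taxa)))
  pmat <- matrix(pmat, nrow = length(taxa))
  p_raw <- if (p_summary == "mean") rowMeans(pmat) else apply(pmat, 1L, median)

  lv <- levels(droplevels(groups))
  effect <- vapply(seq_along(taxa), function(t) {
    per_inst <- vapply(seq_len(n_mc), function(m) {
      med <- tapply(clr[t, , m], groups, median)
      if (length(lv) == 2L) med[[lv[2L]]] - med[[lv[1L]]] else diff(range(med))
    }, numeric(1))
    median(per_inst)
  }, numeric(1))

  tibble::tibble(
    taxon = taxa,
    effect_size = effect,
    p_raw = p_raw,
    p_bh = adjust_bh(p_raw),
    n_mc = n_mc
  )
}

#' Differential abundance between groups (CLR Monte-Carlo engine)
#'
#' Convenience wrapper chaining [prevalence_filter()], taxonomic aggregation,
#' [clr_instances()] and [test_per_taxon()]. The same engine expresses the
#' calprotectin analysis by passing a binary grouping at 100 ug/g.
#'
#' @param counts ASV x samples integer matrix (or wide data frame).
#' @param groups Group label per sample (in column order).
#' @param taxonomy Optional taxonomy tibble; with `rank`, counts are
#'   aggregated before testing.
#' @param rank Optional `"family"` or `"genus"`.
#' @param min_count,min_fraction Prevalence-filter parameters.
#' @param n_mc,prior,seed CLR Monte-Carlo parameters.
#' @return Tibble as [test_per_taxon()], ordered by `p_bh`.
#' @export
diff_abundance <- function(counts, groups, taxonomy = NULL, rank = NULL,
                           min_count = 10L, min_fraction = 0.05,
                           n_mc = 128L, prior = 0.5, seed = NULL) {
  counts <- as_count_matrix(counts)
  if (length(groups) != ncol(counts)) abort("one group label per sample required")
  filtered <- prevalence_filter(counts, min_count, min_fraction)
  if (!is.null(rank)) {
    if (is.null(taxonomy)) abort("aggregation at a rank requires a taxonomy table")
    filtered <- aggregate_taxa(filtered, taxonomy, rank)
  }
  clr <- clr_instances(filtered, n_mc = n_mc, prior = prior, seed = seed)
  res <- test_per_taxon(clr, groups)
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  dplyr::arrange(res, .data$p_bh, .data$p_raw)
}
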