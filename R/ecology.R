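#' Shannon diversity index
#'
#' \eqn{H = -\sum p_k \log p_k} over the positive proportions of a sample, in
#' nats by default.
#'
#' @param abundances Non-negative vector (counts or proportions), or a taxa x
#'   samples matrix (one index per column).
#' @param base Logarithm base (default `exp(1)`).
#' @return Numeric value, or named vector for matrix input.
#' @examples
#' shannon(rep(1, 4)) # log(4)
#' @export
shannon <- function(abundances, base = exp(1)) {
  if (is.matrix(abundances)) {
    return(apply(abundances, 2L, shannon, base = base))
  }
  if (any(abundances < 0)) abort("abundances must be non-negative")
  total <- sum(abundances)
  if (total == 0) abort("cannot compute diversity of an all-zero sample")
  p <- abundances[abundances > 0] / total
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d_{ij} = 1 - 2 \sum_k \min(x_{ki}, x_{kj}) / (\sum_k x_{ki} + \sum_k x_{kj})}
#' between all sample pairs of a taxa x samples matrix.
#'
#' @param matrix Non-negative taxa x samples matrix (counts, proportions or
#'   cells per gram).
#' @return A symmetric n x n matrix of class `dist_matrix` with zero diagonal
#'   and sample ids as dimnames.
#' @export
bray_curtis <- function(matrix) {
  matrix <- as_count_matrix(matrix, integer_counts = FALSE)
  if (any(colSums(matrix) == 0)) abort("all-zero samples have no Bray-Curtis distance")
  d <- as.matrix(vegan::vegdist(t(matrix), method = "bray"))
  diag(d) <- 0
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of the squared distances,
#' \eqn{B = -\tfrac12 J D^2 J}, followed by an eigendecomposition;
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues. Negative eigenvalues (non-Euclidean distances) are reported
#' uncorrected.
#'
#' @param dist Symmetric distance matrix (e.g. from [bray_curtis()]).
#' @param n_axes Number of axes to keep (truncated with a warning if fewer
#'   positive eigenvalues exist).
#' @return Object of class `pcoa_result`: `coordinates` (n x m), `eigenvalues`
#'   (all, decreasing), `proportion_explained` (over positive eigenvalues).
#' @export
pcoa <- function(dist, n_axes = 2L) {
  d <- unclass(as.matrix(dist))
  stopifnot(nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-12) abort("distance matrix must be symmetric")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-9 * max(abs(e$values)))
  if (n_axes > length(pos)) {
    warn(sprintf("only %d positive eigenvalues; truncating to %d axes",
                 length(pos), length(pos)))
    n_axes <- length(pos)
  }
  axes <- pos[seq_len(n_axes)]
  coords <- sweep(e$vectors[, axes, drop = FALSE], 2L, sqrt(e$values[axes]), `*`)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    proportion_explained = e$values[pos] / sum(e$values[pos])
  ), class = "pcoa_result")
}

#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "sample_id")
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' PERMANOVA on a dissimilarity matrix: with \eqn{SS_{total} =
#' \frac1n\sum_{i<j} d_{ij}^2} and \eqn{SS_{within} = \sum_g \frac1{n_g}
#' \sum_{i<j \in g} d_{ij}^2}, the pseudo-F statistic is
#' \eqn{F = \frac{SS_{between}/(g-1)}{SS_{within}/(n-g)}} and the p-value is
#' estimated by seeded label permutation with the observed statistic included
#' in the null set: \eqn{p = (1 + \#\{F^\pi \ge F\})/(1 + n_{perm})}.
#'
#' @param dist Symmetric distance matrix with sample dimnames.
#' @param labels Group label per sample (in distance-matrix order).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed.
#' @return Object of class `permanova_result` with `pseudo_F`, `R2`, `p`,
#'   `df_between`, `df_within`, `n_permutations`, `seed`.
#' @export
permanova <- function(dist, labels, n_permutations = 999L, seed = NULL) {
  d <- unclass(as.matrix(dist))
  n <- nrow(d)
  labels <- as.factor(labels)
  if (length(labels) != n) abort("one label per sample required")
  if (nlevels(droplevels(labels)) < 2L) abort("PERMANOVA needs at least two groups")
  if (any(table(labels) < 2L)) abort("every group needs at least two samples")
  d2 <- d^2
  g <- nlevels(labels)

  ss <- permanova_ss(d2, labels)
  f_obs <- (ss$between / (g - 1)) / (ss$within / (n - g))

  f_null <- with_seed_maybe(seed, {
    vapply(seq_len(n_permutations), function(i) {
      ssp <- permanova_ss(d2, sample(labels))
      (ssp$between / (g - 1)) / (ssp$within / (n - g))
    }, numeric(1))
  })
  p <- (1 + sum(f_null >= f_obs)) / (1 + n_permutations)

  structure(list(
    pseudo_F = f_obs,
    R2 = ss$between / ss$total,
    p = p,
    ss_between = ss$between, ss_within = ss$within, ss_total = ss$total,
    df_between = g - 1L, df_within = n - g,
    n_permutations = as.integer(n_permutations),
    seed = seed
  ), class = "permanova_result")
}

permanova_ss <- function(d2, labels) {
  n <- nrow(d2)
  total <- sum(d2) / (2 * n)
  within <- 0
  for (lev in levels(labels)) {
    idx <- which(labels == lev)
    within <- within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  list(total = total, within = within, between = total - within)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_permutations))
  invisible(x)
}

#' @method tidy permanova_result
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble::tibble(
    term = c("group", "residual", "total"),
    df = c(x$df_between, x$df_within, x$df_between + x$df_within),
    sum_of_squares = c(x$ss_between, x$ss_within, x$ss_total),
    statistic = c(x$pseudo_F, NA, NA),
    R2 = c(x$R2, 1 - x$R2, 1),
    p.value = c(x$p, NA, NA)
  )
}

#' @method glance permanova_result
#' @export
glance.permanova_result <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p.value = x$p,
                 n_permutations = x$n_permutations)
}
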