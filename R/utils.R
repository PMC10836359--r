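#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median rbinom rgamma rhyper rlnorm rmultinom rnbinom rnorm
#'   runif setNames p.adjust kruskal.test wilcox.test chisq.test pchisq r2dtable
#'   quantile sd var optim rbeta
#' @importFrom utils head modifyList
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Run `expr` under a fixed RNG state when `seed` is given, otherwise use the
# session RNG. All stochastic entry points funnel through this.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Single Benjamini-Hochberg code path shared by every module.
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

assert_count_matrix <- function(x, integer_counts = TRUE, arg = "counts") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric taxa x samples matrix", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must have taxon rownames and sample colnames", arg))
  }
  if (anyDuplicated(rownames(x))) abort(sprintf("duplicate taxon ids in `%s`", arg))
  if (anyDuplicated(colnames(x))) abort(sprintf("duplicate sample ids in `%s`", arg))
  if (any(x < 0)) abort(sprintf("negative values in `%s`", arg))
  if (integer_counts && any(x != round(x))) {
    abort(sprintf("`%s` must contain integer counts", arg))
  }
  invisible(x)
}

# Accept either a taxa x samples matrix or a wide data frame whose first column
# holds taxon ids (the counts.tsv dialect); return a base matrix.
as_count_matrix <- function(x, integer_counts = TRUE, arg = "counts") {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
    x <- m
  }
  storage.mode(x) <- "double"
  assert_count_matrix(x, integer_counts = integer_counts, arg = arg)
  x
}

# log(sum(exp(x))) per row, guarded against -Inf rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}
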