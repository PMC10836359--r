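#' Rarefy count vectors without replacement
#'
#' Downsizes integer count vectors to a fixed number of reads by sampling
#' without replacement, i.e. a draw from the multivariate hypergeometric
#' distribution over the sample's reads. This is the downsizing primitive used
#' both by the quantitative-profiling transform (even sampling depth) and by
#' rarefied genus richness.
#'
#' The draw is generated by sequential univariate hypergeometric sampling:
#' conditioning taxon by taxon, the count for taxon \eqn{j} given the reads
#' already allocated is hypergeometric, which yields an exact multivariate
#' hypergeometric sample in \eqn{O(S)} time per sample.
#'
#' @param counts Integer vector of counts (one sample), or a taxa x samples
#'   integer matrix.
#' @param size Target number of reads (single integer, or one per sample).
#' @param seed Optional integer seed for reproducibility.
#' @return Rarefied counts with the same shape and names as `counts`.
#' @examples
#' rarefy_counts(c(a = 50, b = 30, c = 20), size = 10, seed = 1)
#' @export
rarefy_counts <- function(counts, size, seed = NULL) {
  with_seed_maybe(seed, {
    if (is.matrix(counts)) {
      size <- rep_len(size, ncol(counts))
      out <- counts
      for (i in seq_len(ncol(counts))) {
        out[, i] <- rarefy_one(counts[, i], size[i])
      }
      out
    } else {
      out <- rarefy_one(counts, size)
      names(out) <- names(counts)
      out
    }
  })
}

rarefy_one <- function(x, size) {
  if (any(x < 0) || any(x != round(x))) abort("counts must be non-negative integers")
  total <- sum(x)
  if (size > total) {
    abort(sprintf("cannot rarefy %d reads down to %d", total, size))
  }
  out <- integer(length(x))
  remaining <- total
  left <- as.integer(size)
  for (j in seq_along(x)) {
    if (left == 0L) break
    remaining <- remaining - x[j]
    if (remaining == 0L) { # everything left must come from taxon j onward
      out[j] <- left
      left <- 0L
      break
    }
    out[j] <- rhyper(1L, x[j], remaining, left)
    left <- left - out[j]
  }
  out
}
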