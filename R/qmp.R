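#' 16S copy-number correction
#'
#' Divides each taxon's counts by its predicted 16S rRNA gene copy number, so
#' that column sums become copy-number-corrected sequencing depths (read
#' counts expressed in cell-equivalents).
#'
#' @param counts Taxa x samples integer matrix (or wide data frame).
#' @param copy_numbers Named numeric vector of per-taxon copy numbers (>= 1).
#' @return Real-valued corrected matrix with the same dimnames.
#' @examples
#' m <- matrix(c(40, 60), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' copy_number_correct(m, c(a = 2, b = 3)) # corrected depth 40
#' @export
copy_number_correct <- function(counts, copy_numbers) {
  counts <- as_count_matrix(counts)
  missing <- setdiff(rownames(counts), names(copy_numbers))
  if (length(missing)) {
    abort(sprintf("no copy number for taxa: %s", paste(missing, collapse = ", ")))
  }
  cn <- copy_numbers[rownames(counts)]
  if (any(is.na(cn) | cn < 1)) abort("copy numbers must be >= 1")
  counts / cn
}

#' Per-sample sampling depth
#'
#' The sampling depth of a sample is its copy-number-corrected sequencing
#' depth divided by its microbial load (total cells per gram): the fraction of
#' the community the sequencer observed. Equalising it across samples is the
#' basis of the quantitative profiling transform.
#'
#' @param corrected_depth Copy-number-corrected depth(s), >= 0.
#' @param load Microbial load(s) in cells per gram, > 0.
#' @return `corrected_depth / load`.
#' @export
sampling_depth <- function(corrected_depth, load) {
  if (any(load <= 0)) abort("microbial loads must be positive")
  if (any(corrected_depth < 0)) abort("corrected depths must be non-negative")
  corrected_depth / load
}

#' Quantitative microbiome profiling (QMP) transform
#'
#' Converts an ASV count matrix plus per-sample microbial loads into estimated
#' cell counts per gram: counts are copy-number corrected, every sample is
#' downsized (rarefied without replacement) to the even sampling depth
#' \eqn{s^* = \min_i s_i}, samples whose target read count falls below
#' `min_rarefied_reads` are excluded (and the even depth recomputed, iterating
#' to a fixed point), and the rarefied counts are scaled back to cells per
#' gram so that each retained column sums to its sample's load.
#'
#' @param counts Taxa x samples integer matrix (or wide data frame).
#' @param copy_numbers Named per-taxon copy numbers.
#' @param loads Named per-sample microbial loads (cells/gram).
#' @param min_rarefied_reads Exclusion threshold on the rarefied read count
#'   (default 150).
#' @param seed Integer seed for the rarefaction draw.
#' @return An object of class `qmp_matrix`: `cells_per_gram` (taxa x retained
#'   samples), `excluded_samples` (tibble with reasons), `even_sampling_depth`,
#'   `target_reads` (named), `seed`.
#' @export
qmp_transform <- function(counts, copy_numbers, loads,
                          min_rarefied_reads = 150L, seed = NULL) {
  counts <- as_count_matrix(counts)
  if (!all(colnames(counts) %in% names(loads))) {
    abort("every sample needs a microbial load")
  }
  loads <- loads[colnames(counts)]
  corrected <- copy_number_correct(counts, copy_numbers)
  # integer urns for sampling without replacement (round half to even)
  urns <- round(corrected)
  urn_totals <- colSums(urns)
  s_all <- sampling_depth(colSums(corrected), loads)

  # provisional exclusion: a sample whose own corrected depth is below the
  # threshold can never reach it (T_i <= corrected depth), and keeping it
  # would drag the even depth below usability for everyone else
  retained <- colnames(counts)
  excluded <- tibble::tibble(sample_id = character(), reason = character())
  hopeless <- retained[urn_totals < min_rarefied_reads]
  if (length(hopeless)) {
    excluded <- tibble::tibble(
      sample_id = hopeless,
      reason = sprintf("rarefied depth < %d", min_rarefied_reads)
    )
    retained <- setdiff(retained, hopeless)
    if (length(retained) == 0L) abort("all samples excluded by the rarefied-read threshold")
  }
  repeat {
    s_star <- min(s_all[retained])
    target <- round(s_star * loads[retained])
    drop <- retained[target < min_rarefied_reads]
    if (length(drop) == 0L) break
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      sample_id = drop,
      reason = sprintf("rarefied depth < %d", min_rarefied_reads)
    ))
    retained <- setdiff(retained, drop)
    if (length(retained) == 0L) abort("all samples excluded by the rarefied-read threshold")
  }
  # rounding the urn can leave marginally fewer reads than the real-valued
  # corrected depth implies; cap the target at what the urn holds
  target <- pmin(target, urn_totals[retained])

  rarefied <- rarefy_counts(urns[, retained, drop = FALSE], target, seed = seed)
  cpg <- sweep(rarefied, 2L, loads[retained] / pmax(target, 1), `*`)

  structure(list(
    cells_per_gram = cpg,
    excluded_samples = excluded,
    even_sampling_depth = s_star,
    target_reads = target,
    sampling_depths = s_all,
    seed = seed
  ), class = "qmp_matrix")
}

#' @export
print.qmp_matrix <- function(x, ...) {
  cat(sprintf(
    "QMP matrix: %d taxa x %d samples (%d excluded), even sampling depth %.3g\n",
    nrow(x$cells_per_gram), ncol(x$cells_per_gram),
    nrow(x$excluded_samples), x$even_sampling_depth
  ))
  invisible(x)
}

#' @describeIn qmp_transform tidy view: one row per taxon/sample with
#'   estimated cells per gram.
#' @param x A `qmp_matrix`.
#' @param ... Unused.
#' @method tidy qmp_matrix
#' @export
tidy.qmp_matrix <- function(x, ...) {
  tibble::as_tibble(x$cells_per_gram, rownames = "taxon_id") |>
    tidyr::pivot_longer(-"taxon_id", names_to = "sample_id",
                        values_to = "cells_per_gram")
}

#' Relative microbiome profile (proportions)
#'
#' @param counts Taxa x samples non-negative matrix (or wide data frame).
#' @return Matrix of per-sample proportions; each column sums to 1.
#' @export
to_relative <- function(counts) {
  counts <- as_count_matrix(counts, integer_counts = FALSE)
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero)) {
    abort(sprintf("samples with zero total count: %s", paste(zero, collapse = ", ")))
  }
  sweep(counts, 2L, totals, `/`)
}

#' Aggregate a taxon matrix at a taxonomic rank
#'
#' Sums rows sharing the same label at the requested rank; taxa without a
#' label at that rank fall into an `unclassified_<rank>` bucket. Per-sample
#' totals are preserved.
#'
#' @param matrix Taxa x samples matrix (counts or abundances); rownames are
#'   `taxon_id`s.
#' @param taxonomy Tibble with `taxon_id` and the rank columns.
#' @param rank `"family"` or `"genus"`.
#' @return Aggregated matrix with rank labels as rownames.
#' @export
aggregate_taxa <- function(matrix, taxonomy, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  matrix <- as_count_matrix(matrix, integer_counts = FALSE)
  unknown <- setdiff(rownames(matrix), taxonomy$taxon_id)
  if (length(unknown)) {
    abort(sprintf("taxa absent from the taxonomy table: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  labels <- taxonomy[[rank]][match(rownames(matrix), taxonomy$taxon_id)]
  labels[is.na(labels) | labels == ""] <- paste0("unclassified_", rank)
  rowsum(matrix, group = labels)
}
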