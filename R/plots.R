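#' Ordination plot
#'
#' Scatter of the first two principal coordinates, optionally coloured by
#' group.
#'
#' @param object A `pcoa_result`.
#' @param groups Optional named (or positional) group label per sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  pe <- object$proportion_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2))
  if (!is.null(groups)) {
    df$group <- if (!is.null(names(groups))) groups[df$sample_id] else groups
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                          colour = .data$group))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * pe[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * pe[2])
    ) +
    ggplot2::theme_minimal()
}

#' BIC curve of a Dirichlet-multinomial model selection
#'
#' @param object A `dmm_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dmm_selection
#' @export
autoplot.dmm_selection <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$scores[object$scores$k == object$best_k, ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "number of Dirichlet components K", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Per-group abundance boxplot for one taxon
#'
#' @param matrix Taxa x samples abundance matrix (QMP cells/gram or RMP
#'   proportions).
#' @param taxon Row to plot.
#' @param groups Named group label per sample.
#' @param log_scale Use a log10 y axis (default `TRUE`; zeros offset by half
#'   the smallest positive value).
#' @return A ggplot object.
#' @export
plot_taxon_by_group <- function(matrix, taxon, groups, log_scale = TRUE) {
  if (!taxon %in% rownames(matrix)) abort(sprintf("taxon '%s' not in matrix", taxon))
  v <- matrix[taxon, ]
  df <- tibble::tibble(sample_id = colnames(matrix), abundance = v,
                       group = groups[colnames(matrix)])
  if (log_scale) {
    eps <- min(v[v > 0]) / 2
    df$abundance <- df$abundance + eps
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$abundance)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = taxon) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Enterotype composition by group
#'
#' Stacked proportion bars of enterotype labels within each group.
#'
#' @param enterotypes Tibble from [assign_enterotypes()].
#' @param groups Named group label per sample.
#' @return A ggplot object.
#' @export
plot_enterotypes_by_group <- function(enterotypes, groups) {
  df <- enterotypes
  df$group <- groups[df$sample_id]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, fill = .data$label)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of samples", fill = "enterotype") +
    ggplot2::theme_minimal()
}
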