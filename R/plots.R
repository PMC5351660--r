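#' Plot per-sample REO consistency scores by exclusion fraction
#'
#' One box per exclusion fraction over the per-sample-pair consistency
#' scores, the usual view of how discarding closest-expressed gene pairs
#' firms up the orderings.
#'
#' @param object A [cohort_consistency()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reo_consistency <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$fraction), y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = "excluded fraction of closest gene pairs",
                  y = "REO consistency score (k/n)") +
    ggplot2::ylim(min(object$score) * 0.98, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.reo_consistency
#' @param x A `reo_consistency` tibble.
#' @export
plot_consistency <- function(x, ...) autoplot.reo_consistency(x, ...)

#' Plot the DEG fold-change histogram
#'
#' Bar chart of DEG counts per `|log2FC|` bin (see [fold_change_bins()]).
#'
#' @param object A `reo_fc_bins` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reo_fc_bins <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "|log2 fold change| (FFPE vs FF)", y = "DEG count") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.reo_fc_bins
#' @param x A `reo_fc_bins` tibble.
#' @export
plot_fold_change_bins <- function(x, ...) autoplot.reo_fc_bins(x, ...)
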