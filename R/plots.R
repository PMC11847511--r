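#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-cell-type accuracy of a metric report
#'
#' Bar panels of per-cell-type CCC and MAE (higher CCC, lower MAE = better).
#'
#' @param object a `metric_report` from [evaluate()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_celltype, cols = c("ccc", "mae"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$celltype, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-cell-type deconvolution accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of patch-attention maps
#'
#' One tile panel per chromosome of the symmetrized patch-by-patch attention
#' weights.
#'
#' @param object an `attention_map` from [extract_attention()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot attention_map
#' @export
autoplot.attention_map <- function(object, ...) {
  df <- tidy.attention_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patch_i, y = .data$patch_j,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "patch", y = "patch", fill = "attention",
                  title = "Patch attention by chromosome") +
    ggplot2::theme_minimal()
}

#' Scatter plot of true versus predicted proportions
#'
#' @param P_true,P_hat `samples x k` proportion matrices.
#' @return a ggplot object with the identity line.
#' @export
plot_proportions <- function(P_true, P_hat) {
  P_true <- as.matrix(P_true); P_hat <- as.matrix(P_hat)
  k <- ncol(P_true)
  celltypes <- colnames(P_true) %||% paste0("type", seq_len(k))
  df <- tibble::tibble(
    truth = as.vector(P_true),
    predicted = as.vector(P_hat),
    celltype = rep(celltypes, each = nrow(P_true))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$predicted,
                                   colour = .data$celltype)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "true proportion", y = "predicted proportion") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
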