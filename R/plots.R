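#' Plots for screen results
#'
#' `autoplot()` methods give the standard views: the whole-screen embedding
#' coloured by condition, the Dunn-index probe ranking bar chart coloured by
#' probe category, and the fold-change comparison of two treatment arms.
#' [plot_probe_embedding()] zooms the global embedding onto selected probes,
#' one panel per probe.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   facet_wrap labs theme_minimal coord_flip scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' @param object a `phenoprobe_embedding`.
#' @param layout optional layout to colour points by condition.
#' @param ... ignored.
#' @rdname plots
#' @method autoplot phenoprobe_embedding
#' @export
autoplot.phenoprobe_embedding <- function(object, layout = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- if (!is.null(layout)) {
    df <- dplyr::inner_join(df, tibble::as_tibble(layout), by = "image_id")
    ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$condition))
  } else {
    ggplot(df, aes(x = .data$x, y = .data$y))
  }
  p + geom_point(alpha = 0.7, size = 1.5) +
    labs(x = "t-SNE 1", y = "t-SNE 2", colour = "condition") +
    theme_minimal()
}

#' @param embedding a `phenoprobe_embedding`.
#' @param probes character vector of probe SKUs to zoom on.
#' @rdname plots
#' @export
plot_probe_embedding <- function(embedding, layout, probes) {
  df <- dplyr::inner_join(tibble::as_tibble(embedding),
                          tibble::as_tibble(layout), by = "image_id") |>
    dplyr::filter(.data$probe_sku %in% probes)
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$condition)) +
    geom_point(size = 2) +
    facet_wrap(~probe_sku, scales = "free") +
    labs(x = "t-SNE 1", y = "t-SNE 2", colour = "condition") +
    theme_minimal()
}

#' @param top show only the strongest `top` probes (default all).
#' @rdname plots
#' @method autoplot phenoprobe_ranking
#' @export
autoplot.phenoprobe_ranking <- function(object, top = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(top)) df <- df[df$rank <= top, ]
  df$label <- sprintf("%s (%s)", df$probe_name, df$probe_sku)
  df$finite_dunn <- ifelse(is.finite(df$dunn_index), df$dunn_index,
                           max(df$dunn_index[is.finite(df$dunn_index)],
                               1) * 1.5)
  ggplot(df, aes(x = stats::reorder(.data$label, -.data$rank),
                 y = .data$finite_dunn, fill = .data$category)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "Dunn index", fill = "category") +
    theme_minimal()
}

#' @rdname plots
#' @method autoplot phenoprobe_fold_change
#' @export
autoplot.phenoprobe_fold_change <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$fold_change) & df$fold_change > 0, ]
  ggplot(df, aes(x = stats::reorder(.data$probe_sku, .data$fold_change),
                 y = .data$fold_change, fill = .data$category)) +
    geom_col() +
    geom_hline(yintercept = 1, linetype = 2) +
    coord_flip() +
    scale_y_log10() +
    labs(x = NULL, y = "Dunn index fold change (treated / control)") +
    theme_minimal()
}
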