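#' Plot a communication inference result
#'
#' Heatmap of aggregated communication: the number of significant
#' ligand-receptor pairs (or total probability) between every ordered pair
#' of cell groups.
#'
#' @param object A `comm_result`.
#' @param value `"count"` of significant pairs or total `"prob"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot comm_result
#' @export
autoplot.comm_result <- function(object, value = c("count", "prob"), ...) {
  value <- match.arg(value)
  td <- tidy(object) |> filter(.data$significant)
  agg <- td |>
    group_by(.data$source, .data$target) |>
    summarise(
      count = dplyr::n_distinct(.data$id),
      prob = sum(.data$prob), .groups = "drop"
    )
  ggplot(agg, aes(x = .data$target, y = .data$source, fill = .data[[value]])) +
    geom_tile() +
    scale_fill_gradient(low = "grey95", high = "firebrick") +
    labs(
      x = "target group", y = "source group",
      fill = if (value == "count") "significant pairs" else "total probability"
    ) +
    theme_minimal()
}

#' Plot a signaling network's centrality profile
#'
#' Bar panel of the min-max scaled relative importance of each cell group
#' under each centrality measure.
#'
#' @param object A `comm_network`.
#' @param ... Passed to [centrality_scores()].
#' @return A ggplot.
#' @method autoplot comm_network
#' @export
autoplot.comm_network <- function(object, ...) {
  sc <- centrality_scores(object, ...)
  long <- sc |>
    select("group", dplyr::ends_with("_scaled")) |>
    tidyr::pivot_longer(-"group", names_to = "measure", values_to = "importance") |>
    mutate(measure = sub("_scaled$", "", .data$measure))
  ggplot(long, aes(x = .data$group, y = .data$importance)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~measure) +
    labs(x = NULL, y = "relative importance") +
    theme_minimal()
}

#' Plot communication pattern loadings
#'
#' Tile maps of the cell-loading matrix W and signaling-loading matrix H.
#'
#' @param object A `pattern_decomposition`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pattern_decomposition
#' @export
autoplot.pattern_decomposition <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$pattern, y = .data$element, fill = .data$loading)) +
    geom_tile() +
    facet_wrap(~matrix, scales = "free_y") +
    scale_fill_gradient(low = "grey95", high = "darkgreen") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a manifold embedding of signaling networks
#'
#' @param object A [embed_manifold()] / [joint_embed()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot manifold_embedding
#' @export
autoplot.manifold_embedding <- function(object, ...) {
  has_group <- "group" %in% names(object)
  has_ds <- "dataset" %in% names(object)
  p <- ggplot(object, aes(x = .data$x, y = .data$y))
  p <- if (has_group && has_ds) {
    p + geom_point(aes(colour = .data$group, shape = .data$dataset), size = 2)
  } else if (has_group) {
    p + geom_point(aes(colour = .data$group), size = 2)
  } else {
    p + geom_point(size = 2)
  }
  p + labs(x = "UMAP 1", y = "UMAP 2") + theme_minimal()
}
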