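# ggplot2 views of the pipeline's result types.

#' Heatmap of a sensor profile matrix
#'
#' log2-scaled abundance heatmap with rows and columns arranged by
#' hierarchical clustering (average linkage), the standard view for
#' spotting ecosystem-level block structure.
#'
#' @param object A `sensor_profile`.
#' @param annotate_by Optional metadata column used to label rows.
#' @param ... Passed to [hierarchical_order()].
#' @return A ggplot object.
#' @export
autoplot.sensor_profile <- function(object, annotate_by = NULL, ...) {
  ord <- hierarchical_order(object, ...)
  df <- tidy(object) |>
    mutate(
      metagenome_id = factor(.data$metagenome_id,
                             levels = rownames(object$values)[ord$row_order]),
      cluster_id = factor(.data$cluster_id,
                          levels = colnames(object$values)[ord$col_order]),
      log2_value = log2(.data$value + min(object$values[object$values > 0]) / 2)
    )
  p <- ggplot(df, aes(x = .data$cluster_id, y = .data$metagenome_id,
                      fill = .data$log2_value)) +
    geom_tile() +
    scale_fill_viridis_c(name = "log2 fraction") +
    labs(x = "sensor cluster", y = "metagenome") +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank())
  p
}

#' Richness scatter: RER against ETSR
#'
#' One point per ecosystem, sized by its number of samples; the
#' anticorrelation between how much of global sensor diversity an
#' ecosystem spans (RER) and how much of its own repertoire a typical
#' sample carries (ETSR) is the main pattern to read off.
#'
#' @param metrics Output of [ecosystem_metrics()].
#' @param by Grouping column name used in `metrics`.
#' @return A ggplot object.
#' @export
plot_richness <- function(metrics, by = "ecosystem") {
  ggplot(metrics, aes(x = .data$rer, y = .data$etsr,
                      size = .data$n_samples, label = .data[[by]])) +
    geom_point(alpha = 0.7, colour = "steelblue") +
    scale_size_area(name = "samples") +
    labs(x = "Relative Ecosystem Richness",
         y = "Ecosystem Typical Sample Richness") +
    theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param object A `model_eval`.
#' @param normalize Row-normalize counts to per-class rates?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_eval <- function(object, normalize = TRUE, ...) {
  df <- tidy(object)
  if (normalize) {
    df <- df |>
      group_by(.data$true) |>
      mutate(n = ifelse(sum(.data$n) > 0, .data$n / sum(.data$n), 0)) |>
      ungroup()
  }
  ggplot(df, aes(x = .data$predicted, y = .data$true, fill = .data$n)) +
    geom_tile() +
    scale_fill_viridis_c(name = if (normalize) "rate" else "count") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Attribution force-scatter and ranking bar chart
#'
#' For a chosen class, plots each (sample, feature) attribution for the
#' top-ranked features: the y-axis is the feature's importance rank, the
#' x-axis the signed attribution (positive pushes the model toward the
#' class), coloured by the feature's abundance in that sample when a
#' profile is supplied.
#'
#' @param object An `attribution_table`.
#' @param class Class to display (default: first).
#' @param top Number of top features to show.
#' @param profile Optional `sensor_profile` supplying abundance colours.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attribution_table <- function(object, class = NULL, top = 20,
                                       profile = NULL, ...) {
  cls <- class %||% sort(unique(object$class))[1]
  ranks <- rank_features(object, scope = "class") |>
    filter(.data$class == cls, .data$rank <= top)
  df <- object |>
    filter(.data$class == cls, .data$feature %in% ranks$feature) |>
    left_join(select(ranks, "feature", "rank"), by = "feature")
  if (!is.null(profile)) {
    ab <- tidy(profile) |>
      rename(sample = "metagenome_id", feature = "cluster_id",
             abundance = "value")
    df <- left_join(df, ab, by = c("sample", "feature"))
    p <- ggplot(df, aes(x = .data$value, y = .data$rank,
                        colour = .data$abundance))
  } else {
    p <- ggplot(df, aes(x = .data$value, y = .data$rank))
  }
  p +
    geom_jitter(height = 0.2, alpha = 0.6) +
    scale_y_reverse(breaks = ranks$rank, labels = ranks$feature) +
    scale_colour_gradient(low = "blue", high = "red", name = "abundance") +
    labs(x = "attribution value", y = NULL, title = cls) +
    theme_minimal()
}

#' Scatter of a 2-D embedding
#'
#' @param embedding Output of [embed_profile()].
#' @param colour_by Metadata column to colour points by (if present).
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, colour_by = "ecosystem") {
  if (colour_by %in% names(embedding)) {
    p <- ggplot(embedding, aes(x = .data$dim1, y = .data$dim2,
                               colour = .data[[colour_by]]))
  } else {
    p <- ggplot(embedding, aes(x = .data$dim1, y = .data$dim2))
  }
  p + geom_point(alpha = 0.8) + theme_minimal() +
    labs(x = "t-SNE 1", y = "t-SNE 2")
}
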