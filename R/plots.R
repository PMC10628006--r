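#' Plot a within-cluster sum-of-squares elbow curve
#'
#' @param object A `chase_elbow` from [select_k_elbow()].
#' @param ... Unused.
#' @return A ggplot: WSS against k with the selected k circled.
#' @export
autoplot.chase_elbow <- function(object, ...) {
  curve <- object$curve
  chosen <- curve[curve$k == object$k_star, ]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$tot_withinss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = chosen, shape = 21, size = 5, colour = "red", stroke = 1.2
    ) +
    ggplot2::scale_x_continuous(breaks = curve$k) +
    ggplot2::labs(
      x = "Number of clusters k",
      y = "Within-cluster sum of squares",
      title = sprintf("Elbow selection: k* = %d", object$k_star)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a k-means solution over its first two clustering variables
#'
#' @param object A `chase_kmeans` from [kmeans_fit()].
#' @param data The data frame the solution was fitted on.
#' @param ... Unused.
#' @return A ggplot scatter of the first two clustering variables coloured
#'   by cluster, with centroids marked.
#' @export
autoplot.chase_kmeans <- function(object, data, ...) {
  v <- object$vars[1:2]
  d <- as_tibble(data)[, v]
  d$cluster <- factor(object$cluster)
  centers <- as_tibble(object$centers[, v, drop = FALSE])
  centers$cluster <- factor(seq_len(object$k))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data[[v[1]]], y = .data[[v[2]]], colour = .data$cluster
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = centers, shape = 4, size = 4, stroke = 2) +
    ggplot2::labs(colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Distribution of a chasing metric by risk group
#'
#' @param metrics Output of [chasing_metrics()].
#' @param players Player records with `risk_label`.
#' @param metric Name of the metric column to plot. Default
#'   `"frequent_deposit_rate"`.
#' @return A ggplot of boxplots by risk group.
#' @export
plot_metric_by_risk <- function(metrics, players,
                                metric = "frequent_deposit_rate") {
  d <- dplyr::inner_join(as_tibble(metrics), as_tibble(players),
    by = "player_id"
  )
  d$risk_label <- factor(d$risk_label, levels = c("low", "medium", "high"))
  ggplot2::ggplot(
    d[!is.na(d[[metric]]), ],
    ggplot2::aes(x = .data$risk_label, y = .data[[metric]], fill = .data$risk_label)
  ) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, show.legend = FALSE) +
    ggplot2::labs(x = "Risk group", y = metric) +
    ggplot2::theme_minimal()
}
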