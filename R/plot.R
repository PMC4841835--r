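# Plots: feature traces with key-frame colour bars (classification
# timelines) and PCA projections of feature space.  ggplot2 is optional
# (Suggests); all analysis functions work without it.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Plot feature traces with the key-frame timeline
#'
#' Reproduces the classic key-frame timeline view: one line per numeric
#' feature over time, with a colour bar above indicating which key frame of
#' the action each frame was assigned to ("N" = not assigned).
#'
#' @param result A `gdl_classification` from [classify_stream()].
#' @param feature_table A `feature_table` from
#'   [evaluate_features_stream()] for the same stream.
#' @param action Class name of the action whose timeline to show (defaults
#'   to the first).
#' @return A ggplot object.
#' @export
plot_timeline <- function(result, feature_table, action = NULL) {
  .need_ggplot()
  tl <- result$timeline
  acts <- setdiff(names(tl), "time")
  if (is.null(action)) action <- acts[1L]
  numeric_cols <- names(feature_table$columns)[
    feature_table$kinds == "numeric"]
  long <- do.call(rbind, lapply(numeric_cols, function(nm)
    data.frame(time = feature_table$times, feature = nm,
               value = feature_table$columns[[nm]])))
  band_y <- max(long$value, na.rm = TRUE) * 1.06
  band <- data.frame(time = tl$time, label = tl[[action]])
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = value,
                                     colour = feature)) +
    ggplot2::geom_line() +
    ggplot2::geom_tile(data = band,
                       ggplot2::aes(x = time, y = band_y, fill = label),
                       height = diff(range(long$value, na.rm = TRUE)) * 0.05,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "time [s]", y = "angle [deg]",
                  fill = "key frame",
                  title = paste("Key-frame timeline:", action)) +
    ggplot2::theme_minimal()
}

#' Plot a PCA projection of feature space
#'
#' Scatter of the first two principal components of the pooled feature
#' matrix; each point is one frame, coloured by its assigned key-frame
#' cluster.
#'
#' @param projection Result of [pca_project()].
#' @param model Optional `trained_model` supplying cluster assignments.
#' @return A ggplot object.
#' @export
plot_pca <- function(projection, model = NULL) {
  .need_ggplot()
  df <- data.frame(PC1 = projection$scores[, 1L],
                   PC2 = projection$scores[, 2L])
  df$cluster <- if (!is.null(model) && !is.null(model$assignments)) {
    pos <- match(model$assignments, model$temporal_order)
    factor(paste0("kf", pos))
  } else factor("frame")
  ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2, colour = cluster)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      title = "Feature-space PCA projection",
      x = sprintf("PC1 (%.1f%%)", 100 * projection$explained[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * projection$explained[2L])) +
    ggplot2::theme_minimal()
}
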