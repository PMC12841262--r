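# ggplot2 visualizations for the result types.

#' Plot GAN training diagnostics
#'
#' Four-panel view of WGAN-GP training: generator/critic losses, the
#' Wasserstein estimate, real vs generated critic scores, and the gradient
#' penalty, per epoch (faceted per class when several classes are present).
#'
#' @param object A `gan_diagnostics` tibble from [train_wgan_gp()] or
#'   [compose_augmented_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gan_diagnostics
#' @export
autoplot.gan_diagnostics <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"class_label" %in% names(df)) df$class_label <- "class"
  long <- tidyr::pivot_longer(
    df,
    cols = c(
      "generator_loss", "critic_loss", "wasserstein_estimate",
      "gradient_penalty_value", "mean_real_score", "mean_fake_score"
    ),
    names_to = "series", values_to = "value"
  )
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$class_label)) +
    geom_line(linewidth = 0.4) +
    facet_wrap(~series, scales = "free_y") +
    labs(
      x = "epoch", y = NULL, colour = "class",
      title = "WGAN-GP training diagnostics"
    ) +
    theme_minimal()
}

#' Plot classifier training curves
#'
#' Loss and accuracy on training and validation data plus the learning-rate
#' schedule, per epoch.
#'
#' @param object A `train_history` tibble from [train_classifier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot train_history
#' @export
autoplot.train_history <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("train_loss", "val_loss", "train_accuracy", "val_accuracy", "learning_rate"),
    names_to = "series", values_to = "value"
  )
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line(linewidth = 0.4, colour = "steelblue") +
    facet_wrap(~series, scales = "free_y") +
    labs(x = "epoch", y = NULL, title = "Classifier training history") +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A `metrics_report` from [evaluate_classifier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$count)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(title = sprintf("Confusion matrix (accuracy %.3f)", object$accuracy)) +
    theme_minimal()
}

#' Plot a benchmark table
#'
#' @param object A `benchmark_result` from [run_baselines()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  df <- object$table
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot(df, aes(x = .data$mean_accuracy, y = .data$model)) +
    geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(
      aes(
        xmin = .data$mean_accuracy - .data$sd_accuracy,
        xmax = .data$mean_accuracy + .data$sd_accuracy
      ),
      height = 0.25
    ) +
    labs(x = "cross-validated accuracy", y = NULL, title = "Model benchmark") +
    theme_minimal()
}

#' Plot per-gene importance
#'
#' Bar plot of the top genes by Gradient x Input importance.
#'
#' @param imp Importance tibble (`gene_id` + a numeric column).
#' @param top Number of genes shown (default 20).
#' @param column Which column to plot (default the second).
#' @return A ggplot object.
#' @export
plot_importance <- function(imp, top = 20, column = NULL) {
  column <- column %||% names(imp)[2]
  df <- dplyr::arrange(imp, dplyr::desc(.data[[column]]))[seq_len(min(top, nrow(imp))), ]
  df$gene_id <- factor(df$gene_id, levels = rev(df$gene_id))
  ggplot(df, aes(x = .data[[column]], y = .data$gene_id)) +
    geom_col(fill = "steelblue") +
    labs(x = sprintf("%s importance", column), y = NULL) +
    theme_minimal()
}

#' Plot the hub co-expression network
#'
#' Draws the hub network exported by [export_hub_network()]; edge width
#' encodes co-expression strength. Uses a circular layout so no graph
#' package is required at plot time.
#'
#' @param network A list with `nodes` and `edges` from [export_hub_network()].
#' @return A ggplot object.
#' @export
plot_hub_network <- function(network) {
  nodes <- network$nodes
  n <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  nodes$x <- cos(theta)
  nodes$y <- sin(theta)
  edges <- network$edges
  if (nrow(edges) > 0) {
    i <- match(edges$from, nodes$gene_id)
    j <- match(edges$to, nodes$gene_id)
    seg <- tibble::tibble(
      x = nodes$x[i], y = nodes$y[i], xend = nodes$x[j], yend = nodes$y[j],
      weight = edges$weight
    )
  } else {
    seg <- tibble::tibble(
      x = numeric(0), y = numeric(0), xend = numeric(0),
      yend = numeric(0), weight = numeric(0)
    )
  }
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        linewidth = .data$weight
      ),
      colour = "grey70", alpha = 0.7
    ) +
    geom_point(aes(colour = .data$category), size = 3) +
    ggplot2::geom_text(aes(label = .data$gene_id), size = 2.5, vjust = -1) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    labs(title = "Hub gene co-expression network", x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(
      axis.text = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
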