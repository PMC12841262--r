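# broom-style tidiers for the fitted objects.

#' Tidy a fitted classifier
#'
#' One row per parameter tensor with its dimensions and norm, plus the two
#' fusion scalars.
#'
#' @param x An `acmix_swin` model or `classifier_fit`.
#' @param ... Unused.
#' @return A tibble `parameter`, `dimensions`, `n_values`, `l2_norm`.
#' @method tidy acmix_swin
#' @export
tidy.acmix_swin <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    dimensions = vapply(x$params, function(p) {
      paste(dim(p) %||% length(p), collapse = "x")
    }, character(1)),
    n_values = vapply(x$params, length, integer(1)),
    l2_norm = vapply(x$params, function(p) sqrt(sum(p^2)), numeric(1))
  )
}

#' @method tidy classifier_fit
#' @export
tidy.classifier_fit <- function(x, ...) tidy(x$model, ...)

#' Glance at a fitted classifier
#'
#' @param x A `classifier_fit` from [train_classifier()].
#' @param ... Unused.
#' @return A one-row tibble: parameter count, fusion weights, best epoch,
#'   best validation loss, early-stopping flag.
#' @method glance classifier_fit
#' @export
glance.classifier_fit <- function(x, ...) {
  fw <- fusion_weights(x$model)
  tibble::tibble(
    n_parameters = sum(vapply(x$model$params, length, integer(1))),
    alpha = fw["alpha"],
    beta = fw["beta"],
    best_epoch = x$best_epoch,
    best_val_loss = min(x$history$val_loss),
    epochs_run = nrow(x$history),
    stopped_early = x$stopped_early
  )
}

#' @method glance acmix_swin
#' @export
glance.acmix_swin <- function(x, ...) {
  fw <- fusion_weights(x)
  cfg <- x$config
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, integer(1))),
    n_genes = cfg$n_genes, n_classes = cfg$n_classes,
    embed_dim = cfg$embed_dim, n_tokens = cfg$n_tokens,
    n_heads = cfg$n_heads, window_size = cfg$window_size,
    alpha = fw["alpha"], beta = fw["beta"]
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$metrics

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$metrics),
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = x$sd_accuracy,
    mean_macro_f1 = mean(x$metrics$macro_f1)
  )
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report` from [evaluate_classifier()].
#' @param ... Unused.
#' @return Per-class precision/recall/F1 tibble.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, macro_precision = x$macro_precision,
    macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
    n = sum(x$confusion)
  )
}

#' Tidy a hub selection
#'
#' @param x A `hub_selection` from [select_hubs()].
#' @param ... Unused.
#' @return A tibble `list` (overall or class name), `rank`, `gene_id`,
#'   `score`.
#' @method tidy hub_selection
#' @export
tidy.hub_selection <- function(x, ...) {
  rows <- list(dplyr::mutate(x$overall, list = "overall", .before = 1))
  for (cl in names(x$per_class)) {
    rows[[length(rows) + 1]] <- dplyr::mutate(x$per_class[[cl]], list = cl, .before = 1)
  }
  dplyr::bind_rows(rows)
}
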