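#' Gradient x Input gene importance
#'
#' For each sample, the gradient of the per-sample classification loss with
#' respect to the raw input gene vector is multiplied elementwise by the
#' input; the overall importance of a gene is the mean absolute product
#' across samples. The model is evaluated with dropout off, so the gradients
#' are deterministic.
#'
#' @param model An `acmix_swin` model.
#' @param expr Genes x samples expression matrix.
#' @param labels True class labels (used for the loss).
#' @param smoothing Label smoothing used in the loss (default 0, plain
#'   cross-entropy).
#' @return A tibble `gene_id`, `importance` (>= 0), sorted by the matrix's
#'   gene order.
#' @export
gradient_x_input <- function(model, expr, labels, smoothing = 0) {
  x <- t(expr)
  classes <- model$classes %||% sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes)
  if (anyNA(y)) stop("labels contain classes unknown to the model", call. = FALSE)
  g <- model_graph(model, x, training = FALSE)
  targets <- smooth_targets(y, model$config$n_classes, smoothing)
  # sum over samples: the input-gradient rows are then exactly the
  # per-sample loss gradients (samples are independent in eval mode)
  loss <- ad_softmax_xent(g$logits, targets, reduce = "sum")
  ad_backward(loss)
  products <- g$input$grad * x
  tibble::tibble(
    gene_id = rownames(expr),
    importance = unname(colMeans(abs(products)))
  )
}

#' Class-directed gene importance
#'
#' Like [gradient_x_input()] but the gradient is taken of the target-class
#' logit (not the loss), and the mean absolute gradient-times-input product
#' is computed over the samples of that class only.
#'
#' @param model An `acmix_swin` model.
#' @param expr Genes x samples expression matrix.
#' @param labels Class labels per sample.
#' @param target_class The class whose logit drives the gradient.
#' @return A tibble `gene_id`, `importance`.
#' @export
class_importance <- function(model, expr, labels, target_class) {
  classes <- model$classes %||% sort(unique(as.character(labels)))
  ci <- match(target_class, classes)
  if (is.na(ci)) stop(sprintf("unknown class '%s'", target_class), call. = FALSE)
  keep <- as.character(labels) == target_class
  if (!any(keep)) stop(sprintf("no samples of class '%s'", target_class), call. = FALSE)
  x <- t(expr[, keep, drop = FALSE])
  g <- model_graph(model, x, training = FALSE)
  loss <- ad_logit_sum(g$logits, ci)
  ad_backward(loss)
  products <- g$input$grad * x
  tibble::tibble(
    gene_id = rownames(expr),
    importance = unname(colMeans(abs(products)))
  )
}

#' Full importance table (overall and per class)
#'
#' @param model An `acmix_swin` model.
#' @param expr Genes x samples expression matrix.
#' @param labels Class labels per sample.
#' @param smoothing Label smoothing for the overall loss gradient.
#' @return A tibble with `gene_id`, `overall` and one column per class.
#' @export
importance_table <- function(model, expr, labels, smoothing = 0) {
  out <- gradient_x_input(model, expr, labels, smoothing)
  names(out)[2] <- "overall"
  for (cl in model$classes %||% sort(unique(as.character(labels)))) {
    out[[cl]] <- class_importance(model, expr, labels, cl)$importance
  }
  out
}

#' Combine deep-learning and network scores
#'
#' `weighted_sum` mode implements
#' `combined = w_dl * DL_score + (1 - w_dl) * WGCNA_score` with both score
#' families min-max rescaled to \[0, 1\] (DL from the importance values;
#' WGCNA from `GS * |MM|`). `product` mode computes
#' `DL_score * GS * |MM|`. Genes missing from the network table get a
#' network score of 0 with a warning.
#'
#' @param dl Importance tibble (`gene_id`, importance in the second column).
#' @param net Network-score tibble (`gene_id`, `GS`, `MM`).
#' @param w_dl Weight on the deep-learning score in `[0, 1]` (default 1.0).
#' @param mode `"weighted_sum"` (default) or `"product"`.
#' @return A tibble `gene_id`, `dl_score`, `wgcna_score`, `combined`, sorted
#'   by combined score (ties broken by gene id).
#' @export
combine_scores <- function(dl, net = NULL, w_dl = 1.0,
                           mode = c("weighted_sum", "product")) {
  mode <- match.arg(mode)
  if (w_dl < 0 || w_dl > 1) stop("w_dl must lie in [0, 1]", call. = FALSE)
  imp <- dl[[2]]
  dl_score <- minmax_rescale(imp)
  gs <- mm <- rep(0, nrow(dl))
  if (!is.null(net)) {
    idx <- match(dl$gene_id, net$gene_id)
    if (anyNA(idx)) {
      warning(sprintf(
        "%d gene(s) missing network scores; their WGCNA score is 0",
        sum(is.na(idx))
      ), call. = FALSE)
    }
    gs <- ifelse(is.na(idx), 0, net$GS[idx])
    mm <- ifelse(is.na(idx), 0, net$MM[idx])
  }
  wg_raw <- gs * abs(mm)
  out <- tibble::tibble(
    gene_id = dl$gene_id,
    dl_score = dl_score,
    wgcna_score = minmax_rescale(wg_raw),
    combined = if (mode == "weighted_sum") {
      w_dl * dl_score + (1 - w_dl) * minmax_rescale(wg_raw)
    } else {
      dl_score * gs * abs(mm)
    }
  )
  dplyr::arrange(out, dplyr::desc(.data$combined), .data$gene_id)
}

#' Select hub genes
#'
#' Picks the top `n_overall` genes by combined score plus the top
#' `n_per_class` genes per class; ties break lexicographically by gene id.
#' Shorter-than-requested score tables are returned whole with a warning.
#'
#' @param combined Combined-score tibble from [combine_scores()] (columns
#'   `gene_id`, `combined`).
#' @param per_class Named list of per-class score tibbles (`gene_id` +
#'   a score column named either `combined` or `importance`).
#' @param n_overall Overall hub count (default 20).
#' @param n_per_class Per-class hub count (default 10).
#' @return A `hub_selection` list: `overall` (tibble `rank`, `gene_id`,
#'   `score`), `per_class` (named list of such tibbles), and the sizes.
#' @export
select_hubs <- function(combined, per_class = list(), n_overall = 20,
                        n_per_class = 10) {
  if (nrow(combined) == 0) stop("empty score table", call. = FALSE)
  take_top <- function(tab, score_col, n) {
    if (nrow(tab) < n) {
      warning(sprintf("only %d genes available for a top-%d list", nrow(tab), n),
        call. = FALSE
      )
      n <- nrow(tab)
    }
    ord <- order(-tab[[score_col]], tab$gene_id)
    sel <- tab[ord[seq_len(n)], ]
    tibble::tibble(rank = seq_len(n), gene_id = sel$gene_id, score = sel[[score_col]])
  }
  score_col <- if ("combined" %in% names(combined)) "combined" else names(combined)[2]
  overall <- take_top(combined, score_col, n_overall)
  per_cl <- lapply(per_class, function(tab) {
    sc <- if ("combined" %in% names(tab)) "combined" else names(tab)[2]
    take_top(tab, sc, n_per_class)
  })
  structure(
    list(
      overall = overall, per_class = per_cl,
      n_overall = nrow(overall),
      n_per_class = vapply(per_cl, nrow, integer(1))
    ),
    class = "hub_selection"
  )
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("<hub_selection> %d overall hubs", x$n_overall))
  if (length(x$per_class)) {
    cat(
      "; per class:",
      paste(sprintf("%s (%d)", names(x$per_class), x$n_per_class), collapse = ", ")
    )
  }
  cat("\n  top overall:", paste(utils::head(x$overall$gene_id, 10), collapse = ", "), "\n")
  invisible(x)
}

#' Export the hub co-expression network
#'
#' Builds an edge list over the selected hub genes: an edge joins two hubs
#' whose absolute Pearson expression correlation reaches `cor_threshold`,
#' weighted by that absolute correlation. Node categories record whether a
#' hub is overall and/or class-specific.
#'
#' @param hubs A `hub_selection`.
#' @param expr Genes x samples expression matrix containing the hub genes.
#' @param cor_threshold Minimum absolute correlation (default 0.7).
#' @return A list: `nodes` (tibble `gene_id`, `category`) and `edges`
#'   (tibble `from`, `to`, `weight`).
#' @export
export_hub_network <- function(hubs, expr, cor_threshold = 0.7) {
  cats <- list()
  for (g in hubs$overall$gene_id) cats[[g]] <- c(cats[[g]], "overall")
  for (cl in names(hubs$per_class)) {
    for (g in hubs$per_class[[cl]]$gene_id) cats[[g]] <- c(cats[[g]], cl)
  }
  genes <- names(cats)
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g) > 0) {
    stop(sprintf("hub gene absent from matrix: %s", missing_g[1]), call. = FALSE)
  }
  nodes <- tibble::tibble(
    gene_id = genes,
    category = vapply(cats, function(x) paste(unique(x), collapse = "|"), character(1))
  )
  cm <- abs(stats::cor(t(expr[genes, , drop = FALSE])))
  idx <- which(upper.tri(cm) & cm >= cor_threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = genes[idx[, 1]],
    to = genes[idx[, 2]],
    weight = cm[idx]
  )
  list(nodes = nodes, edges = edges)
}
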