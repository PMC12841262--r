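#' Pipeline configuration
#'
#' Bundles paths and all stage configurations with one global seed that fans
#' out into named per-stage seed streams (augmentation, splits, model
#' initialization, training shuffles), so a run is reproducible end to end.
#'
#' @param expr_path,meta_path Input expression matrix / metadata paths
#'   (`NULL` when matrices are passed to [run_pipeline()] directly).
#' @param network_scores_path Optional external network-score table.
#' @param out_dir Output directory (created; a timestamped subdirectory is
#'   used unless `timestamp = FALSE`).
#' @param aug An [augmentation_config()].
#' @param wgan A [wgan_config()].
#' @param model_overrides Named list of [model_config()] overrides (the gene
#'   and class counts come from the data).
#' @param train A [train_config()].
#' @param w_dl,combine_mode,n_overall,n_per_class Hub-scoring parameters.
#' @param cor_threshold Hub-network edge threshold.
#' @param delimiter Field separator for all inputs/outputs.
#' @param timestamp Use a timestamped run subdirectory (default TRUE).
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expr_path = NULL, meta_path = NULL,
                            network_scores_path = NULL, out_dir = "castehub_run",
                            aug = augmentation_config(), wgan = wgan_config(),
                            model_overrides = list(), train = train_config(),
                            w_dl = 1.0, combine_mode = "weighted_sum",
                            n_overall = 20, n_per_class = 10,
                            cor_threshold = 0.7, delimiter = "\t",
                            timestamp = TRUE, seed = 1) {
  structure(
    list(
      expr_path = expr_path, meta_path = meta_path,
      network_scores_path = network_scores_path, out_dir = out_dir,
      aug = aug, wgan = wgan, model_overrides = model_overrides,
      train = train, w_dl = w_dl, combine_mode = combine_mode,
      n_overall = n_overall, n_per_class = n_per_class,
      cor_threshold = cor_threshold, delimiter = delimiter,
      timestamp = timestamp, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Checks every type invariant (fractions sum to one, divisibility of the
#' embedding dimension by the head count, bounds on dropout and smoothing,
#' ...). Violations are returned as data, not thrown.
#'
#' @param cfg A [pipeline_config()].
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  a <- cfg$aug
  fr <- c(a$frac_wgan, a$frac_smote, a$frac_noise, a$frac_mixup)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    v <- c(v, sprintf(
      "augmentation fractions (wgan %.3g, smote %.3g, noise %.3g, mixup %.3g) must be nonnegative and sum to 1 (sum %.3g)",
      fr[1], fr[2], fr[3], fr[4], sum(fr)
    ))
  }
  if (a$target_min_per_class > a$target_max_per_class) {
    v <- c(v, "target_min_per_class exceeds target_max_per_class")
  }
  if (length(a$noise_scale_range) != 2 || a$noise_scale_range[1] < 0 ||
    a$noise_scale_range[1] > a$noise_scale_range[2]) {
    v <- c(v, "noise_scale_range must be 0 <= low <= high")
  }
  w <- cfg$wgan
  if (w$lambda_gp < 0) v <- c(v, "lambda_gp must be >= 0")
  if (w$n_critic < 1) v <- c(v, "n_critic must be >= 1")
  if (w$epochs < 1) v <- c(v, "wgan epochs must be >= 1")
  mo <- cfg$model_overrides
  embed_dim <- mo$embed_dim %||% 64
  n_heads <- mo$n_heads %||% 8
  n_tokens <- mo$n_tokens %||% 7
  window_size <- mo$window_size %||% 7
  if (embed_dim %% n_heads != 0) {
    v <- c(v, sprintf("embed_dim (%d) must be divisible by n_heads (%d)", embed_dim, n_heads))
  }
  if (window_size > n_tokens || n_tokens %% window_size != 0) {
    v <- c(v, sprintf("window_size (%d) must divide n_tokens (%d)", window_size, n_tokens))
  }
  t <- cfg$train
  if (t$label_smoothing < 0 || t$label_smoothing >= 1) {
    v <- c(v, "label_smoothing must lie in [0, 1)")
  }
  if (t$patience > t$max_epochs) v <- c(v, "patience must be <= max_epochs")
  if (cfg$w_dl < 0 || cfg$w_dl > 1) v <- c(v, "w_dl must lie in [0, 1]")
  if (!cfg$combine_mode %in% c("weighted_sum", "product")) {
    v <- c(v, "combine_mode must be 'weighted_sum' or 'product'")
  }
  v
}

#' Run the full pipeline
#'
#' Executes augment -> train -> evaluate -> attribute -> hub selection on an
#' expression matrix with sample metadata. Every artifact (resolved
#' configuration, augmented data, GAN diagnostics, training history,
#' metrics, importance tables, hub lists, hub network, log) is written as
#' delimited text under the run directory. Rerunning with the same
#' configuration and seed reproduces all numeric outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param expr Optional genes x samples matrix (otherwise read from
#'   `cfg$expr_path`).
#' @param meta Optional metadata tibble (otherwise read from `cfg$meta_path`).
#' @param net Optional network-score tibble (otherwise read from
#'   `cfg$network_scores_path` when set).
#' @param zscore Z-score the matrix first (default TRUE).
#' @return A `pipeline_result` list (invisible components also on disk):
#'   `run_dir`, `metrics`, `fit`, `hubs`, `combined`, `importance`,
#'   `augmented`, `split`.
#' @export
run_pipeline <- function(cfg, expr = NULL, meta = NULL, net = NULL,
                         zscore = TRUE) {
  violations <- validate_config(cfg)
  if (length(violations) > 0) {
    stop(paste(c("invalid configuration:", violations), collapse = "\n  "), call. = FALSE)
  }
  if (is.null(expr)) expr <- read_expression_matrix(cfg$expr_path, cfg$delimiter)
  if (is.null(meta)) meta <- read_sample_metadata(cfg$meta_path, cfg$delimiter, expr)
  if (is.null(net) && !is.null(cfg$network_scores_path)) {
    net <- read_network_scores(cfg$network_scores_path, cfg$delimiter, expr)
  }
  validate_sample_metadata(meta, expr)

  run_dir <- cfg$out_dir
  if (isTRUE(cfg$timestamp)) {
    run_dir <- file.path(cfg$out_dir, format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "log.txt")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
      file = log_path, append = TRUE
    )
  }

  # resolved config serialized before any computation
  yaml::write_yaml(unclass_config(cfg), file.path(run_dir, "config.yaml"))
  logline("config written; global seed %d", cfg$seed)

  if (zscore) expr <- zscore_normalize(expr)
  classes <- unique(meta$class_label)

  split <- train_val_test_split(meta, seed = derive_seed(cfg$seed, "pipeline_split"))
  logline(
    "split: %d train / %d val / %d test",
    length(split$train), length(split$val), length(split$test)
  )

  aug_cfg <- cfg$aug
  aug_cfg$seed <- derive_seed(cfg$seed, "pipeline_aug")
  tr_meta <- meta[meta$sample_id %in% split$train, ]
  aug <- compose_augmented_dataset(
    expr[, tr_meta$sample_id, drop = FALSE], tr_meta, aug_cfg, cfg$wgan
  )
  write_expression_matrix(aug$expr, file.path(run_dir, "augmented_matrix.tsv"), cfg$delimiter)
  readr::write_tsv(aug$labels, file.path(run_dir, "augmented_labels.tsv"))
  if (!is.null(aug$diagnostics)) {
    readr::write_tsv(aug$diagnostics, file.path(run_dir, "gan_diagnostics.tsv"))
  }
  logline("augmented: %s", paste(sprintf("%s=%d", names(aug$targets), aug$targets), collapse = " "))

  mcfg_args <- utils::modifyList(
    list(n_genes = nrow(expr), n_classes = length(classes)),
    cfg$model_overrides
  )
  mcfg <- do.call(model_config, mcfg_args)
  tcfg <- cfg$train
  tcfg$seed <- derive_seed(cfg$seed, "pipeline_train")
  fit <- train_classifier(aug,
    mcfg = mcfg, tcfg = tcfg,
    val_expr = expr[, split$val, drop = FALSE],
    val_labels = meta$class_label[match(split$val, meta$sample_id)],
    classes = classes
  )
  readr::write_tsv(fit$history, file.path(run_dir, "train_history.tsv"))
  save_model(fit$model, file.path(run_dir, "model.rds"))
  fw <- fusion_weights(fit$model)
  logline(
    "trained: best epoch %d%s; fusion alpha=%.3f beta=%.3f",
    fit$best_epoch, if (fit$stopped_early) " (early stop)" else "", fw[1], fw[2]
  )

  metrics <- evaluate_classifier(
    fit$model, expr[, split$test, drop = FALSE],
    meta$class_label[match(split$test, meta$sample_id)]
  )
  readr::write_tsv(
    tibble::tibble(
      metric = c("accuracy", "macro_precision", "macro_recall", "macro_f1"),
      value = c(
        metrics$accuracy, metrics$macro_precision,
        metrics$macro_recall, metrics$macro_f1
      )
    ),
    file.path(run_dir, "metrics.tsv")
  )
  utils::write.csv(metrics$confusion, file.path(run_dir, "confusion.csv"))
  logline("test accuracy %.3f", metrics$accuracy)

  # attribution on all real samples
  imp <- importance_table(
    fit$model, expr, meta$class_label[match(colnames(expr), meta$sample_id)]
  )
  readr::write_tsv(imp, file.path(run_dir, "importance.tsv"))

  dl_overall <- imp[, c("gene_id", "overall")]
  combined <- combine_scores(dl_overall, net, w_dl = cfg$w_dl, mode = cfg$combine_mode)
  readr::write_tsv(combined, file.path(run_dir, "combined_scores.tsv"))

  per_class_scores <- lapply(classes, function(cl) {
    combine_scores(imp[, c("gene_id", cl)], net, w_dl = cfg$w_dl, mode = cfg$combine_mode)
  })
  names(per_class_scores) <- classes

  hubs <- select_hubs(combined, per_class_scores,
    n_overall = cfg$n_overall, n_per_class = cfg$n_per_class
  )
  readr::write_tsv(hubs$overall, file.path(run_dir, "hubs_overall.tsv"))
  for (cl in names(hubs$per_class)) {
    readr::write_tsv(
      hubs$per_class[[cl]],
      file.path(run_dir, sprintf("hubs_%s.tsv", cl))
    )
  }
  net_export <- export_hub_network(hubs, expr, cfg$cor_threshold)
  readr::write_tsv(net_export$nodes, file.path(run_dir, "hub_network_nodes.tsv"))
  readr::write_tsv(net_export$edges, file.path(run_dir, "hub_network_edges.tsv"))
  logline("hubs: %d overall, %s per class", hubs$n_overall, paste(hubs$n_per_class, collapse = "/"))

  structure(
    list(
      run_dir = run_dir, metrics = metrics, fit = fit, hubs = hubs,
      combined = combined, importance = imp, augmented = aug, split = split,
      network = net_export
    ),
    class = "pipeline_result"
  )
}

unclass_config <- function(cfg) {
  lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %s | test accuracy %.3f | %d overall hubs\n",
    x$run_dir, x$metrics$accuracy, x$hubs$n_overall
  ))
  invisible(x)
}
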