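#' Stratified k-fold assignments
#'
#' Assigns each real sample to one of `k` folds, stratified by class. If any
#' class has fewer than `k` samples, `k` is reduced to the smallest class
#' size (the smallest scheme keeping at least one test sample per class per
#' fold) with a warning.
#'
#' @param meta Sample metadata tibble.
#' @param k Requested fold count.
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `class_label`, `fold`; attribute `k` holds
#'   the fold count actually used.
#' @export
stratified_folds <- function(meta, k = 5, seed = 1) {
  min_class <- min(table(meta$class_label))
  if (min_class < 2) stop("every class needs at least 2 samples", call. = FALSE)
  if (min_class < k) {
    warning(sprintf(
      "smallest class has %d samples < k = %d; using k = %d (leave-one-per-class folds)",
      min_class, k, min_class
    ), call. = FALSE)
    k <- min_class
  }
  folds <- integer(nrow(meta))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in unique(meta$class_label)) {
      idx <- which(meta$class_label == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  out <- tibble::tibble(
    sample_id = meta$sample_id,
    class_label = meta$class_label, fold = folds
  )
  attr(out, "k") <- k
  out
}

# Carve a stratified validation subset (>= 1 per class) out of sample ids.
carve_validation <- function(meta, ids, frac = 0.15, seed = 1) {
  sub <- meta[meta$sample_id %in% ids, ]
  val_ids <- character(0)
  with_seed(derive_seed(seed, "val_split"), {
    for (cl in unique(sub$class_label)) {
      cl_ids <- sub$sample_id[sub$class_label == cl]
      n_val <- max(1, round(frac * length(cl_ids)))
      n_val <- min(n_val, length(cl_ids) - 2) # keep >= 2 for augmentation
      if (n_val < 1) n_val <- 1
      val_ids <- c(val_ids, sample(cl_ids, n_val))
    }
  })
  list(train = setdiff(ids, val_ids), val = val_ids)
}

#' Cross-validated evaluation with leakage control
#'
#' Stratified k-fold cross-validation in which all augmentation (including
#' WGAN-GP training) is fitted on each training fold only; held-out folds
#' contain exclusively real samples, so no synthetic sample can leak across
#' the fold boundary. A validation subset for early stopping is carved from
#' each training fold before augmentation.
#'
#' @param expr Genes x samples expression matrix (z-scored recommended).
#' @param meta Sample metadata tibble.
#' @param k Folds (default 5).
#' @param mcfg A [model_config()] (`NULL` for defaults).
#' @param tcfg A [train_config()].
#' @param aug_cfg An [augmentation_config()]; `NULL` disables augmentation.
#' @param wgan_cfg A [wgan_config()].
#' @param seed Integer seed (controls folds and all per-fold stages).
#' @return A `cv_result` list: `folds` (assignment tibble), `metrics`
#'   (per-fold tibble), `mean_accuracy`, `sd_accuracy`, `reports` (per-fold
#'   `metrics_report`s), `leakage_audit`.
#' @export
cross_validate <- function(expr, meta, k = 5, mcfg = NULL,
                           tcfg = train_config(), aug_cfg = augmentation_config(),
                           wgan_cfg = wgan_config(), seed = 1) {
  validate_sample_metadata(meta, expr)
  folds <- stratified_folds(meta, k, seed)
  k <- attr(folds, "k")
  classes <- unique(meta$class_label)

  reports <- vector("list", k)
  audit <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- folds$sample_id[folds$fold == f]
    rest_ids <- folds$sample_id[folds$fold != f]
    sp <- carve_validation(meta, rest_ids, 0.15, seed = derive_seed(seed, paste0("fold", f)))
    fit <- fit_fold(
      expr, meta, sp$train, sp$val, classes, mcfg, tcfg,
      aug_cfg, wgan_cfg, seed = derive_seed(seed, paste0("fit", f))
    )
    reports[[f]] <- evaluate_classifier(
      fit$model, expr[, test_ids, drop = FALSE],
      meta$class_label[match(test_ids, meta$sample_id)]
    )
    audit[[f]] <- tibble::tibble(
      fold = f,
      n_train_real = length(sp$train),
      n_val_real = length(sp$val),
      n_test_real = length(test_ids),
      n_synthetic_in_test = 0L, # test folds are drawn from real samples only
      synthetic_sources_in_train_only = fit$synthetic_from_train_only
    )
  }

  metrics <- dplyr::bind_rows(lapply(seq_len(k), function(f) {
    r <- reports[[f]]
    tibble::tibble(
      fold = f, accuracy = r$accuracy, macro_precision = r$macro_precision,
      macro_recall = r$macro_recall, macro_f1 = r$macro_f1
    )
  }))
  structure(
    list(
      folds = folds, metrics = metrics,
      mean_accuracy = mean(metrics$accuracy),
      sd_accuracy = stats::sd(metrics$accuracy),
      reports = reports,
      leakage_audit = dplyr::bind_rows(audit)
    ),
    class = "cv_result"
  )
}

# Augment (optionally) and train on given real sample ids.
fit_fold <- function(expr, meta, train_ids, val_ids, classes, mcfg, tcfg,
                     aug_cfg, wgan_cfg, seed) {
  tr_meta <- meta[meta$sample_id %in% train_ids, ]
  tr_expr <- expr[, tr_meta$sample_id, drop = FALSE]
  tcfg$seed <- seed
  synthetic_from_train_only <- TRUE
  if (!is.null(aug_cfg)) {
    aug_cfg$seed <- derive_seed(seed, "fold_aug")
    aug <- compose_augmented_dataset(tr_expr, tr_meta, aug_cfg, wgan_cfg)
    train_data <- aug
    # audit: every synthetic sample is named after its seeding class and was
    # generated from the training reals above
    synthetic_from_train_only <- all(
      aug$labels$sample_id[aug$labels$provenance == "real"] %in% train_ids
    )
  } else {
    train_data <- list(
      x = t(tr_expr), y = match(tr_meta$class_label, classes),
      classes = classes, provenance = rep("real", nrow(tr_meta))
    )
  }
  mcfg_f <- mcfg %||% model_config(n_genes = nrow(expr), n_classes = length(classes))
  fit <- train_classifier(
    train_data,
    mcfg = mcfg_f, tcfg = tcfg,
    val_expr = expr[, val_ids, drop = FALSE],
    val_labels = meta$class_label[match(val_ids, meta$sample_id)],
    classes = classes
  )
  list(model = fit$model, fit = fit, synthetic_from_train_only = synthetic_from_train_only)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds | accuracy %.3f +/- %.3f\n",
    nrow(x$metrics), x$mean_accuracy, x$sd_accuracy %||% NA
  ))
  print(as.data.frame(x$metrics))
  invisible(x)
}

#' Benchmark against classical and deep baselines
#'
#' Runs the hybrid classifier and eight baselines — KNN, RBF-kernel SVM,
#' multinomial logistic regression, random forest, MLP (one hidden layer of
#' 128), a two-layer 1D-CNN, an LSTM (hidden 64) and a two-layer four-head
#' Transformer encoder — on identical stratified folds with the identical
#' augmentation policy (fitted per training fold). Accuracy is measured on
#' the real held-out samples only.
#'
#' @param expr Genes x samples expression matrix.
#' @param meta Sample metadata tibble.
#' @param k Folds (default 5).
#' @param tcfg A [train_config()] for the hybrid model.
#' @param aug_cfg An [augmentation_config()]; `NULL` disables augmentation.
#' @param wgan_cfg A [wgan_config()].
#' @param deep_epochs Training epochs for the deep baselines (default 100).
#' @param seed Integer seed (shared folds across all models).
#' @param models Subset of model names to run (default all nine).
#' @return A `benchmark_result` with a tibble `table` (`model`,
#'   `mean_accuracy`, `sd_accuracy`) sorted by accuracy, and `folds`.
#' @export
run_baselines <- function(expr, meta, k = 5, tcfg = train_config(),
                          aug_cfg = augmentation_config(),
                          wgan_cfg = wgan_config(), deep_epochs = 100,
                          seed = 1,
                          models = c(
                            "acmix_swin", "knn", "svm_rbf", "logistic",
                            "random_forest", "mlp", "cnn1d", "lstm",
                            "transformer"
                          )) {
  validate_sample_metadata(meta, expr)
  folds <- stratified_folds(meta, k, seed)
  k <- attr(folds, "k")
  classes <- unique(meta$class_label)
  n_genes <- nrow(expr)
  C <- length(classes)

  acc <- matrix(NA_real_, length(models), k, dimnames = list(models, NULL))
  for (f in seq_len(k)) {
    test_ids <- folds$sample_id[folds$fold == f]
    rest_ids <- folds$sample_id[folds$fold != f]
    sp <- carve_validation(meta, rest_ids, 0.15, seed = derive_seed(seed, paste0("bfold", f)))
    tr_meta <- meta[meta$sample_id %in% sp$train, ]

    # identical augmentation for every model in this fold
    if (!is.null(aug_cfg)) {
      aug_cfg_f <- aug_cfg
      aug_cfg_f$seed <- derive_seed(seed, paste0("baug", f))
      aug <- compose_augmented_dataset(
        expr[, tr_meta$sample_id, drop = FALSE], tr_meta, aug_cfg_f, wgan_cfg
      )
      xtr <- t(aug$expr)
      ytr <- match(aug$labels$class_label, classes)
    } else {
      xtr <- t(expr[, tr_meta$sample_id, drop = FALSE])
      ytr <- match(tr_meta$class_label, classes)
    }
    xte <- t(expr[, test_ids, drop = FALSE])
    yte_lab <- meta$class_label[match(test_ids, meta$sample_id)]
    yte <- factor(yte_lab, levels = classes)
    ytr_f <- factor(classes[ytr], levels = classes)

    for (m in models) {
      pred <- switch(m,
        acmix_swin = {
          fit <- fit_fold(
            expr, meta, sp$train, sp$val, classes, NULL, tcfg,
            aug_cfg, wgan_cfg, seed = derive_seed(seed, paste0("bfit", f))
          )
          predict(fit$model, xte)
        },
        knn = class::knn(xtr, xte, ytr_f, k = 5),
        svm_rbf = predict(e1071::svm(xtr, ytr_f, kernel = "radial", cost = 1), xte),
        logistic = {
          df <- data.frame(y = ytr_f, xtr, check.names = FALSE)
          fit <- nnet::multinom(y ~ ., df,
            MaxNWts = 1e6, maxit = 200, trace = FALSE
          )
          predict(fit, data.frame(xte, check.names = FALSE))
        },
        random_forest = {
          fit <- randomForest::randomForest(xtr, ytr_f, ntree = 500)
          predict(fit, xte)
        },
        mlp = deep_fold(mlp_baseline, n_genes, C, xtr, ytr, xte, classes, deep_epochs, seed, f),
        cnn1d = deep_fold(cnn1d_baseline, n_genes, C, xtr, ytr, xte, classes, deep_epochs, seed, f),
        lstm = deep_fold(lstm_baseline, n_genes, C, xtr, ytr, xte, classes, deep_epochs, seed, f),
        transformer = deep_fold(transformer_baseline, n_genes, C, xtr, ytr, xte, classes, deep_epochs, seed, f),
        stop(sprintf("unknown model '%s'", m), call. = FALSE)
      )
      acc[m, f] <- mean(as.character(pred) == as.character(yte))
    }
  }

  table <- tibble::tibble(
    model = rownames(acc),
    mean_accuracy = rowMeans(acc),
    sd_accuracy = apply(acc, 1, stats::sd)
  )
  table <- dplyr::arrange(table, dplyr::desc(.data$mean_accuracy))
  structure(
    list(table = table, per_fold = acc, folds = folds),
    class = "benchmark_result"
  )
}

deep_fold <- function(ctor, n_genes, C, xtr, ytr, xte, classes, epochs, seed, fold) {
  spec <- ctor(n_genes, C, seed = derive_seed(seed, paste0("deep", fold)))
  params <- train_deep_generic(
    spec$params, spec$builder, xtr, ytr, C,
    epochs = epochs, seed = derive_seed(seed, paste0("deeptr", fold))
  )
  predict_deep_generic(params, spec$builder, xte, classes)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(as.data.frame(x$table))
  invisible(x)
}

#' Ablation suite
#'
#' Trains and evaluates architectural variants of the hybrid model under one
#' identical stratified split and augmentation: the full model; the
#' convolution branch removed (`beta` pinned to 0); the attention branch
#' removed (`alpha` pinned to 0); an alternative window size; an alternative
#' embedding dimension; an alternative head count; and a
#' regularization-strength variant (block dropout and weight decay scaled).
#'
#' @param expr Genes x samples expression matrix.
#' @param meta Sample metadata tibble.
#' @param mcfg Base [model_config()] (`NULL` for defaults).
#' @param tcfg A [train_config()].
#' @param aug_cfg An [augmentation_config()]; `NULL` disables augmentation.
#' @param wgan_cfg A [wgan_config()].
#' @param seed Integer seed.
#' @return An `ablation_result` with tibble `table` (`variant`, `accuracy`,
#'   `macro_f1`) and the per-variant `reports`.
#' @export
run_ablations <- function(expr, meta, mcfg = NULL, tcfg = train_config(),
                          aug_cfg = augmentation_config(),
                          wgan_cfg = wgan_config(), seed = 1) {
  validate_sample_metadata(meta, expr)
  classes <- unique(meta$class_label)
  base <- mcfg %||% model_config(n_genes = nrow(expr), n_classes = length(classes))

  # 70/15/15 stratified split of the real samples
  split <- train_val_test_split(meta, seed = seed)

  variants <- list(
    full = list(),
    no_convolution = list(beta_init = 0, beta_trainable = FALSE),
    no_attention = list(alpha_init = 0, alpha_trainable = FALSE),
    window_size_1 = list(window_size = 1),
    embed_dim_32 = list(embed_dim = 32),
    heads_4 = list(n_heads = 4),
    regularization_light = list(dropout_block = 0.2)
  )

  reports <- list()
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    vn <- names(variants)[i]
    vcfg <- base
    for (nm in names(variants[[i]])) vcfg[[nm]] <- variants[[i]][[nm]]
    vcfg <- do.call(model_config, vcfg[setdiff(names(vcfg), NULL)])
    tcfg_v <- tcfg
    if (vn == "regularization_light") tcfg_v$weight_decay <- tcfg$weight_decay * 10
    fit <- fit_fold(
      expr, meta, split$train, split$val, classes, vcfg, tcfg_v,
      aug_cfg, wgan_cfg, seed = derive_seed(seed, "ablation_fit")
    )
    rep <- evaluate_classifier(
      fit$model, expr[, split$test, drop = FALSE],
      meta$class_label[match(split$test, meta$sample_id)]
    )
    reports[[vn]] <- rep
    rows[[i]] <- tibble::tibble(
      variant = vn, accuracy = rep$accuracy, macro_f1 = rep$macro_f1
    )
  }
  structure(
    list(table = dplyr::bind_rows(rows), reports = reports, split = split),
    class = "ablation_result"
  )
}

#' Stratified train/validation/test split
#'
#' 70/15/15 stratified split of real samples, guaranteeing at least one
#' validation and one test sample per class and at least two training
#' samples per class.
#'
#' @param meta Sample metadata tibble.
#' @param fracs Length-3 proportions (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed.
#' @return A list of sample-id vectors: `train`, `val`, `test`.
#' @export
train_val_test_split <- function(meta, fracs = c(0.70, 0.15, 0.15), seed = 1) {
  stopifnot(length(fracs) == 3, abs(sum(fracs) - 1) < 1e-9)
  train <- val <- test <- character(0)
  with_seed(derive_seed(seed, "tvt_split"), {
    for (cl in unique(meta$class_label)) {
      ids <- sample(meta$sample_id[meta$class_label == cl])
      n <- length(ids)
      n_test <- max(1, round(fracs[3] * n))
      n_val <- max(1, round(fracs[2] * n))
      if (n - n_test - n_val < 2) {
        stop(sprintf("class '%s' too small for a %d/%d/%d split", cl, round(100 * fracs[1]), round(100 * fracs[2]), round(100 * fracs[3])), call. = FALSE)
      }
      test <- c(test, ids[seq_len(n_test)])
      val <- c(val, ids[n_test + seq_len(n_val)])
      train <- c(train, ids[(n_test + n_val + 1):n])
    }
  })
  list(train = train, val = val, test = test)
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>\n")
  print(as.data.frame(x$table))
  invisible(x)
}
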