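#' Training configuration
#'
#' The classifier's optimization recipe: AdamW (decoupled weight decay),
#' linear warmup for the first `warmup_epochs` epochs followed by cosine
#' annealing, label-smoothed cross-entropy, per-batch cross-class Mixup,
#' global gradient-norm clipping, and early stopping on validation loss with
#' the best-validation parameters restored.
#'
#' @param learning_rate Peak learning rate (default 1e-4).
#' @param weight_decay AdamW weight decay (default 1e-3).
#' @param warmup_epochs Linear warmup length (default 10).
#' @param max_epochs Maximum epochs (default 300).
#' @param patience Early-stopping patience on validation loss (default 50).
#' @param label_smoothing Smoothing mass (default 0.05).
#' @param mixup_alpha Beta parameter of train-time cross-class Mixup
#'   (default 0.2; 0 disables).
#' @param grad_clip_norm Global gradient-norm cap (default 1.0).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-3,
                         warmup_epochs = 10, max_epochs = 300, patience = 50,
                         label_smoothing = 0.05, mixup_alpha = 0.2,
                         grad_clip_norm = 1.0, batch_size = 32, seed = 1) {
  cfg <- list(
    learning_rate = learning_rate, weight_decay = weight_decay,
    warmup_epochs = warmup_epochs, max_epochs = max_epochs,
    patience = patience, label_smoothing = label_smoothing,
    mixup_alpha = mixup_alpha, grad_clip_norm = grad_clip_norm,
    batch_size = batch_size, seed = seed
  )
  stopifnot(
    cfg$label_smoothing >= 0, cfg$label_smoothing < 1,
    cfg$patience <= cfg$max_epochs, cfg$max_epochs >= 1
  )
  structure(cfg, class = "train_config")
}

#' Learning-rate schedule: linear warmup then cosine annealing
#'
#' For epoch `e` (0-based) below `warmup_epochs` the rate is
#' `lr * (e + 1) / warmup_epochs`; afterwards it decays as
#' `lr * 0.5 * (1 + cos(pi * t / T))` with `t = e - warmup` and
#' `T = max_epochs - warmup`.
#'
#' @param epoch 0-based epoch index in `[0, max_epochs)`.
#' @param cfg A [train_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg) {
  stopifnot(epoch >= 0, epoch < cfg$max_epochs)
  lr <- cfg$learning_rate
  w <- cfg$warmup_epochs
  if (epoch < w) {
    return(lr * (epoch + 1) / w)
  }
  t <- epoch - w
  T_ <- max(cfg$max_epochs - w, 1)
  lr * 0.5 * (1 + cos(pi * t / T_))
}

#' Label-smoothed cross-entropy
#'
#' The target distribution places `1 - s` on the true class plus a uniform
#' `s / C` over all `C` classes (so the true class receives
#' `1 - s + s / C`); the loss is the mean negative log-likelihood of the
#' logits' softmax against that target.
#'
#' @param logits Matrix (samples x classes).
#' @param labels Integer class ids in `1..C`.
#' @param smoothing Smoothing mass `s` in `[0, 1)`.
#' @return Scalar loss.
#' @export
smoothed_cross_entropy <- function(logits, labels, smoothing = 0.05) {
  C <- ncol(logits)
  stopifnot(all(labels >= 1), all(labels <= C))
  targets <- smooth_targets(labels, C, smoothing)
  ad_value(ad_softmax_xent(ad_wrap(logits), targets))
}

smooth_targets <- function(labels, C, smoothing) {
  t <- matrix(smoothing / C, length(labels), C)
  t[cbind(seq_along(labels), labels)] <- 1 - smoothing + smoothing / C
  t
}

# Normalize the various dataset shapes into list(x = samples x genes, y =
# integer labels, classes = label set, provenance = chr).
as_training_set <- function(data, labels = NULL, classes = NULL) {
  if (inherits(data, "augmented_dataset")) {
    classes <- classes %||% unique(data$labels$class_label)
    return(list(
      x = t(data$expr),
      y = match(data$labels$class_label, classes),
      classes = classes,
      provenance = data$labels$provenance
    ))
  }
  if (is.list(data) && !is.null(data$x)) {
    return(data)
  }
  stopifnot(is.matrix(data), !is.null(labels))
  # genes x samples matrix + per-sample labels
  classes <- classes %||% unique(as.character(labels))
  list(
    x = t(data), y = match(as.character(labels), classes), classes = classes,
    provenance = rep("real", ncol(data))
  )
}

#' Train the classifier
#'
#' Optimizes an [acmix_swin()] model with the recipe in [train_config()]:
#' AdamW, warmup + cosine schedule, label smoothing, per-batch cross-class
#' Mixup of inputs and targets, global gradient clipping, early stopping on
#' validation loss (best parameters restored). Deterministic given the seed.
#'
#' @param train An `augmented_dataset`, or a genes x samples matrix (pass
#'   `train_labels`).
#' @param mcfg A [model_config()]; `NULL` derives defaults from the data.
#' @param tcfg A [train_config()].
#' @param val_expr Genes x samples validation matrix (real samples).
#' @param val_labels Class labels for the validation samples.
#' @param train_labels Labels when `train` is a bare matrix.
#' @param classes Optional class-label ordering.
#' @return A `classifier_fit` list: `model`, `history` (per-epoch tibble),
#'   `best_epoch`, `stopped_early`.
#' @export
train_classifier <- function(train, mcfg = NULL, tcfg = train_config(),
                             val_expr, val_labels, train_labels = NULL,
                             classes = NULL) {
  ts <- as_training_set(train, train_labels, classes)
  classes <- ts$classes
  x <- ts$x
  y <- ts$y
  C <- length(classes)
  mcfg <- mcfg %||% model_config(n_genes = ncol(x), n_classes = C)
  stopifnot(mcfg$n_genes == ncol(x), mcfg$n_classes == C)

  xv <- t(val_expr)
  yv <- match(as.character(val_labels), classes)
  if (anyNA(yv)) stop("validation labels contain classes absent from training", call. = FALSE)

  model <- acmix_swin(mcfg, seed = tcfg$seed, classes = classes)
  frozen <- model_frozen(mcfg)
  opt <- adamw_init(model$params,
    lr = tcfg$learning_rate, beta1 = 0.9, beta2 = 0.999,
    weight_decay = tcfg$weight_decay
  )

  n <- nrow(x)
  nb <- min(tcfg$batch_size, n)
  best <- list(loss = Inf, params = model$params, bn = as.list(model$bn), epoch = 0)
  wait <- 0
  stopped_early <- FALSE
  hist_rows <- vector("list", tcfg$max_epochs)

  with_seed(derive_seed(tcfg$seed, "train"), {
    for (epoch in seq_len(tcfg$max_epochs)) {
      lr <- lr_schedule(epoch - 1, tcfg)
      ord <- sample.int(n)
      epoch_loss <- 0
      epoch_correct <- 0
      n_batches <- 0
      for (start in seq(1, n, by = nb)) {
        rows <- ord[start:min(start + nb - 1, n)]
        if (length(rows) < 2) next
        xb <- x[rows, , drop = FALSE]
        tb <- smooth_targets(y[rows], C, tcfg$label_smoothing)
        if (tcfg$mixup_alpha > 0) {
          lam <- stats::rbeta(1, tcfg$mixup_alpha, tcfg$mixup_alpha)
          perm <- sample.int(length(rows))
          xb <- lam * xb + (1 - lam) * xb[perm, , drop = FALSE]
          tb <- lam * tb + (1 - lam) * tb[perm, , drop = FALSE]
        }
        g <- model_graph(model, xb, training = TRUE)
        loss <- ad_softmax_xent(g$logits, tb)
        if (!is.finite(loss$value)) {
          stop(sprintf("training loss diverged (non-finite) at epoch %d", epoch), call. = FALSE)
        }
        ad_backward(loss)
        grads <- collect_grads(g$leaves, model$params)
        grads <- clip_global_norm(grads, tcfg$grad_clip_norm)$grads
        st <- adamw_step(model$params, grads, opt,
          lr = lr,
          skip = frozen, no_decay = model_no_decay()
        )
        model$params <- st$params
        opt <- st$opt
        epoch_loss <- epoch_loss + loss$value
        epoch_correct <- epoch_correct +
          sum(max.col(g$logits$value, ties.method = "first") == y[rows])
        n_batches <- n_batches + 1
      }

      val_logits <- model_forward(model, xv, training = FALSE)
      val_loss <- smoothed_cross_entropy(val_logits, yv, tcfg$label_smoothing)
      train_logits_loss <- epoch_loss / max(n_batches, 1)
      hist_rows[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = train_logits_loss,
        val_loss = val_loss,
        train_accuracy = epoch_correct / n,
        val_accuracy = mean(max.col(val_logits, ties.method = "first") == yv),
        learning_rate = lr
      )

      if (val_loss < best$loss - 1e-12) {
        best <- list(
          loss = val_loss, params = model$params,
          bn = list(mean = model$bn$mean, var = model$bn$var), epoch = epoch
        )
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= tcfg$patience) {
          stopped_early <- TRUE
          break
        }
      }
    }
  })

  model$params <- best$params
  model$bn$mean <- best$bn$mean
  model$bn$var <- best$bn$var
  history <- dplyr::bind_rows(hist_rows[!vapply(hist_rows, is.null, logical(1))])
  structure(
    list(
      model = model,
      history = structure(history, class = c("train_history", class(history))),
      best_epoch = best$epoch,
      stopped_early = stopped_early,
      config = tcfg
    ),
    class = "classifier_fit"
  )
}

#' Evaluate a classifier
#'
#' Computes the confusion matrix and accuracy / macro-precision /
#' macro-recall / macro-F1 from held-out labeled samples. Classes never
#' predicted get precision 0 (with a flag in the report).
#'
#' @param model An `acmix_swin` model (or any object with a `predict`
#'   method returning labels).
#' @param expr Genes x samples expression matrix.
#' @param labels True class labels.
#' @return A `metrics_report` list: `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `confusion` (classes x classes count
#'   matrix, rows = truth), `degenerate_classes`.
#' @export
evaluate_classifier <- function(model, expr, labels) {
  if (ncol(expr) == 0) stop("no samples to evaluate", call. = FALSE)
  classes <- model$classes %||% sort(unique(as.character(labels)))
  pred <- predict(model, t(expr))
  metrics_from_predictions(factor(as.character(labels), levels = classes),
    factor(as.character(pred), levels = classes),
    classes = classes
  )
}

metrics_from_predictions <- function(truth, pred, classes) {
  confusion <- table(truth = truth, predicted = pred)
  confusion <- unclass(confusion)[classes, classes, drop = FALSE]
  tp <- diag(confusion)
  prec_den <- colSums(confusion)
  rec_den <- rowSums(confusion)
  precision <- ifelse(prec_den > 0, tp / prec_den, 0)
  recall <- ifelse(rec_den > 0, tp / rec_den, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  structure(
    list(
      accuracy = sum(tp) / sum(confusion),
      macro_precision = mean(precision),
      macro_recall = mean(recall),
      macro_f1 = mean(f1),
      confusion = confusion,
      per_class = tibble::tibble(
        class = classes, precision = precision, recall = recall, f1 = f1
      ),
      degenerate_classes = classes[prec_den == 0]
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy %.3f | macro P %.3f R %.3f F1 %.3f\n",
    x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1
  ))
  print(x$confusion)
  if (length(x$degenerate_classes)) {
    cat("never predicted:", paste(x$degenerate_classes, collapse = ", "), "\n")
  }
  invisible(x)
}
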