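test_that("learning-rate schedule: warmup hits the peak, cosine decays to ~0", {
  cfg <- train_config() # lr 1e-4, warmup 10, 300 epochs
  # end of warmup reaches exactly the configured rate
  expect_equal(lr_schedule(10, cfg), 1e-4)
  expect_equal(lr_schedule(9, cfg), 1e-4) # last warmup epoch: lr * 10/10
  expect_equal(lr_schedule(0, cfg), 1e-5)
  # final epoch is near zero
  expect_lte(lr_schedule(299, cfg), 0.01 * 1e-4)
  # non-increasing after warmup
  rates <- vapply(10:299, lr_schedule, numeric(1), cfg = cfg)
  expect_true(all(diff(rates) <= 1e-18))
  expect_error(lr_schedule(300, cfg))
})

test_that("label-smoothed cross-entropy matches closed forms", {
  # s = 0 reduces to the ordinary cross-entropy
  set.seed(1)
  logits <- matrix(rnorm(6), 2, 3)
  y <- c(1L, 3L)
  p <- exp(logits) / rowSums(exp(logits))
  expect_equal(
    smoothed_cross_entropy(logits, y, 0),
    mean(-log(p[cbind(1:2, y)])),
    tolerance = 1e-12
  )

  # uniform logits: loss = ln C exactly, for any smoothing
  uni <- matrix(1.7, 4, 3)
  expect_equal(smoothed_cross_entropy(uni, c(1L, 2L, 3L, 1L), 0), log(3), tolerance = 1e-12)
  expect_equal(smoothed_cross_entropy(uni, c(1L, 2L, 3L, 1L), 0.05), log(3), tolerance = 1e-12)
  expect_equal(smoothed_cross_entropy(uni, c(1L, 2L, 3L, 1L), 0.5), log(3), tolerance = 1e-12)

  # s = 0.05, C = 3: hand evaluation on a 2-sample toy batch
  lg <- rbind(c(4, 0, 0), c(0, 5, 1))
  yy <- c(1L, 2L)
  hand <- 0
  for (i in 1:2) {
    logp <- lg[i, ] - log(sum(exp(lg[i, ])))
    tgt <- rep(0.05 / 3, 3)
    tgt[yy[i]] <- 0.95 + 0.05 / 3
    hand <- hand - sum(tgt * logp)
  }
  expect_equal(smoothed_cross_entropy(lg, yy, 0.05), hand / 2, tolerance = 1e-12)
})

test_that("training history, early stopping and best-epoch restoration behave", {
  ds <- tiny_dataset(n_genes = 40, seed = 44)
  z <- zscore_normalize(ds$expr)
  meta <- ds$meta
  va <- meta$sample_id[meta$replicate == 6]
  tr <- setdiff(meta$sample_id, va)
  lab <- function(ids) meta$class_label[match(ids, meta$sample_id)]

  tcfg <- train_config(max_epochs = 30, patience = 30, batch_size = 16, seed = 3, learning_rate = 1e-3)
  fit <- train_classifier(z[, tr],
    tcfg = tcfg,
    val_expr = z[, va], val_labels = lab(va), train_labels = lab(tr)
  )
  h <- fit$history
  expect_lte(nrow(h), 30)
  expect_equal(fit$best_epoch, h$epoch[which.min(h$val_loss)])
  expect_equal(
    h$learning_rate,
    vapply(h$epoch - 1, lr_schedule, numeric(1), cfg = tcfg)
  )

  # determinism: identical config + seed -> identical history
  fit2 <- train_classifier(z[, tr],
    tcfg = tcfg,
    val_expr = z[, va], val_labels = lab(va), train_labels = lab(tr)
  )
  expect_equal(as.data.frame(fit$history), as.data.frame(fit2$history), tolerance = 1e-15)

  # tight patience stops early
  tcfg_p <- train_config(max_epochs = 30, patience = 2, batch_size = 16, seed = 3, learning_rate = 1)
  fit3 <- train_classifier(z[, tr],
    tcfg = tcfg_p,
    val_expr = z[, va], val_labels = lab(va), train_labels = lab(tr)
  )
  expect_true(fit3$stopped_early || nrow(fit3$history) < 30)
})

test_that("gradient clipping caps the global norm", {
  grads <- list(a = matrix(3, 2, 2), b = rep(4, 5))
  out <- castehub:::clip_global_norm(grads, 1.0)
  total <- sqrt(sum(unlist(lapply(out$grads, function(g) sum(g^2)))))
  expect_lte(total, 1.0 + 1e-6)
  # directions preserved
  expect_equal(out$grads$a / out$grads$a[1, 1], grads$a / grads$a[1, 1])
  # small gradients pass through untouched
  small <- list(a = matrix(1e-3, 2, 2))
  expect_identical(castehub:::clip_global_norm(small, 1.0)$grads, small)
})

test_that("evaluation metrics are internally consistent", {
  classes <- c("queen", "worker", "drone")
  truth <- factor(rep(classes, each = 4), levels = classes)

  # perfect predictor
  m1 <- castehub:::metrics_from_predictions(truth, truth, classes)
  expect_equal(m1$accuracy, 1)
  expect_equal(unname(diag(m1$confusion)), rep(4, 3))
  expect_equal(m1$macro_f1, 1)

  # constant predictor on balanced classes: accuracy = recall = 1/3
  pred_const <- factor(rep("queen", 12), levels = classes)
  m2 <- castehub:::metrics_from_predictions(truth, pred_const, classes)
  expect_equal(m2$accuracy, 1 / 3)
  expect_equal(m2$macro_recall, 1 / 3)
  expect_setequal(m2$degenerate_classes, c("worker", "drone"))

  # metrics recomputed from the returned confusion match the scalars
  set.seed(2)
  pred_rand <- factor(sample(classes, 12, replace = TRUE), levels = classes)
  m3 <- castehub:::metrics_from_predictions(truth, pred_rand, classes)
  cm <- m3$confusion
  expect_equal(m3$accuracy, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  prec <- ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), 0)
  rec <- diag(cm) / rowSums(cm)
  expect_equal(m3$macro_precision, mean(prec), tolerance = 1e-12)
  expect_equal(m3$macro_recall, mean(rec), tolerance = 1e-12)
  expect_equal(sum(cm), 12)
})

test_that("tidiers summarize fits and metrics", {
  ds <- tiny_dataset(n_genes = 30, seed = 45)
  z <- zscore_normalize(ds$expr)
  meta <- ds$meta
  va <- meta$sample_id[meta$replicate >= 5]
  tr <- setdiff(meta$sample_id, va)
  lab <- function(ids) meta$class_label[match(ids, meta$sample_id)]
  fit <- train_classifier(z[, tr],
    tcfg = train_config(max_epochs = 3, patience = 3, seed = 1),
    val_expr = z[, va], val_labels = lab(va), train_labels = lab(tr)
  )
  td <- tidy(fit)
  expect_true(all(c("parameter", "n_values", "l2_norm") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("alpha", "beta", "best_epoch") %in% names(gl)))

  rep <- evaluate_classifier(fit$model, z[, va], lab(va))
  expect_equal(nrow(tidy(rep)), 3)
  expect_equal(glance(rep)$n, length(va))
})
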