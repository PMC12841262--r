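# A tiny trained model shared by the attribution tests.
fit_tiny_model <- function(n_genes = 30, seed = 46) {
  ds <- tiny_dataset(n_genes = n_genes, seed = seed)
  z <- zscore_normalize(ds$expr)
  meta <- ds$meta
  va <- meta$sample_id[meta$replicate >= 5]
  tr <- setdiff(meta$sample_id, va)
  lab <- function(ids) meta$class_label[match(ids, meta$sample_id)]
  fit <- train_classifier(z[, tr],
    tcfg = train_config(
      max_epochs = 15, patience = 15, batch_size = 12,
      learning_rate = 1e-3, seed = 5
    ),
    val_expr = z[, va], val_labels = lab(va), train_labels = lab(tr)
  )
  list(model = fit$model, z = z, meta = meta)
}

test_that("gradient x input matches a central finite-difference oracle", {
  env <- fit_tiny_model()
  model <- env$model
  z <- env$z
  meta <- env$meta
  x_cols <- meta$sample_id[c(1, 7, 13)] # one per class
  expr <- z[, x_cols]
  labels <- meta$class_label[match(x_cols, meta$sample_id)]

  got <- gradient_x_input(model, expr, labels)
  expect_equal(got$gene_id, rownames(expr))
  expect_true(all(got$importance >= 0))

  # oracle: per-sample loss via plain forward; perturb one gene at a time
  classes <- model$classes
  y <- match(labels, classes)
  loss_of <- function(xrow, yi) {
    logits <- model_forward(model, matrix(xrow, 1))
    p <- exp(logits - max(logits))
    p <- p / sum(p)
    -log(p[yi])
  }
  h <- 1e-4
  set.seed(3)
  test_genes <- sample(nrow(expr), 10)
  for (g in test_genes) {
    prods <- numeric(ncol(expr))
    for (s in seq_len(ncol(expr))) {
      xp <- expr[, s]; xp[g] <- xp[g] + h
      xm <- expr[, s]; xm[g] <- xm[g] - h
      grad_fd <- (loss_of(xp, y[s]) - loss_of(xm, y[s])) / (2 * h)
      prods[s] <- grad_fd * expr[g, s]
    }
    expect_equal(unname(got$importance[g]), mean(abs(prods)),
      tolerance = 1e-3,
      label = sprintf("gene %d", g)
    )
  }
})

test_that("an all-zero input sample contributes zero to every gene", {
  env <- fit_tiny_model(seed = 47)
  model <- env$model
  zero <- matrix(0, nrow(env$z), 1,
    dimnames = list(rownames(env$z), "null_sample")
  )
  got <- gradient_x_input(model, zero, model$classes[1])
  expect_true(all(got$importance == 0))
})

test_that("class importance concentrates on the discriminative support (linear case)", {
  # hand-built two-class linear model with disjoint supports: importance for
  # class A must vanish off A's support
  cfg <- model_config(
    n_genes = 8, n_classes = 2, embed_dim = 4, n_tokens = 2, n_heads = 2,
    window_size = 2, hidden_embed = 6,
    dropout_embed = 0, dropout_block = 0, dropout_head = 0
  )
  model <- acmix_swin(cfg, seed = 1, classes = c("A", "B"))
  # zero the embedding path except a direct copy of genes 1-4 for class A
  # is intricate for the full architecture; instead verify the invariant
  # numerically: genes with zero weight everywhere in the first layer
  # receive zero importance
  model$params$We1[5:8, ] <- 0
  x <- matrix(rnorm(6 * 8), 8, 6,
    dimnames = list(paste0("g", 1:8), paste0("s", 1:6))
  )
  imp <- class_importance(model, x, rep(c("A", "B"), 3), "A")
  expect_true(all(imp$importance[5:8] == 0))
  expect_true(any(imp$importance[1:4] > 0))

  expect_error(class_importance(model, x, rep("A", 6), "C"), "unknown class")
  expect_error(class_importance(model, x, rep("B", 6), "A"), "no samples")
})

test_that("combined scoring modes follow their formulas and degenerate correctly", {
  dl <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    importance = c(5, 4, 3, 2, 1)
  )
  net <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    GS = c(0.1, 0.2, 0.9, 0.8, 0.7),
    MM = c(0.1, -0.3, 0.9, -0.9, 0.5),
    module = "M1"
  )

  # w_dl = 1: ranking identical to the DL ranking
  c1 <- combine_scores(dl, net, w_dl = 1)
  expect_equal(c1$gene_id, paste0("g", 1:5))
  expect_equal(c1$combined, castehub:::minmax_rescale(dl$importance))

  # w_dl = 0: ranking identical to the network-score ranking (GS * |MM|)
  c0 <- combine_scores(dl, net, w_dl = 0)
  expect_equal(c0$gene_id, net$gene_id[order(-net$GS * abs(net$MM), net$gene_id)])

  # w_dl = 0.5 weights both rescaled families equally
  c5 <- combine_scores(dl, net, w_dl = 0.5)
  manual <- 0.5 * castehub:::minmax_rescale(dl$importance) +
    0.5 * castehub:::minmax_rescale(net$GS * abs(net$MM))
  expect_equal(c5$combined[match(dl$gene_id, c5$gene_id)], manual, tolerance = 1e-12)

  # product mode: DL_score * GS * |MM|
  cp <- combine_scores(dl, net, mode = "product")
  manualp <- castehub:::minmax_rescale(dl$importance) * net$GS * abs(net$MM)
  expect_equal(cp$combined[match(dl$gene_id, cp$gene_id)], manualp, tolerance = 1e-12)

  # product mode with all-equal network scores ranks like w_dl = 1
  net_flat <- net
  net_flat$GS <- 0.5
  net_flat$MM <- 0.5
  expect_equal(
    combine_scores(dl, net_flat, mode = "product")$gene_id,
    combine_scores(dl, net_flat, w_dl = 1)$gene_id
  )

  # missing genes get network score 0 with a warning
  expect_warning(cm <- combine_scores(dl, net[1:3, ], w_dl = 0), "missing network scores")
  expect_true(all(cm$wgcna_score[cm$gene_id %in% c("g4", "g5")] == 0))

  expect_error(combine_scores(dl, net, w_dl = 1.2), "w_dl")
})

test_that("hub selection sizes, truncation and deterministic tie-breaking", {
  scores <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:40),
    combined = rep(c(0.9, 0.5), each = 20)
  )
  per_class <- list(
    queen = tibble::tibble(gene_id = sprintf("q%02d", 1:15), combined = 15:1),
    worker = tibble::tibble(gene_id = sprintf("w%02d", 1:15), combined = 1:15)
  )
  hubs <- select_hubs(scores, per_class)
  expect_equal(hubs$n_overall, 20)
  expect_equal(unname(hubs$n_per_class), c(10, 10))
  # ties broken lexicographically: the 20 genes at 0.9 are g001..g020
  expect_equal(hubs$overall$gene_id, sprintf("g%03d", 1:20))
  # stable across calls
  expect_identical(hubs$overall, select_hubs(scores, per_class)$overall)
  expect_equal(hubs$per_class$worker$gene_id[1], "w15")

  expect_warning(small <- select_hubs(scores[1:5, ], n_overall = 20), "only 5")
  expect_equal(small$n_overall, 5)
})

test_that("hub network export respects the correlation threshold", {
  set.seed(8)
  base <- rnorm(12)
  expr <- rbind(
    g1 = base, g2 = base + rnorm(12, 0, 0.05), # near-perfect pair
    g3 = rnorm(12), g4 = rnorm(12)
  )
  colnames(expr) <- paste0("s", 1:12)
  hubs <- select_hubs(
    tibble::tibble(gene_id = rownames(expr), combined = 4:1),
    list(), n_overall = 4
  )

  # threshold 0: complete graph on the hubs
  net0 <- export_hub_network(hubs, expr, cor_threshold = 0)
  expect_equal(nrow(net0$edges), choose(4, 2))
  expect_true(all(net0$edges$weight >= 0 & net0$edges$weight <= 1))

  # threshold 1: no pair is perfectly correlated on noisy data
  net1 <- export_hub_network(hubs, expr, cor_threshold = 1)
  expect_equal(nrow(net1$edges), 0)

  # high threshold keeps only the planted pair
  net9 <- export_hub_network(hubs, expr, cor_threshold = 0.9)
  expect_equal(nrow(net9$edges), 1)
  expect_setequal(c(net9$edges$from, net9$edges$to), c("g1", "g2"))
})
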