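test_that("embedding produces (B, 7, 64) tokens deterministically in eval mode", {
  cfg <- model_config(n_genes = 50)
  model <- acmix_swin(cfg, seed = 1)
  set.seed(2)
  x <- matrix(rnorm(4 * 50), 4, 50)
  tok <- embed_input(model, x)
  expect_equal(dim(tok), c(4, 7, 64))
  expect_identical(tok, embed_input(model, x)) # no stochastic path in eval
  expect_error(embed_input(model, x[, 1:10]), "expects")
})

test_that("windowed attention matches masked dense attention and is local", {
  set.seed(3)
  B <- 2; L <- 8; D <- 8; heads <- 2; W <- 4
  dk <- D / heads
  tokens <- array(rnorm(B * L * D), c(B, L, D))
  weights <- list(
    Wq = matrix(rnorm(D * D, 0, 0.3), D), bq = rnorm(D),
    Wk = matrix(rnorm(D * D, 0, 0.3), D), bk = rnorm(D),
    Wv = matrix(rnorm(D * D, 0, 0.3), D), bv = rnorm(D),
    Wo = matrix(rnorm(D * D, 0, 0.3), D), bo = rnorm(D),
    bias = matrix(rnorm(heads * (2 * W - 1), 0, 0.2), heads)
  )
  out <- window_attention(tokens, weights, heads, W)
  expect_equal(dim(out), dim(tokens))

  # oracle: dense per-window attention head by head
  for (b in seq_len(B)) {
    X <- tokens[b, , ]
    Q <- sweep(X %*% weights$Wq, 2, weights$bq, "+")
    K <- sweep(X %*% weights$Wk, 2, weights$bk, "+")
    V <- sweep(X %*% weights$Wv, 2, weights$bv, "+")
    O <- matrix(0, L, D)
    for (w in seq_len(L / W)) {
      rows <- (w - 1) * W + seq_len(W)
      for (h in seq_len(heads)) {
        cols <- (h - 1) * dk + seq_len(dk)
        bias_mat <- outer(seq_len(W), seq_len(W), function(i, j) {
          weights$bias[h, j - i + W]
        })
        O[rows, cols] <- dense_attention_oracle(
          Q[rows, cols], K[rows, cols], V[rows, cols], bias_mat, dk
        )
      }
    }
    O <- sweep(O %*% weights$Wo, 2, weights$bo, "+")
    expect_equal(out[b, , ], O, tolerance = 1e-10)
  }
})

test_that("attention degenerates correctly: uniform weights and window 1", {
  B <- 1; L <- 4; D <- 4; heads <- 2
  set.seed(4)
  tokens <- array(rnorm(B * L * D), c(B, L, D))
  idw <- diag(D)
  # Q = K = 0 and zero bias -> uniform attention -> per-window mean of V
  weights0 <- list(
    Wq = matrix(0, D, D), bq = numeric(D),
    Wk = matrix(0, D, D), bk = numeric(D),
    Wv = idw, bv = numeric(D),
    Wo = idw, bo = numeric(D),
    bias = matrix(0, heads, 2 * L - 1)
  )
  out <- window_attention(tokens, weights0, heads, window = L)
  expect_equal(out[1, 1, ], colMeans(tokens[1, , ]), tolerance = 1e-10)
  expect_equal(out[1, 3, ], colMeans(tokens[1, , ]), tolerance = 1e-10)

  # window = 1: output token t depends only on input token t
  weights1 <- weights0
  weights1$bias <- matrix(0, heads, 1)
  weights1$Wq <- matrix(rnorm(D * D), D)
  weights1$Wk <- matrix(rnorm(D * D), D)
  base <- window_attention(tokens, weights1, heads, window = 1)
  perturbed <- tokens
  perturbed[1, 2, ] <- perturbed[1, 2, ] + 10
  out_p <- window_attention(perturbed, weights1, heads, window = 1)
  expect_equal(out_p[1, -2, ], base[1, -2, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out_p[1, 2, ], base[1, 2, ])))
})

test_that("attention rejects token counts not divisible by the window", {
  cfg_err <- tryCatch(model_config(n_genes = 10, n_tokens = 7, window_size = 3),
    error = identity
  )
  expect_s3_class(cfg_err, "error")
  tokens <- array(rnorm(1 * 6 * 4), c(1, 6, 4))
  weights <- list(
    Wq = diag(4), bq = numeric(4), Wk = diag(4), bk = numeric(4),
    Wv = diag(4), bv = numeric(4), Wo = diag(4), bo = numeric(4),
    bias = matrix(0, 2, 7)
  )
  expect_error(window_attention(tokens, weights, 2, window = 4), "divisible")
})

test_that("convolution branch is shape-preserving, channelwise and delta-kernel exact", {
  cfg <- model_config(n_genes = 20, embed_dim = 8, n_tokens = 4, n_heads = 2, window_size = 4)
  model <- acmix_swin(cfg, seed = 5)
  set.seed(6)
  tokens <- array(rnorm(3 * 4 * 8), c(3, 4, 8))

  out <- conv_branch(tokens, model)
  expect_equal(dim(out), dim(tokens))

  # delta kernel + identity pointwise + neutral normalization = identity
  # before the GELU, so output = GELU(tokens)
  model$params$dw <- rbind(rep(0, 8), rep(1, 8), rep(0, 8))
  model$params$dw_b <- numeric(8)
  model$params$Wp <- diag(8)
  model$params$bp <- numeric(8)
  model$bn$mean <- numeric(8)
  model$bn$var <- rep(1, 8)
  out_id <- conv_branch(tokens, model, training = FALSE)
  # inference batch norm scales by 1/sqrt(1 + eps), a 5e-6 relative factor
  expect_equal(out_id, array(tokens * stats::pnorm(tokens), dim(tokens)), tolerance = 1e-4)

  # depthwise stage mixes no channels: zeroing channel c changes only c
  tokens2 <- tokens
  tokens2[, , 3] <- 0
  m2 <- model
  m2$params$Wp <- diag(8) # keep pointwise identity to observe the depthwise stage
  a <- conv_branch(tokens, m2)
  b <- conv_branch(tokens2, m2)
  expect_equal(a[, , -3], b[, , -3], tolerance = 1e-10)
})

test_that("branch fusion is the stated linear combination", {
  set.seed(7)
  att <- array(rnorm(24), c(2, 3, 4))
  conv <- array(rnorm(24), c(2, 3, 4))
  expect_equal(fuse_branches(att, conv, 1, 0), att)
  expect_equal(fuse_branches(att, conv, 0.5, 0.5), (att + conv) / 2)
  expect_equal(fuse_branches(att, conv, 0.462, 0.365), 0.462 * att + 0.365 * conv)
  expect_error(fuse_branches(att, conv[, 1:2, ], 1, 1), "identical shapes")
})

test_that("forward pass yields (B, 3) logits, eval determinism, per-sample independence", {
  cfg <- model_config(n_genes = 30)
  model <- acmix_swin(cfg, seed = 8, classes = c("queen", "worker", "drone"))
  set.seed(9)
  x <- matrix(rnorm(5 * 30), 5, 30)
  logits <- model_forward(model, x)
  expect_equal(dim(logits), c(5, 3))
  expect_identical(logits, model_forward(model, x))

  # permuting samples permutes logits identically (running-stats batch norm)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(model_forward(model, x[perm, ]), logits[perm, ],
    tolerance = 1e-12, ignore_attr = TRUE
  )

  pred <- predict(model, x)
  expect_s3_class(pred, "factor")
  expect_length(pred, 5)
})

test_that("checkpoints round-trip the model exactly", {
  cfg <- model_config(n_genes = 25)
  model <- acmix_swin(cfg, seed = 12, classes = c("queen", "worker", "drone"))
  model$bn$mean <- rnorm(64)
  model$bn$var <- runif(64, 0.5, 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  set.seed(13)
  x <- matrix(rnorm(3 * 25), 3, 25)
  expect_identical(model_forward(back, x), model_forward(model, x))
  expect_identical(back$classes, model$classes)
})

test_that("one optimization step moves both branches (gradient flows everywhere)", {
  ds <- tiny_dataset(n_genes = 30, seed = 43)
  z <- zscore_normalize(ds$expr)
  cfg <- model_config(n_genes = 30)
  tcfg <- train_config(max_epochs = 1, patience = 1, batch_size = 18, seed = 2, learning_rate = 1e-3)
  before <- acmix_swin(cfg, seed = tcfg$seed)$params
  fit <- train_classifier(
    z, mcfg = cfg, tcfg = tcfg,
    val_expr = z[, 1:3], val_labels = ds$meta$class_label[1:3],
    train_labels = ds$meta$class_label
  )
  after <- fit$model$params
  att_names <- c("Wq", "Wk", "Wv", "Wo", "bias")
  conv_names <- c("dw", "Wp", "bn_g")
  d_att <- sum(vapply(att_names, function(nm) sum((after[[nm]] - before[[nm]])^2), numeric(1)))
  d_conv <- sum(vapply(conv_names, function(nm) sum((after[[nm]] - before[[nm]])^2), numeric(1)))
  expect_gt(d_att, 0)
  expect_gt(d_conv, 0)
})

test_that("model parameter gradients agree with finite differences", {
  # end-to-end check through embedding, attention, convolution, batch norm,
  # fusion, layer norm, pooling and the head (training mode, dropout off)
  cfg <- model_config(
    n_genes = 12, n_classes = 3, embed_dim = 8, n_tokens = 4,
    n_heads = 2, window_size = 2, hidden_embed = 10,
    dropout_embed = 0, dropout_block = 0, dropout_head = 0
  )
  model <- acmix_swin(cfg, seed = 10)
  set.seed(11)
  x <- matrix(rnorm(3 * 12), 3, 12)
  y <- c(1L, 2L, 3L)
  targets <- castehub:::smooth_targets(y, 3, 0.05)

  loss_value <- function(params) {
    m2 <- model
    m2$params <- params
    m2$bn <- new.env()
    m2$bn$mean <- numeric(8); m2$bn$var <- rep(1, 8); m2$bn$momentum <- 0.1
    g <- castehub:::model_graph(m2, x, training = TRUE)
    castehub:::ad_value(castehub:::ad_softmax_xent(g$logits, targets))
  }

  m0 <- model
  m0$bn <- new.env()
  m0$bn$mean <- numeric(8); m0$bn$var <- rep(1, 8); m0$bn$momentum <- 0.1
  g <- castehub:::model_graph(m0, x, training = TRUE)
  loss <- castehub:::ad_softmax_xent(g$logits, targets)
  castehub:::ad_backward(loss)
  grads <- castehub:::collect_grads(g$leaves, model$params)

  eps <- 1e-5
  for (nm in c("We1", "Wq", "bias", "dw", "Wp", "alpha", "beta", "Wh", "ln2_g")) {
    p0 <- model$params
    idx <- seq_len(min(5, length(p0[[nm]])))
    for (i in idx) {
      pp <- p0; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p0; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (loss_value(pp) - loss_value(pm)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]][i]), fd,
        tolerance = 1e-4,
        label = sprintf("grad %s[%d]", nm, i)
      )
    }
  }
})
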