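# Deep baseline models (MLP, 1D-CNN, LSTM, Transformer) built on the same
# autodiff engine and AdamW recipe as the main classifier. Classical
# baselines (KNN, RBF-SVM, multinomial logistic, random forest) delegate to
# class, e1071, nnet and randomForest.

# Generic minibatch trainer for a forward builder: builder(P, xb, training)
# must return the logits node. Plain cross-entropy, AdamW, cosine decay.
train_deep_generic <- function(params, builder, x, y, C, epochs = 100,
                               lr = 1e-3, batch_size = 32, seed = 1,
                               weight_decay = 1e-4) {
  opt <- adamw_init(params, lr = lr, weight_decay = weight_decay)
  n <- nrow(x)
  nb <- min(batch_size, n)
  with_seed(derive_seed(seed, "deep_baseline"), {
    for (epoch in seq_len(epochs)) {
      lr_e <- lr * 0.5 * (1 + cos(pi * (epoch - 1) / epochs))
      ord <- sample.int(n)
      for (start in seq(1, n, by = nb)) {
        rows <- ord[start:min(start + nb - 1, n)]
        if (length(rows) < 2) next
        P <- leafify(params)
        logits <- builder(P, x[rows, , drop = FALSE], TRUE)
        targets <- smooth_targets(y[rows], C, 0)
        loss <- ad_softmax_xent(logits, targets)
        ad_backward(loss)
        grads <- collect_grads(P, params)
        grads <- clip_global_norm(grads, 5)$grads
        st <- adamw_step(params, grads, opt, lr = lr_e)
        params <- st$params
        opt <- st$opt
      }
    }
  })
  params
}

predict_deep_generic <- function(params, builder, x, classes) {
  P <- leafify(params)
  logits <- builder(P, x, FALSE)$value
  factor(classes[max.col(logits, ties.method = "first")], levels = classes)
}

## ---- MLP: one hidden layer of 128 ----------------------------------------

mlp_baseline <- function(n_genes, C, seed) {
  with_seed(derive_seed(seed, "mlp_init"), {
    params <- list(
      W1 = init_dense(n_genes, 128), b1 = numeric(128),
      W2 = init_dense(128, C), b2 = numeric(C)
    )
  })
  builder <- function(P, xb, training) {
    h <- ad_gelu(ad_add_bias(ad_matmul(ad_wrap(xb), P$W1), P$b1))
    h <- ad_dropout(h, 0.3, training)
    ad_add_bias(ad_matmul(h, P$W2), P$b2)
  }
  list(params = params, builder = builder)
}

## ---- 1D-CNN: two convolution layers over the gene axis --------------------

cnn1d_baseline <- function(n_genes, C, seed) {
  ch1 <- 8; ch2 <- 16; pool <- 4
  L2 <- n_genes %/% pool
  L3 <- L2 %/% pool
  with_seed(derive_seed(seed, "cnn_init"), {
    params <- list(
      K1 = array(stats::rnorm(7 * 1 * ch1, 0, sqrt(2 / 7)), c(7, 1, ch1)),
      c1b = numeric(ch1),
      K2 = array(stats::rnorm(5 * ch1 * ch2, 0, sqrt(2 / (5 * ch1))), c(5, ch1, ch2)),
      c2b = numeric(ch2),
      # position-preserving flatten head (gene positions are meaningful)
      Wh = init_dense(L3 * ch2, C), bh = numeric(C)
    )
  })
  builder <- function(P, xb, training) {
    B <- nrow(xb)
    sig <- ad_wrap(matrix(as.numeric(t(xb)), B * n_genes, 1)) # (B*G) x 1
    h <- ad_gelu(ad_conv1d(sig, P$K1, P$c1b, B, n_genes))
    h <- ad_token_pool(h, B, n_genes, pool)
    h <- ad_gelu(ad_conv1d(h, P$K2, P$c2b, B, L2))
    h <- ad_token_pool(h, B, L2, pool)
    flat <- ad_from_tokens(h, B, L3)
    ad_add_bias(ad_matmul(flat, P$Wh), P$bh)
  }
  list(params = params, builder = builder)
}

## ---- token chunking shared by LSTM / Transformer --------------------------

# Split a gene vector into n_chunk contiguous chunks (zero-padded).
chunk_tokens <- function(xb, n_chunk) {
  B <- nrow(xb)
  G <- ncol(xb)
  width <- ceiling(G / n_chunk)
  padded <- matrix(0, B, n_chunk * width)
  padded[, seq_len(G)] <- xb
  # token t of sample b -> row (b-1)*n_chunk + t
  out <- matrix(0, B * n_chunk, width)
  for (t in seq_len(n_chunk)) {
    out[(seq_len(B) - 1) * n_chunk + t, ] <- padded[, (t - 1) * width + seq_len(width)]
  }
  out
}

## ---- LSTM over gene chunks ------------------------------------------------

lstm_baseline <- function(n_genes, C, seed, n_chunk = 8, hidden = 64) {
  width <- ceiling(n_genes / n_chunk)
  with_seed(derive_seed(seed, "lstm_init"), {
    params <- list(
      Wx = init_dense(width, 4 * hidden),
      Wh = init_dense(hidden, 4 * hidden),
      b = numeric(4 * hidden),
      Wo = init_dense(hidden, C), bo = numeric(C)
    )
    # forget-gate bias 1 for stable memory at init
    params$b[hidden + seq_len(hidden)] <- 1
  })
  builder <- function(P, xb, training) {
    B <- nrow(xb)
    toks <- chunk_tokens(xb, n_chunk)
    h <- ad_wrap(matrix(0, B, hidden))
    cst <- ad_wrap(matrix(0, B, hidden))
    for (t in seq_len(n_chunk)) {
      xt <- ad_wrap(toks[(seq_len(B) - 1) * n_chunk + t, , drop = FALSE])
      z <- ad_add_bias(ad_add(ad_matmul(xt, P$Wx), ad_matmul(h, P$Wh)), P$b)
      i <- ad_sigmoid(ad_cols(z, seq_len(hidden)))
      f <- ad_sigmoid(ad_cols(z, hidden + seq_len(hidden)))
      o <- ad_sigmoid(ad_cols(z, 2 * hidden + seq_len(hidden)))
      g <- ad_tanh(ad_cols(z, 3 * hidden + seq_len(hidden)))
      cst <- ad_add(ad_mul(f, cst), ad_mul(i, g))
      h <- ad_mul(o, ad_tanh(cst))
    }
    ad_add_bias(ad_matmul(h, P$Wo), P$bo)
  }
  list(params = params, builder = builder)
}

## ---- Transformer encoder (2 layers, 4 heads) over gene chunks -------------

transformer_baseline <- function(n_genes, C, seed, n_chunk = 8, d_model = 32) {
  width <- ceiling(n_genes / n_chunk)
  n_heads <- 4
  with_seed(derive_seed(seed, "trf_init"), {
    params <- list(
      Wemb = init_dense(width, d_model), bemb = numeric(d_model),
      pos = matrix(stats::rnorm(n_chunk * d_model, 0, 0.02), n_chunk, d_model)
    )
    for (l in 1:2) {
      params[[paste0("Wq", l)]] <- init_dense(d_model, d_model)
      params[[paste0("Wk", l)]] <- init_dense(d_model, d_model)
      params[[paste0("Wv", l)]] <- init_dense(d_model, d_model)
      params[[paste0("Wo", l)]] <- init_dense(d_model, d_model)
      params[[paste0("bias", l)]] <- matrix(0, n_heads, 2 * n_chunk - 1)
      params[[paste0("lng", l)]] <- rep(1, d_model)
      params[[paste0("lnb", l)]] <- numeric(d_model)
      params[[paste0("Wf1_", l)]] <- init_dense(d_model, 2 * d_model)
      params[[paste0("bf1_", l)]] <- numeric(2 * d_model)
      params[[paste0("Wf2_", l)]] <- init_dense(2 * d_model, d_model)
      params[[paste0("bf2_", l)]] <- numeric(d_model)
      params[[paste0("lng2_", l)]] <- rep(1, d_model)
      params[[paste0("lnb2_", l)]] <- numeric(d_model)
    }
    params$Wh <- init_dense(d_model, C)
    params$bh <- numeric(C)
  })
  builder <- function(P, xb, training) {
    B <- nrow(xb)
    toks <- chunk_tokens(xb, n_chunk)
    emb <- ad_add_bias(ad_matmul(ad_wrap(toks), P$Wemb), P$bemb)
    h <- ad_add(emb, ad_rows(P$pos, rep(seq_len(n_chunk), times = B)))
    for (l in 1:2) {
      q <- ad_matmul(h, P[[paste0("Wq", l)]])
      k <- ad_matmul(h, P[[paste0("Wk", l)]])
      v <- ad_matmul(h, P[[paste0("Wv", l)]])
      att <- ad_window_attention(q, k, v, P[[paste0("bias", l)]], n_heads, n_chunk, B, n_chunk)
      att <- ad_matmul(att, P[[paste0("Wo", l)]])
      h <- ad_layernorm(ad_add(h, att), P[[paste0("lng", l)]], P[[paste0("lnb", l)]])
      ff <- ad_gelu(ad_add_bias(ad_matmul(h, P[[paste0("Wf1_", l)]]), P[[paste0("bf1_", l)]]))
      ff <- ad_add_bias(ad_matmul(ff, P[[paste0("Wf2_", l)]]), P[[paste0("bf2_", l)]])
      h <- ad_layernorm(ad_add(h, ff), P[[paste0("lng2_", l)]], P[[paste0("lnb2_", l)]])
    }
    pooled <- ad_token_mean(h, B, n_chunk)
    ad_add_bias(ad_matmul(pooled, P$Wh), P$bh)
  }
  list(params = params, builder = builder)
}
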