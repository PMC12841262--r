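#' Classifier model configuration
#'
#' Architecture hyperparameters of the hybrid windowed-attention /
#' depthwise-convolution classifier: a two-layer embedding (LayerNorm, GELU,
#' dropout 0.15) maps the gene vector to `n_tokens` tokens of width
#' `embed_dim`; one block runs a Swin-style windowed multi-head attention
#' branch (relative positional bias) in parallel with a depthwise-separable
#' convolution branch over the shared V projection, fused as
#' `alpha * attention + beta * convolution`; LayerNorm, mean pooling and a
#' dropout-0.3 linear head produce the class logits.
#'
#' @param n_genes Number of input genes.
#' @param n_classes Number of phenotype classes (default 3).
#' @param embed_dim Token width (default 64; divisible by `n_heads`).
#' @param n_tokens Number of tokens (default 7).
#' @param n_heads Attention heads (default 8).
#' @param window_size Attention window length (default 7; must divide
#'   `n_tokens`).
#' @param hidden_embed Width of the first embedding layer (default 256).
#' @param dropout_embed,dropout_block,dropout_head Dropout rates
#'   (defaults 0.15, 0.6, 0.3).
#' @param conv_kernel Depthwise kernel width (default 3).
#' @param alpha_init,beta_init Initial fusion weights (default 0.5 each).
#' @param alpha_trainable,beta_trainable Set `FALSE` to pin a fusion weight
#'   (used by the ablation variants).
#' @return A `model_config` list.
#' @export
model_config <- function(n_genes, n_classes = 3, embed_dim = 64, n_tokens = 7,
                         n_heads = 8, window_size = 7, hidden_embed = 256,
                         dropout_embed = 0.15, dropout_block = 0.6,
                         dropout_head = 0.3, conv_kernel = 3,
                         alpha_init = 0.5, beta_init = 0.5,
                         alpha_trainable = TRUE, beta_trainable = TRUE) {
  cfg <- list(
    n_genes = n_genes, n_classes = n_classes, embed_dim = embed_dim,
    n_tokens = n_tokens, n_heads = n_heads, window_size = window_size,
    hidden_embed = hidden_embed, dropout_embed = dropout_embed,
    dropout_block = dropout_block, dropout_head = dropout_head,
    conv_kernel = conv_kernel, alpha_init = alpha_init, beta_init = beta_init,
    alpha_trainable = alpha_trainable, beta_trainable = beta_trainable
  )
  if (cfg$embed_dim %% cfg$n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  if (cfg$window_size > cfg$n_tokens || cfg$n_tokens %% cfg$window_size != 0) {
    stop("window_size must divide n_tokens", call. = FALSE)
  }
  structure(cfg, class = "model_config")
}

#' Construct an untrained hybrid attention/convolution classifier
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for parameter initialization.
#' @param classes Optional character vector of class labels (stored for
#'   prediction).
#' @return An `acmix_swin` model object.
#' @export
acmix_swin <- function(cfg, seed = 1, classes = NULL) {
  D <- cfg$embed_dim
  L <- cfg$n_tokens
  with_seed(derive_seed(seed, "model_init"), {
    params <- list(
      # gene-facing layer initialized small: the layer norm right after it
      # makes the forward pass scale-free, while input gradients (the basis
      # of Gradient x Input attribution) are then dominated by the learned
      # weights rather than by the random initialization
      We1 = 0.01 * init_dense(cfg$n_genes, cfg$hidden_embed),
      be1 = numeric(cfg$hidden_embed),
      ln1_g = rep(1, cfg$hidden_embed), ln1_b = numeric(cfg$hidden_embed),
      We2 = init_dense(cfg$hidden_embed, L * D),
      be2 = numeric(L * D),
      Wq = init_dense(D, D), bq = numeric(D),
      Wk = init_dense(D, D), bk = numeric(D),
      Wv = init_dense(D, D), bv = numeric(D),
      bias = matrix(0, cfg$n_heads, 2 * cfg$window_size - 1), # zero-init rel. bias
      Wo = init_dense(D, D), bo = numeric(D),
      dw = matrix(stats::rnorm(cfg$conv_kernel * D, 0, sqrt(1 / cfg$conv_kernel)),
        cfg$conv_kernel, D
      ),
      dw_b = numeric(D),
      Wp = init_dense(D, D), bp = numeric(D),
      bn_g = rep(1, D), bn_b = numeric(D),
      alpha = cfg$alpha_init, beta = cfg$beta_init,
      ln2_g = rep(1, D), ln2_b = numeric(D),
      Wh = init_dense(D, cfg$n_classes), bh = numeric(cfg$n_classes)
    )
  })
  bn_state <- new.env(parent = emptyenv())
  bn_state$mean <- numeric(D)
  bn_state$var <- rep(1, D)
  bn_state$momentum <- 0.1
  structure(
    list(params = params, config = cfg, bn = bn_state, classes = classes),
    class = "acmix_swin"
  )
}

# Parameters exempt from weight decay and parameters frozen by config.
model_no_decay <- function() {
  c(
    "be1", "ln1_g", "ln1_b", "be2", "bq", "bk", "bv", "bias", "bo", "dw_b",
    "bp", "bn_g", "bn_b", "alpha", "beta", "ln2_g", "ln2_b", "bh"
  )
}

model_frozen <- function(cfg) {
  frozen <- character(0)
  if (!cfg$alpha_trainable) {
    frozen <- c(frozen, "alpha", "Wq", "bq", "Wk", "bk", "bias", "Wo", "bo")
  }
  if (!cfg$beta_trainable) {
    frozen <- c(frozen, "beta", "dw", "dw_b", "Wp", "bp", "bn_g", "bn_b")
  }
  # V feeds both branches; freeze it only if both branches are pinned
  if (!cfg$alpha_trainable && !cfg$beta_trainable) frozen <- c(frozen, "Wv", "bv")
  frozen
}

# Build the forward graph. Returns the logits node plus the input leaf (for
# input-gradient attribution) and intermediate nodes used by the module-level
# operations.
model_graph <- function(model, x, training = FALSE) {
  cfg <- model$config
  P <- leafify(model$params)
  B <- nrow(x)
  L <- cfg$n_tokens
  D <- cfg$embed_dim

  xin <- ad_leaf(x)
  h <- ad_add_bias(ad_matmul(xin, P$We1), P$be1)
  h <- ad_layernorm(h, P$ln1_g, P$ln1_b)
  h <- ad_gelu(h)
  h <- ad_dropout(h, cfg$dropout_embed, training)
  flat <- ad_add_bias(ad_matmul(h, P$We2), P$be2)
  tokens <- ad_to_tokens(flat, L, D)

  q <- ad_add_bias(ad_matmul(tokens, P$Wq), P$bq)
  k <- ad_add_bias(ad_matmul(tokens, P$Wk), P$bk)
  v <- ad_add_bias(ad_matmul(tokens, P$Wv), P$bv)

  att <- ad_window_attention(q, k, v, P$bias, cfg$n_heads, cfg$window_size, B, L)
  att <- ad_add_bias(ad_matmul(att, P$Wo), P$bo)

  conv <- ad_depthwise_conv(v, P$dw, P$dw_b, B, L)
  conv <- ad_add_bias(ad_matmul(conv, P$Wp), P$bp)
  conv <- ad_batchnorm(conv, P$bn_g, P$bn_b, model$bn, training)
  conv <- ad_gelu(conv)

  fused <- ad_add(ad_scalar_mul(att, P$alpha), ad_scalar_mul(conv, P$beta))
  fused <- ad_dropout(fused, cfg$dropout_block, training)
  fused <- ad_layernorm(fused, P$ln2_g, P$ln2_b)

  pooled <- ad_token_mean(fused, B, L)
  pooled <- ad_dropout(pooled, cfg$dropout_head, training)
  logits <- ad_add_bias(ad_matmul(pooled, P$Wh), P$bh)

  list(
    logits = logits, input = xin, leaves = P,
    tokens = tokens, att = att, conv = conv, fused = fused
  )
}

#' Embed gene vectors into tokens
#'
#' Runs the two-layer embedding (LayerNorm, GELU, dropout in training mode)
#' and reshapes the output into `(batch, n_tokens, embed_dim)` tokens.
#'
#' @param model An `acmix_swin` model.
#' @param x Matrix (samples x genes).
#' @param training Enable dropout (default `FALSE`).
#' @return A 3-d array `(batch, n_tokens, embed_dim)`.
#' @export
embed_input <- function(model, x, training = FALSE) {
  cfg <- model$config
  if (ncol(x) != cfg$n_genes) {
    stop(sprintf("input has %d genes; model expects %d", ncol(x), cfg$n_genes), call. = FALSE)
  }
  g <- model_graph(model, x, training)
  tok <- g$tokens$value
  arr <- array(0, dim = c(nrow(x), cfg$n_tokens, cfg$embed_dim))
  for (b in seq_len(nrow(x))) {
    arr[b, , ] <- tok[(b - 1) * cfg$n_tokens + seq_len(cfg$n_tokens), ]
  }
  arr
}

#' Windowed multi-head attention over a token array
#'
#' Standalone attention operator: tokens are projected to Q, K, V, split
#' into contiguous non-overlapping windows, scored per head as
#' `Q K^T / sqrt(d_k)` plus a relative positional bias, row-softmaxed and
#' applied to V; heads are concatenated and output-projected. No
#' cross-window mixing occurs.
#'
#' @param tokens 3-d array `(batch, L, D)`.
#' @param weights List with `Wq, bq, Wk, bk, Wv, bv, Wo, bo` and `bias`
#'   (`n_heads x (2*window - 1)` matrix).
#' @param n_heads Number of attention heads.
#' @param window Window length (must divide L).
#' @return A 3-d array of the same shape.
#' @export
window_attention <- function(tokens, weights, n_heads, window) {
  dims <- dim(tokens)
  B <- dims[1]; L <- dims[2]; D <- dims[3]
  if (L %% window != 0) {
    stop("token count must be divisible by the window length (no padding)", call. = FALSE)
  }
  flat <- matrix(0, B * L, D)
  for (b in seq_len(B)) flat[(b - 1) * L + seq_len(L), ] <- tokens[b, , ]
  q <- sweep(flat %*% weights$Wq, 2, weights$bq, "+")
  k <- sweep(flat %*% weights$Wk, 2, weights$bk, "+")
  v <- sweep(flat %*% weights$Wv, 2, weights$bv, "+")
  node <- ad_window_attention(
    ad_wrap(q), ad_wrap(k), ad_wrap(v), ad_wrap(weights$bias),
    n_heads, window, B, L
  )
  outf <- sweep(node$value %*% weights$Wo, 2, weights$bo, "+")
  out <- array(0, dim = dims)
  for (b in seq_len(B)) out[b, , ] <- outf[(b - 1) * L + seq_len(L), ]
  out
}

#' Convolution branch over a token array
#'
#' Depthwise 1-d convolution along the token axis (same padding), pointwise
#' 1x1 channel mixing, batch normalization and GELU; shape preserved.
#'
#' @param tokens 3-d array `(batch, L, D)`.
#' @param model An `acmix_swin` model (supplies kernel, pointwise weights and
#'   batch-norm state).
#' @param training Use batch statistics and update running ones (default
#'   `FALSE`, which uses running statistics).
#' @return A 3-d array of the same shape.
#' @export
conv_branch <- function(tokens, model, training = FALSE) {
  dims <- dim(tokens)
  B <- dims[1]; L <- dims[2]; D <- dims[3]
  P <- model$params
  flat <- matrix(0, B * L, D)
  for (b in seq_len(B)) flat[(b - 1) * L + seq_len(L), ] <- tokens[b, , ]
  node <- ad_depthwise_conv(ad_wrap(flat), ad_wrap(P$dw), ad_wrap(P$dw_b), B, L)
  node <- ad_add_bias(ad_matmul(node, ad_wrap(P$Wp)), ad_wrap(P$bp))
  node <- ad_batchnorm(node, ad_wrap(P$bn_g), ad_wrap(P$bn_b), model$bn, training)
  node <- ad_gelu(node)
  out <- array(0, dim = dims)
  for (b in seq_len(B)) out[b, , ] <- node$value[(b - 1) * L + seq_len(L), ]
  out
}

#' Fuse the attention and convolution branches
#'
#' Elementwise `alpha * att + beta * conv`.
#'
#' @param att,conv Arrays of identical shape.
#' @param alpha,beta Scalar fusion weights.
#' @return Array of the same shape.
#' @export
fuse_branches <- function(att, conv, alpha, beta) {
  if (!identical(dim(att), dim(conv))) {
    stop("attention and convolution branch outputs must have identical shapes", call. = FALSE)
  }
  alpha * att + beta * conv
}

#' Forward pass: class logits
#'
#' @param model An `acmix_swin` model.
#' @param x Matrix (samples x genes).
#' @param training Enable dropout / batch statistics (default `FALSE`).
#' @return Matrix (samples x n_classes) of logits.
#' @export
model_forward <- function(model, x, training = FALSE) {
  if (ncol(x) != model$config$n_genes) {
    stop(sprintf(
      "input has %d genes; model expects %d",
      ncol(x), model$config$n_genes
    ), call. = FALSE)
  }
  model_graph(model, x, training)$logits$value
}

#' Predict class labels
#'
#' @param object An `acmix_swin` model.
#' @param x Matrix (samples x genes) or genes x samples expression matrix
#'   with gene ids matching the training orientation handled by the caller.
#' @param ... Unused.
#' @return Factor of predicted class labels (or column indices if the model
#'   stores no class names).
#' @export
predict.acmix_swin <- function(object, x, ...) {
  logits <- model_forward(object, x, training = FALSE)
  idx <- max.col(logits, ties.method = "first")
  if (!is.null(object$classes)) {
    factor(object$classes[idx], levels = object$classes)
  } else {
    idx
  }
}

#' @export
print.acmix_swin <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    paste0(
      "<acmix_swin> %d genes -> %d tokens x %d dims, %d heads, window %d -> %d classes\n",
      "  fusion weights: alpha (attention) = %.3f, beta (convolution) = %.3f\n",
      "  parameters: %s\n"
    ),
    cfg$n_genes, cfg$n_tokens, cfg$embed_dim, cfg$n_heads, cfg$window_size,
    cfg$n_classes, x$params$alpha, x$params$beta, format(n_par, big.mark = ",")
  ))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Serializes the configuration, all parameters (including the fusion
#' scalars), the batch-norm running statistics and the class labels.
#'
#' @param model An `acmix_swin` model.
#' @param path Checkpoint file path.
#' @return `path` invisibly for `save_model()`; the restored model for
#'   `load_model()`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(
    config = model$config,
    params = model$params,
    bn = list(mean = model$bn$mean, var = model$bn$var, momentum = model$bn$momentum),
    classes = model$classes
  ), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- acmix_swin(obj$config, classes = obj$classes)
  model$params <- obj$params
  model$bn$mean <- obj$bn$mean
  model$bn$var <- obj$bn$var
  model$bn$momentum <- obj$bn$momentum
  model
}

#' Fusion weights of a trained model
#'
#' @param model An `acmix_swin` model.
#' @return Named numeric vector with `alpha` (attention) and `beta`
#'   (convolution).
#' @export
fusion_weights <- function(model) {
  c(alpha = as.numeric(model$params$alpha), beta = as.numeric(model$params$beta))
}
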