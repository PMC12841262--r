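# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Each node is an environment holding a value, its parents, and a backward
# closure mapping the node's output gradient to parent gradients. Graphs are
# built per forward pass; ad_backward() topologically sorts and accumulates.
# Only what the package's networks need is implemented; shapes are matrices
# (samples x features) with token tensors stored row-major as (B*L) x D.

ad_env <- new.env(parent = emptyenv())
ad_env$id <- 0L

ad_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  ad_env$id <- ad_env$id + 1L
  e$id <- ad_env$id
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$requires <- length(parents) > 0 &&
    any(vapply(parents, function(p) p$requires, logical(1)))
  class(e) <- "ad_node"
  e
}

# A leaf that participates in differentiation (parameter or input).
ad_leaf <- function(value) {
  e <- ad_node(value)
  e$requires <- TRUE
  e
}

# Wrap plain numerics as constant nodes.
ad_wrap <- function(x) {
  if (inherits(x, "ad_node")) return(x)
  e <- ad_node(x)
  e$requires <- FALSE
  e
}

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

ad_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Reverse pass from a scalar root. Fills $grad on every requiring node.
ad_backward <- function(root, seed = 1) {
  order <- vector("list", 256)
  n <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  # iterative DFS post-order (graphs can be a few hundred nodes deep)
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$requires && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n <- n + 1L
      if (n > length(order)) order <- c(order, vector("list", length(order)))
      order[[n]] <- node
    }
  }
  root$grad <- array(seed, dim = dim(root$value) %||% length(root$value))
  for (i in seq(n, 1L)) {
    node <- order[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) {
      node$backward(node)
    }
  }
  invisible(root)
}

## ---- primitive operations -------------------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  out <- ad_node(a$value %*% b$value, list(a, b), function(node) {
    g <- node$grad
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, t(a$value) %*% g)
  })
  out
}

ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_node(a$value + b$value, list(a, b), function(node) {
    ad_accum(a, node$grad)
    ad_accum(b, node$grad)
  })
}

# Add a length-d row vector to every row of an n x d matrix (bias add).
ad_add_bias <- function(a, bias) {
  a <- ad_wrap(a); bias <- ad_wrap(bias)
  ad_node(sweep(a$value, 2, bias$value, "+"), list(a, bias), function(node) {
    ad_accum(a, node$grad)
    ad_accum(bias, colSums(node$grad))
  })
}

ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_node(a$value * b$value, list(a, b), function(node) {
    ad_accum(a, node$grad * b$value)
    ad_accum(b, node$grad * a$value)
  })
}

# Multiply an array node by a learnable scalar node (1-element).
ad_scalar_mul <- function(x, s) {
  x <- ad_wrap(x); s <- ad_wrap(s)
  ad_node(x$value * as.numeric(s$value), list(x, s), function(node) {
    ad_accum(x, node$grad * as.numeric(s$value))
    ad_accum(s, sum(node$grad * x$value))
  })
}

ad_gelu <- function(x) {
  x <- ad_wrap(x)
  v <- x$value
  phi <- stats::pnorm(v)
  ad_node(v * phi, list(x), function(node) {
    ad_accum(x, node$grad * (phi + v * stats::dnorm(v)))
  })
}

ad_tanh <- function(x) {
  x <- ad_wrap(x)
  t <- tanh(x$value)
  ad_node(t, list(x), function(node) ad_accum(x, node$grad * (1 - t^2)))
}

ad_sigmoid <- function(x) {
  x <- ad_wrap(x)
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(node) ad_accum(x, node$grad * s * (1 - s)))
}

ad_relu <- function(x) {
  x <- ad_wrap(x)
  mask <- x$value > 0
  ad_node(x$value * mask, list(x), function(node) ad_accum(x, node$grad * mask))
}

# Layer normalization across columns of each row, with affine gamma/beta.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- ad_wrap(x); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  v <- x$value
  d <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  varr <- rowMeans(xc^2)
  inv <- 1 / sqrt(varr + eps)
  xhat <- xc * inv
  out_v <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  ad_node(out_v, list(x, gamma, beta), function(node) {
    g <- node$grad
    ad_accum(gamma, colSums(g * xhat))
    ad_accum(beta, colSums(g))
    gx <- sweep(g, 2, gamma$value, "*")
    # standard layernorm backward per row
    gsum <- rowSums(gx)
    gdot <- rowSums(gx * xhat)
    ad_accum(x, inv * (gx - gsum / d - xhat * gdot / d))
  })
}

# Batch normalization across rows (per column), with running statistics.
# `state` is an environment with $mean, $var, $momentum updated in training.
ad_batchnorm <- function(x, gamma, beta, state, training, eps = 1e-5) {
  x <- ad_wrap(x); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  v <- x$value
  n <- nrow(v)
  if (training && n > 1) {
    mu <- colMeans(v)
    xc <- sweep(v, 2, mu)
    varr <- colMeans(xc^2)
    state$mean <- (1 - state$momentum) * state$mean + state$momentum * mu
    state$var <- (1 - state$momentum) * state$var + state$momentum * varr
    inv <- 1 / sqrt(varr + eps)
    xhat <- sweep(xc, 2, inv, "*")
    out_v <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
    ad_node(out_v, list(x, gamma, beta), function(node) {
      g <- node$grad
      ad_accum(gamma, colSums(g * xhat))
      ad_accum(beta, colSums(g))
      gx <- sweep(g, 2, gamma$value, "*")
      gsum <- colSums(gx)
      gdot <- colSums(gx * xhat)
      term <- sweep(gx, 2, gsum / n) - sweep(xhat, 2, gdot / n, "*")
      ad_accum(x, sweep(term, 2, inv, "*"))
    })
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- sweep(sweep(v, 2, state$mean), 2, inv, "*")
    out_v <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
    ad_node(out_v, list(x, gamma, beta), function(node) {
      g <- node$grad
      ad_accum(gamma, colSums(g * xhat))
      ad_accum(beta, colSums(g))
      ad_accum(x, sweep(sweep(g, 2, gamma$value, "*"), 2, inv, "*"))
    })
  }
}

# Inverted dropout; identity when not training. Draws from the current RNG.
ad_dropout <- function(x, p, training) {
  x <- ad_wrap(x)
  if (!training || p <= 0) return(x)
  mask <- (array(stats::runif(length(x$value)), dim = dim(x$value)) >= p) / (1 - p)
  ad_node(x$value * mask, list(x), function(node) ad_accum(x, node$grad * mask))
}

# Reshape an n x (L*D) matrix into token rows ((n*L) x D, sample-major).
ad_to_tokens <- function(x, L, D) {
  x <- ad_wrap(x)
  n <- nrow(x$value)
  # row (b-1)*L + l takes columns ((l-1)*D + 1) : (l*D) of row b
  idx <- matrix(0L, n * L, D)
  for (l in seq_len(L)) {
    rows <- (seq_len(n) - 1L) * L + l
    idx[rows, ] <- matrix(
      rep((seq_len(n) - 1L), D) + n * rep(((l - 1L) * D) + seq_len(D) - 1L, each = n),
      nrow = n
    ) + 1L
  }
  v <- matrix(x$value[idx], nrow = n * L)
  ad_node(v, list(x), function(node) {
    g <- matrix(0, n, L * D)
    g[idx] <- node$grad
    ad_accum(x, g)
  })
}

# Inverse of ad_to_tokens: (B*L) x D token rows -> B x (L*D) flat rows.
ad_from_tokens <- function(x, B, L) {
  x <- ad_wrap(x)
  D <- ncol(x$value)
  out <- matrix(0, B, L * D)
  for (l in seq_len(L)) {
    out[, (l - 1) * D + seq_len(D)] <- x$value[(seq_len(B) - 1) * L + l, , drop = FALSE]
  }
  ad_node(out, list(x), function(node) {
    g <- matrix(0, B * L, D)
    for (l in seq_len(L)) {
      g[(seq_len(B) - 1) * L + l, ] <- node$grad[, (l - 1) * D + seq_len(D), drop = FALSE]
    }
    ad_accum(x, g)
  })
}

# Mean over the L token rows of each sample: (B*L) x D -> B x D.
ad_token_mean <- function(x, B, L) {
  x <- ad_wrap(x)
  grp <- rep(seq_len(B), each = L)
  v <- rowsum(x$value, grp) / L
  ad_node(v, list(x), function(node) {
    ad_accum(x, node$grad[grp, , drop = FALSE] / L)
  })
}

# Select (possibly repeated) rows; backward scatter-adds duplicates.
ad_rows <- function(x, idx) {
  x <- ad_wrap(x)
  ad_node(x$value[idx, , drop = FALSE], list(x), function(node) {
    g <- rowsum(node$grad, idx)
    full <- array(0, dim = dim(x$value))
    full[as.integer(rownames(g)), ] <- g
    ad_accum(x, full)
  })
}

# Select columns (with gradient scatter).
ad_cols <- function(x, cols) {
  x <- ad_wrap(x)
  ad_node(x$value[, cols, drop = FALSE], list(x), function(node) {
    g <- array(0, dim = dim(x$value))
    g[, cols] <- node$grad
    ad_accum(x, g)
  })
}

ad_cbind2 <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  na <- ncol(a$value)
  ad_node(cbind(a$value, b$value), list(a, b), function(node) {
    ad_accum(a, node$grad[, seq_len(na), drop = FALSE])
    ad_accum(b, node$grad[, -seq_len(na), drop = FALSE])
  })
}

## ---- fused losses ---------------------------------------------------------

# Mean (or sum) soft-target cross-entropy with log-softmax, fused for
# numerical stability. `targets` is a constant matrix of row-distributions.
ad_softmax_xent <- function(logits, targets, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  logits <- ad_wrap(logits)
  z <- logits$value
  zmax <- apply(z, 1, max)
  ez <- exp(z - zmax)
  p <- ez / rowSums(ez)
  logp <- (z - zmax) - log(rowSums(ez))
  per <- -rowSums(targets * logp)
  scale <- if (reduce == "mean") nrow(z) else 1
  ad_node(sum(per) / scale, list(logits), function(node) {
    ad_accum(logits, as.numeric(node$grad) * (p - targets) / scale)
  })
}

# Sum of selected logit columns (one class column per row, or a single
# class for all rows) — used for class-directed attribution.
ad_logit_sum <- function(logits, class_idx) {
  logits <- ad_wrap(logits)
  n <- nrow(logits$value)
  sel <- cbind(seq_len(n), rep_len(class_idx, n))
  ad_node(sum(logits$value[sel]), list(logits), function(node) {
    g <- array(0, dim = dim(logits$value))
    g[sel] <- as.numeric(node$grad)
    ad_accum(logits, g)
  })
}

ad_mean_all <- function(x) {
  x <- ad_wrap(x)
  n <- length(x$value)
  ad_node(sum(x$value) / n, list(x), function(node) {
    ad_accum(x, array(as.numeric(node$grad) / n, dim = dim(x$value) %||% n))
  })
}

## ---- windowed multi-head attention ---------------------------------------

# Relative-position bias matrix (W x W) from a (2W-1) table for one head:
# entry (i, j) is table[j - i + W].
rel_bias_matrix <- function(tab, W) {
  off <- outer(seq_len(W), seq_len(W), function(i, j) j - i) + W
  matrix(tab[off], W, W)
}

# Swin-style windowed multi-head attention over token rows.
# q, k, v: (B*L) x D nodes; bias: n_heads x (2W-1) node. Tokens are split
# into contiguous non-overlapping windows of length `window`; attention is
# computed per window and head, heads are concatenated (output projection is
# applied by the caller). No cross-window mixing.
ad_window_attention <- function(q, k, v, bias, n_heads, window, B, L) {
  q <- ad_wrap(q); k <- ad_wrap(k); v <- ad_wrap(v); bias <- ad_wrap(bias)
  D <- ncol(q$value)
  stopifnot(D %% n_heads == 0, L %% window == 0)
  dk <- D %/% n_heads
  W <- window
  nblk <- B * (L %/% W) # total windows across the batch
  blk_of_row <- rep(seq_len(nblk), each = W)
  pos_in_blk <- rep(seq_len(W), times = nblk)

  out_v <- matrix(0, B * L, D)
  cache <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    Qh <- q$value[, cols, drop = FALSE]
    Kh <- k$value[, cols, drop = FALSE]
    Vh <- v$value[, cols, drop = FALSE]
    Bh <- rel_bias_matrix(bias$value[h, ], W)
    # scores: for each row r, against rows of its own window
    S <- matrix(0, B * L, W)
    for (j in seq_len(W)) {
      krows <- (blk_of_row - 1L) * W + j
      S[, j] <- rowSums(Qh * Kh[krows, , drop = FALSE]) / sqrt(dk)
    }
    S <- S + Bh[pos_in_blk, , drop = FALSE]
    S <- S - apply(S, 1, max)
    A <- exp(S)
    A <- A / rowSums(A)
    Oh <- matrix(0, B * L, dk)
    for (j in seq_len(W)) {
      krows <- (blk_of_row - 1L) * W + j
      Oh <- Oh + A[, j] * Vh[krows, , drop = FALSE]
    }
    out_v[, cols] <- Oh
    cache[[h]] <- list(A = A, cols = cols)
  }

  ad_node(out_v, list(q, k, v, bias), function(node) {
    G <- node$grad
    gq <- matrix(0, B * L, D)
    gk <- matrix(0, B * L, D)
    gv <- matrix(0, B * L, D)
    gbias <- matrix(0, n_heads, 2 * W - 1)
    for (h in seq_len(n_heads)) {
      cols <- cache[[h]]$cols
      A <- cache[[h]]$A
      Gh <- G[, cols, drop = FALSE]
      Qh <- q$value[, cols, drop = FALSE]
      Kh <- k$value[, cols, drop = FALSE]
      Vh <- v$value[, cols, drop = FALSE]
      # dV and dA (accumulate per window with rowsum: duplicated row
      # indices must sum, not overwrite)
      dA <- matrix(0, B * L, W)
      for (j in seq_len(W)) {
        krows <- (blk_of_row - 1L) * W + j
        dA[, j] <- rowSums(Gh * Vh[krows, , drop = FALSE])
        vrows <- (seq_len(nblk) - 1L) * W + j
        gv[vrows, cols] <- gv[vrows, cols] + rowsum(A[, j] * Gh, blk_of_row)
      }
      # softmax backward: dS = A * (dA - rowSums(dA * A))
      dS <- A * (dA - rowSums(dA * A))
      # bias gradient: accumulate dS by relative offset
      for (j in seq_len(W)) {
        off_idx <- j - pos_in_blk + W # in 1..2W-1
        gbias[h, ] <- gbias[h, ] +
          vapply(seq_len(2 * W - 1), function(o) sum(dS[off_idx == o, j]), numeric(1))
      }
      # dQ, dK
      for (j in seq_len(W)) {
        krows <- (blk_of_row - 1L) * W + j
        gq[, cols] <- gq[, cols] + dS[, j] * Kh[krows, , drop = FALSE] / sqrt(dk)
        vrows <- (seq_len(nblk) - 1L) * W + j
        gk[vrows, cols] <- gk[vrows, cols] + rowsum(dS[, j] * Qh, blk_of_row) / sqrt(dk)
      }
    }
    ad_accum(q, gq)
    ad_accum(k, gk)
    ad_accum(v, gv)
    ad_accum(bias, gbias)
  })
}

## ---- 1-D convolutions along the token axis --------------------------------

# Depthwise conv: kernel is K x D (one length-K filter per channel), same
# (zero) padding along the token axis within each sample.
ad_depthwise_conv <- function(x, kernel, bias, B, L) {
  x <- ad_wrap(x); kernel <- ad_wrap(kernel); bias <- ad_wrap(bias)
  K <- nrow(kernel$value)
  D <- ncol(x$value)
  half <- (K - 1) %/% 2
  pos <- rep(seq_len(L), times = B)
  shift_rows <- function(t) {
    # row index of token (pos + t) in same sample, NA when out of range
    tgt <- pos + t
    ok <- tgt >= 1 & tgt <= L
    rows <- seq_len(B * L) + t
    rows[!ok] <- NA_integer_
    rows
  }
  v <- matrix(0, B * L, D)
  taps <- (-half):(K - 1 - half)
  for (ti in seq_along(taps)) {
    rows <- shift_rows(taps[ti])
    ok <- !is.na(rows)
    v[ok, ] <- v[ok, ] + sweep(x$value[rows[ok], , drop = FALSE], 2, kernel$value[ti, ], "*")
  }
  v <- sweep(v, 2, bias$value, "+")
  ad_node(v, list(x, kernel, bias), function(node) {
    G <- node$grad
    gx <- matrix(0, B * L, D)
    gk <- matrix(0, K, D)
    for (ti in seq_along(taps)) {
      rows <- shift_rows(taps[ti])
      ok <- !is.na(rows)
      gk[ti, ] <- colSums(G[ok, , drop = FALSE] * x$value[rows[ok], , drop = FALSE])
      gx[rows[ok], ] <- gx[rows[ok], ] +
        sweep(G[ok, , drop = FALSE], 2, kernel$value[ti, ], "*")
    }
    ad_accum(x, gx)
    ad_accum(kernel, gk)
    ad_accum(bias, colSums(G))
  })
}

# General 1-D convolution along a length-L axis: input (B*L) x Cin,
# kernel K x Cin x Cout (array), bias length Cout; same padding.
ad_conv1d <- function(x, kernel, bias, B, L) {
  x <- ad_wrap(x); kernel <- ad_wrap(kernel); bias <- ad_wrap(bias)
  kd <- dim(kernel$value)
  K <- kd[1]; cin <- kd[2]; cout <- kd[3]
  half <- (K - 1) %/% 2
  pos <- rep(seq_len(L), times = B)
  taps <- (-half):(K - 1 - half)
  v <- matrix(0, B * L, cout)
  for (ti in seq_along(taps)) {
    tgt <- pos + taps[ti]
    ok <- tgt >= 1 & tgt <= L
    rows <- seq_len(B * L) + taps[ti]
    Wt <- matrix(kernel$value[ti, , ], cin, cout)
    v[ok, ] <- v[ok, ] + x$value[rows[ok], , drop = FALSE] %*% Wt
  }
  v <- sweep(v, 2, bias$value, "+")
  ad_node(v, list(x, kernel, bias), function(node) {
    G <- node$grad
    gx <- matrix(0, B * L, cin)
    gk <- array(0, dim = kd)
    for (ti in seq_along(taps)) {
      tgt <- pos + taps[ti]
      ok <- tgt >= 1 & tgt <= L
      rows <- seq_len(B * L) + taps[ti]
      Wt <- matrix(kernel$value[ti, , ], cin, cout)
      gk[ti, , ] <- t(x$value[rows[ok], , drop = FALSE]) %*% G[ok, , drop = FALSE]
      gx[rows[ok], ] <- gx[rows[ok], ] + G[ok, , drop = FALSE] %*% t(Wt)
    }
    ad_accum(x, gx)
    ad_accum(kernel, gk)
    ad_accum(bias, colSums(G))
  })
}

# Mean-pool non-overlapping groups of `stride` tokens: (B*L) x C -> (B*L2) x C.
ad_token_pool <- function(x, B, L, stride) {
  x <- ad_wrap(x)
  L2 <- L %/% stride
  keep <- rep(seq_len(L2 * stride), times = B) +
    rep((seq_len(B) - 1L) * L, each = L2 * stride)
  grp <- rep(seq_len(B * L2), each = stride)
  v <- rowsum(x$value[keep, , drop = FALSE], grp) / stride
  ad_node(v, list(x), function(node) {
    g <- matrix(0, nrow(x$value), ncol(x$value))
    g[keep, ] <- node$grad[grp, , drop = FALSE] / stride
    ad_accum(x, g)
  })
}
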