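# Parameter initialization, the AdamW optimizer and gradient clipping shared
# by the classifier, the WGAN-GP networks and the deep baselines.

init_dense <- function(n_in, n_out) {
  # He/Kaiming-style normal init, suitable for GELU networks
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

# Orthogonal init: with spectral normalization this leaves layers
# near-isometric, so a unit input-gradient norm (the gradient-penalty
# optimum) is reachable instead of being crushed by mismatched singular
# directions.
init_orthogonal <- function(n_in, n_out) {
  a <- matrix(stats::rnorm(n_in * n_out), n_in, n_out)
  s <- svd(a)
  s$u %*% t(s$v)
}

init_zeros <- function(...) {
  d <- c(...)
  if (length(d) == 1) numeric(d) else array(0, dim = d)
}

# Turn a named list of parameter arrays into leaf nodes for one forward pass.
leafify <- function(params) lapply(params, ad_leaf)

# Collect gradients from leaf nodes back into a named list (zeros if unused).
collect_grads <- function(leaves, params) {
  out <- params
  for (nm in names(params)) {
    g <- leaves[[nm]]$grad
    out[[nm]] <- if (is.null(g)) array(0, dim = dim(params[[nm]]) %||% length(params[[nm]])) else g
  }
  out
}

# Scale all gradients so the global L2 norm is at most `max_norm`.
clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm && total > 0) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  list(grads = grads, norm = total)
}

adamw_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, wd = weight_decay,
    t = 0,
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  )
}

# One decoupled-weight-decay Adam step. `skip` names parameters frozen for
# this run (ablation variants); `no_decay` names parameters exempt from decay
# (biases, norms, scalars).
adamw_step <- function(params, grads, opt, lr = NULL, skip = character(0),
                       no_decay = character(0)) {
  lr <- lr %||% opt$lr
  opt$t <- opt$t + 1
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + opt$eps)
    if (opt$wd > 0 && !(nm %in% no_decay)) {
      upd <- upd + opt$wd * params[[nm]]
    }
    newp <- params[[nm]] - lr * upd
    if (is.null(dim(params[[nm]]))) newp <- as.numeric(newp)
    params[[nm]] <- newp
  }
  list(params = params, opt = opt)
}
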