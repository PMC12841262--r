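#' WGAN-GP configuration
#'
#' Defaults follow the training setup used throughout the package: a
#' two-layer generator (hidden 128, GELU, linear output), a three-layer
#' spectral-normalized critic, gradient-penalty coefficient 10, five critic
#' updates per generator update, and Adam with learning rate 1e-4,
#' beta1 = 0, beta2 = 0.9.
#'
#' @param noise_dim Latent noise dimension (default 64).
#' @param gen_hidden Generator hidden width (default 128).
#' @param critic_layers Number of critic layers (default 3; widths 256, 128, 1).
#' @param lambda_gp Gradient-penalty coefficient (default 10).
#' @param n_critic Critic updates per generator update (default 5).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param adam_beta1,adam_beta2 Adam moment coefficients (defaults 0.0, 0.9).
#' @param epochs Training epochs (default 600).
#' @param batch_size Batch size; `NULL` uses the class size.
#' @param seed Integer seed.
#' @return A `wgan_config` list.
#' @export
wgan_config <- function(noise_dim = 64, gen_hidden = 128, critic_layers = 3,
                        lambda_gp = 10, n_critic = 5, learning_rate = 1e-4,
                        adam_beta1 = 0.0, adam_beta2 = 0.9, epochs = 600,
                        batch_size = NULL, seed = 1) {
  cfg <- list(
    noise_dim = noise_dim, gen_hidden = gen_hidden,
    critic_layers = critic_layers, lambda_gp = lambda_gp,
    n_critic = n_critic, learning_rate = learning_rate,
    adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
    epochs = epochs, batch_size = batch_size, seed = seed
  )
  stopifnot(cfg$lambda_gp >= 0, cfg$n_critic >= 1, cfg$epochs >= 1)
  structure(cfg, class = "wgan_config")
}

## ---- critics --------------------------------------------------------------

#' Linear critic
#'
#' A critic scoring `x %*% w + b`; its input gradient is `w` everywhere, so
#' the gradient penalty has the closed form `lambda * (||w|| - 1)^2`. Used as
#' an analytic oracle for [gradient_penalty()].
#'
#' @param w Weight vector (length = gene count).
#' @param b Scalar offset.
#' @return A `linear_critic` object usable with [gradient_penalty()].
#' @export
linear_critic <- function(w, b = 0) {
  structure(list(w = as.numeric(w), b = b), class = c("linear_critic", "critic"))
}

critic_score <- function(critic, x) UseMethod("critic_score")
critic_input_grad <- function(critic, x) UseMethod("critic_input_grad")

#' @export
critic_score.linear_critic <- function(critic, x) {
  as.numeric(x %*% critic$w + critic$b)
}

#' @export
critic_input_grad.linear_critic <- function(critic, x) {
  matrix(critic$w, nrow(x), length(critic$w), byrow = TRUE)
}

# Spectral normalization: one power iteration per call; u persists in the
# critic state. Returns the normalized weight and the pieces the parameter
# gradient needs.
spectral_normalize <- function(W, u) {
  v <- as.numeric(t(W) %*% u)
  v <- v / max(sqrt(sum(v^2)), 1e-12)
  u_new <- as.numeric(W %*% v)
  u_new <- u_new / max(sqrt(sum(u_new^2)), 1e-12)
  sigma <- as.numeric(t(u_new) %*% W %*% v)
  list(Wbar = W / sigma, sigma = sigma, u = u_new, v = v)
}

# Map a gradient wrt the normalized weight back to the raw weight
# (u, v treated as constants, the usual convention).
spectral_grad <- function(gWbar, Wbar, sigma, u, v) {
  (gWbar - sum(gWbar * Wbar) * (u %o% v)) / sigma
}

new_wgan_critic <- function(n_genes, widths = c(256, 128)) {
  p <- list(
    W1 = init_orthogonal(n_genes, widths[1]), b1 = numeric(widths[1]),
    W2 = init_orthogonal(widths[1], widths[2]), b2 = numeric(widths[2]),
    W3 = init_orthogonal(widths[2], 1), b3 = numeric(1)
  )
  # power-iteration vectors: u has length nrow(W)
  state <- list(
    u1 = stats::rnorm(n_genes),
    u2 = stats::rnorm(widths[1]),
    u3 = stats::rnorm(widths[2])
  )
  structure(list(params = p, sn = state, slope = 0.2),
    class = c("wgan_critic", "critic")
  )
}

# Forward pass caching pre-activations and normalized weights.
critic_forward <- function(critic, x, update_power = FALSE) {
  p <- critic$params
  s1 <- spectral_normalize(p$W1, critic$sn$u1)
  s2 <- spectral_normalize(p$W2, critic$sn$u2)
  s3 <- spectral_normalize(p$W3, critic$sn$u3)
  lrelu <- function(z, a) ifelse(z > 0, z, a * z)
  z1 <- sweep(x %*% s1$Wbar, 2, p$b1, "+")
  a1 <- lrelu(z1, critic$slope)
  z2 <- sweep(a1 %*% s2$Wbar, 2, p$b2, "+")
  a2 <- lrelu(z2, critic$slope)
  score <- as.numeric(a2 %*% s3$Wbar + p$b3)
  list(
    score = score, x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
    s1 = s1, s2 = s2, s3 = s3
  )
}

#' @export
critic_score.wgan_critic <- function(critic, x) {
  critic_forward(critic, x)$score
}

#' @export
critic_input_grad.wgan_critic <- function(critic, x) {
  fw <- critic_forward(critic, x)
  critic_input_grad_cached(critic, fw)
}

critic_input_grad_cached <- function(critic, fw) {
  a <- critic$slope
  d2 <- ifelse(fw$z2 > 0, 1, a) # B x h2
  d1 <- ifelse(fw$z1 > 0, 1, a) # B x h1
  u2 <- d2 * matrix(fw$s3$Wbar[, 1], nrow(d2), ncol(d2), byrow = TRUE)
  u1 <- d1 * (u2 %*% t(fw$s2$Wbar))
  u1 %*% t(fw$s1$Wbar) # B x n_genes
}

#' Gradient penalty
#'
#' The WGAN-GP penalty `lambda * mean[(||grad_xhat critic(xhat)||_2 - 1)^2]`
#' over interpolates `xhat = eps * x_real + (1 - eps) * x_fake` with
#' `eps ~ Uniform(0, 1)` drawn per pair.
#'
#' @param critic A critic object ([linear_critic()] or an internal WGAN
#'   critic), or a list with functions `score(x)` and `grad(x)`.
#' @param real_batch,fake_batch Matrices (samples x genes) of equal width.
#' @param lambda_gp Penalty coefficient.
#' @param seed Seed for the interpolation draw.
#' @return The scalar penalty (>= 0).
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch, lambda_gp = 10, seed = 1) {
  real_batch <- as.matrix(real_batch)
  fake_batch <- as.matrix(fake_batch)
  if (ncol(real_batch) != ncol(fake_batch)) {
    stop("real and fake batches must have the same number of genes", call. = FALSE)
  }
  n <- min(nrow(real_batch), nrow(fake_batch))
  with_seed(seed, {
    eps <- stats::runif(n)
  })
  xhat <- eps * real_batch[seq_len(n), , drop = FALSE] +
    (1 - eps) * fake_batch[seq_len(n), , drop = FALSE]
  g <- if (inherits(critic, "critic")) {
    critic_input_grad(critic, xhat)
  } else if (is.list(critic) && is.function(critic$grad)) {
    critic$grad(xhat)
  } else {
    stop("unsupported critic object", call. = FALSE)
  }
  norms <- sqrt(rowSums(g^2))
  lambda_gp * mean((norms - 1)^2)
}

# Penalty + parameter gradients for the internal critic, derived by hand.
# With a LeakyReLU critic the activation second derivative is zero almost
# everywhere, so only the direct weight dependencies of the input gradient
# contribute (matching reverse-over-reverse autodiff a.e.). Biases receive no
# penalty gradient for the same reason.
gp_with_grads <- function(critic, xhat, lambda_gp) {
  fw <- critic_forward(critic, xhat)
  a <- critic$slope
  n <- nrow(xhat)
  d1 <- ifelse(fw$z1 > 0, 1, a)
  d2 <- ifelse(fw$z2 > 0, 1, a)
  W1b <- fw$s1$Wbar; W2b <- fw$s2$Wbar; w3b <- fw$s3$Wbar[, 1]
  U2 <- d2 * matrix(w3b, n, length(w3b), byrow = TRUE) # B x h2
  U1 <- d1 * (U2 %*% t(W2b)) # B x h1
  G <- U1 %*% t(W1b) # B x genes
  norms <- sqrt(pmax(rowSums(G^2), 1e-12))
  penalty <- lambda_gp * mean((norms - 1)^2)
  r <- (2 * lambda_gp / n) * (norms - 1) / norms * G # dP/dG
  S1 <- d1 * (r %*% W1b) # B x h1
  S2 <- d2 * (S1 %*% W2b) # B x h2
  gW1b <- t(r) %*% U1 # genes x h1
  gW2b <- t(S1) %*% U2 # h1 x h2
  gw3b <- colSums(S2)
  list(
    penalty = penalty,
    gW1 = spectral_grad(gW1b, W1b, fw$s1$sigma, fw$s1$u, fw$s1$v),
    gW2 = spectral_grad(gW2b, W2b, fw$s2$sigma, fw$s2$u, fw$s2$v),
    gW3 = spectral_grad(matrix(gw3b, ncol = 1), fw$s3$Wbar, fw$s3$sigma, fw$s3$u, fw$s3$v)
  )
}

# Backprop of mean critic score wrt parameters (standard first-order pass).
# `sign` +1/-1 weights real/fake contributions; returns grads wrt raw weights.
critic_score_grads <- function(critic, fw, coef) {
  a <- critic$slope
  n <- nrow(fw$x)
  d1 <- ifelse(fw$z1 > 0, 1, a)
  d2 <- ifelse(fw$z2 > 0, 1, a)
  # dL/dscore_i = coef / n
  gs <- rep(coef / n, n)
  ga2 <- gs %o% fw$s3$Wbar[, 1]
  gz2 <- ga2 * d2
  ga1 <- gz2 %*% t(fw$s2$Wbar)
  gz1 <- ga1 * d1
  list(
    gW1 = spectral_grad(t(fw$x) %*% gz1, fw$s1$Wbar, fw$s1$sigma, fw$s1$u, fw$s1$v),
    gb1 = colSums(gz1),
    gW2 = spectral_grad(t(fw$a1) %*% gz2, fw$s2$Wbar, fw$s2$sigma, fw$s2$u, fw$s2$v),
    gb2 = colSums(gz2),
    gW3 = spectral_grad(t(fw$a2) %*% matrix(gs, ncol = 1), fw$s3$Wbar, fw$s3$sigma, fw$s3$u, fw$s3$v),
    gb3 = sum(gs)
  )
}

## ---- generator ------------------------------------------------------------

# Output layer initialized small so early fakes sit near the center of the
# (standardized) data; keeps the adversarial race from diverging before the
# critic's slope builds up.
new_wgan_generator <- function(noise_dim, hidden, n_genes, out_scale = 0.1) {
  list(
    W1 = init_dense(noise_dim, hidden), b1 = numeric(hidden),
    W2 = out_scale * init_dense(hidden, n_genes), b2 = numeric(n_genes)
  )
}

generator_forward <- function(gp, z) {
  z1 <- sweep(z %*% gp$W1, 2, gp$b1, "+")
  h <- z1 * stats::pnorm(z1) # GELU
  x <- sweep(h %*% gp$W2, 2, gp$b2, "+")
  list(x = x, z = z, z1 = z1, h = h)
}

generator_backward <- function(gp, fw, gx) {
  gh <- gx %*% t(gp$W2)
  dgelu <- stats::pnorm(fw$z1) + fw$z1 * stats::dnorm(fw$z1)
  gz1 <- gh * dgelu
  list(
    gW1 = t(fw$z) %*% gz1, gb1 = colSums(gz1),
    gW2 = t(fw$h) %*% gx, gb2 = colSums(gx)
  )
}

#' Train a WGAN-GP on one class's expression profiles
#'
#' Adversarially trains a generator of synthetic expression vectors for a
#' single phenotype class. The generator has two fully connected layers
#' (hidden 128, GELU, linear output); the critic is a three-layer
#' spectral-normalized network scored with the Wasserstein objective plus the
#' gradient penalty. The critic takes `n_critic` updates per generator
#' update. Per-epoch diagnostics are recorded.
#'
#' @param class_samples Matrix (samples x genes) of one class's real profiles
#'   (at least 2 rows).
#' @param cfg A [wgan_config()].
#' @return A `wgan_fit` list: `generate(n, seed)` draws n synthetic samples;
#'   `diagnostics` is a per-epoch tibble (`epoch`, `generator_loss`,
#'   `critic_loss`, `wasserstein_estimate`, `gradient_penalty_value`,
#'   `mean_real_score`, `mean_fake_score`).
#' @export
train_wgan_gp <- function(class_samples, cfg = wgan_config()) {
  x <- as.matrix(class_samples)
  if (nrow(x) < 2) stop("need at least 2 class samples to train a WGAN-GP", call. = FALSE)
  n_genes <- ncol(x)
  nb <- cfg$batch_size %||% nrow(x)

  with_seed(derive_seed(cfg$seed, "wgan"), {
    gen <- new_wgan_generator(cfg$noise_dim, cfg$gen_hidden, n_genes)
    critic <- new_wgan_critic(n_genes)

    opt_g <- adamw_init(gen,
      lr = cfg$learning_rate, beta1 = cfg$adam_beta1,
      beta2 = cfg$adam_beta2
    )
    crit_p <- critic$params
    opt_c <- adamw_init(crit_p,
      lr = cfg$learning_rate, beta1 = cfg$adam_beta1,
      beta2 = cfg$adam_beta2
    )

    diag_rows <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      last <- NULL
      for (step in seq_len(cfg$n_critic)) {
        rows <- sample.int(nrow(x), nb, replace = nb > nrow(x))
        real <- x[rows, , drop = FALSE]
        z <- matrix(stats::rnorm(nb * cfg$noise_dim), nb)
        fake <- generator_forward(gen, z)$x

        fw_r <- critic_forward(critic, real)
        fw_f <- critic_forward(critic, fake)
        # persist power-iteration state from the real pass
        critic$sn$u1 <- fw_r$s1$u; critic$sn$u2 <- fw_r$s2$u; critic$sn$u3 <- fw_r$s3$u

        eps <- stats::runif(nb)
        xhat <- eps * real + (1 - eps) * fake
        gp_out <- gp_with_grads(critic, xhat, cfg$lambda_gp)

        w_est <- mean(fw_r$score) - mean(fw_f$score)
        c_loss <- -w_est + gp_out$penalty
        if (!is.finite(c_loss)) {
          stop(sprintf("critic loss diverged (non-finite) at epoch %d", epoch), call. = FALSE)
        }

        gr <- critic_score_grads(critic, fw_r, coef = -1)
        gf <- critic_score_grads(critic, fw_f, coef = +1)
        grads <- list(
          W1 = gr$gW1 + gf$gW1 + gp_out$gW1,
          b1 = gr$gb1 + gf$gb1,
          W2 = gr$gW2 + gf$gW2 + gp_out$gW2,
          b2 = gr$gb2 + gf$gb2,
          W3 = gr$gW3 + gf$gW3 + gp_out$gW3,
          b3 = gr$gb3 + gf$gb3
        )
        st <- adamw_step(crit_p, grads, opt_c)
        crit_p <- st$params; opt_c <- st$opt
        critic$params <- crit_p

        last <- list(
          critic_loss = c_loss, w = w_est, gp = gp_out$penalty,
          real = mean(fw_r$score), fake = mean(fw_f$score)
        )
      }

      # generator update: minimize -mean(critic(G(z)))
      z <- matrix(stats::rnorm(nb * cfg$noise_dim), nb)
      gfw <- generator_forward(gen, z)
      fw_f <- critic_forward(critic, gfw$x)
      g_loss <- -mean(fw_f$score)
      if (!is.finite(g_loss)) {
        stop(sprintf("generator loss diverged (non-finite) at epoch %d", epoch), call. = FALSE)
      }
      gx <- -critic_input_grad_cached(critic, fw_f) / nb
      ggrads <- generator_backward(gen, gfw, gx)
      names(ggrads) <- sub("^g", "", names(ggrads))
      st <- adamw_step(gen, ggrads, opt_g)
      gen <- st$params; opt_g <- st$opt

      diag_rows[[epoch]] <- tibble::tibble(
        epoch = epoch,
        generator_loss = g_loss,
        critic_loss = last$critic_loss,
        wasserstein_estimate = last$w,
        gradient_penalty_value = last$gp,
        mean_real_score = last$real,
        mean_fake_score = last$fake
      )
    }
  })

  diagnostics <- dplyr::bind_rows(diag_rows)
  gen_params <- gen
  noise_dim <- cfg$noise_dim
  structure(
    list(
      generate = function(n, seed = 1) {
        with_seed(seed, {
          z <- matrix(stats::rnorm(n * noise_dim), n)
        })
        generator_forward(gen_params, z)$x
      },
      generator = gen_params,
      critic = critic,
      diagnostics = structure(diagnostics, class = c("gan_diagnostics", class(diagnostics))),
      config = cfg
    ),
    class = "wgan_fit"
  )
}
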