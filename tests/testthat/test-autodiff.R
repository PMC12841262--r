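# Property-style gradient checks of the reverse-mode engine against central
# finite differences, over several random shapes under a fixed seed.

fd_gradient <- function(fwd, x0, eps = 1e-5) {
  g <- array(0, dim = dim(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    g[i] <- (castehub:::ad_value(fwd(castehub:::ad_wrap(xp))) -
      castehub:::ad_value(fwd(castehub:::ad_wrap(xm)))) / (2 * eps)
  }
  g
}

check_grad <- function(fwd, x0, tol = 1e-6) {
  leaf <- castehub:::ad_leaf(x0)
  out <- fwd(leaf)
  castehub:::ad_backward(out)
  fd <- fd_gradient(fwd, x0)
  expect_lt(max(abs(leaf$grad - fd)), tol)
}

test_that("core primitives differentiate correctly", {
  ad <- asNamespace("castehub")
  set.seed(101)
  for (rep in 1:3) {
    n <- sample(2:5, 1)
    d <- sample(2:6, 1)
    W <- matrix(rnorm(d * 3), d, 3)
    x0 <- matrix(rnorm(n * d), n, d)
    mask <- matrix(rnorm(n * 3), n, 3)
    targets <- diag(3)[sample(1:3, n, replace = TRUE), , drop = FALSE]

    # matmul + bias + gelu + softmax cross-entropy
    b <- rnorm(3)
    check_grad(function(x) {
      ad$ad_softmax_xent(ad$ad_gelu(ad$ad_add_bias(ad$ad_matmul(x, ad$ad_wrap(W)), ad$ad_wrap(b))), targets)
    }, x0)

    # layernorm with affine parameters
    gam <- rnorm(d); bet <- rnorm(d); m2 <- matrix(rnorm(n * d), n, d)
    check_grad(function(x) {
      ad$ad_mean_all(ad$ad_mul(ad$ad_layernorm(x, ad$ad_wrap(gam), ad$ad_wrap(bet)), ad$ad_wrap(m2)))
    }, x0)

    # tanh / sigmoid chains (LSTM ingredients)
    check_grad(function(x) {
      ad$ad_mean_all(ad$ad_mul(ad$ad_tanh(x), ad$ad_sigmoid(x)))
    }, x0)
  }
})

test_that("attention, convolutions and reshapes differentiate correctly", {
  ad <- asNamespace("castehub")
  set.seed(102)
  B <- 2; L <- 4; D <- 4; heads <- 2; W <- 2
  q0 <- matrix(rnorm(B * L * D), B * L, D)
  k0 <- matrix(rnorm(B * L * D), B * L, D)
  v0 <- matrix(rnorm(B * L * D), B * L, D)
  bias0 <- matrix(rnorm(heads * (2 * W - 1)), heads)
  mask <- matrix(rnorm(B * L * D), B * L, D)

  for (target in c("q", "k", "v", "bias")) {
    x0 <- switch(target, q = q0, k = k0, v = v0, bias = bias0)
    check_grad(function(x) {
      qs <- if (target == "q") x else ad$ad_wrap(q0)
      ks <- if (target == "k") x else ad$ad_wrap(k0)
      vs <- if (target == "v") x else ad$ad_wrap(v0)
      bs <- if (target == "bias") x else ad$ad_wrap(bias0)
      ad$ad_mean_all(ad$ad_mul(
        ad$ad_window_attention(qs, ks, vs, bs, heads, W, B, L), ad$ad_wrap(mask)
      ))
    }, x0, tol = 1e-5)
  }

  kern <- matrix(rnorm(3 * D), 3, D)
  cb <- rnorm(D)
  check_grad(function(x) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_depthwise_conv(x, ad$ad_wrap(kern), ad$ad_wrap(cb), B, L), ad$ad_wrap(mask)))
  }, q0, tol = 1e-5)
  check_grad(function(x) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_depthwise_conv(ad$ad_wrap(q0), x, ad$ad_wrap(cb), B, L), ad$ad_wrap(mask)))
  }, kern, tol = 1e-5)

  kern3 <- array(rnorm(3 * D * 5), c(3, D, 5))
  cb3 <- rnorm(5)
  mask5 <- matrix(rnorm(B * L * 5), B * L, 5)
  check_grad(function(x) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_conv1d(x, ad$ad_wrap(kern3), ad$ad_wrap(cb3), B, L), ad$ad_wrap(mask5)))
  }, q0, tol = 1e-5)

  flat0 <- matrix(rnorm(B * L * D), B, L * D)
  mk <- matrix(rnorm(B * D), B, D)
  check_grad(function(x) {
    ad$ad_mean_all(ad$ad_mul(
      ad$ad_token_mean(ad$ad_to_tokens(x, L, D), B, L), ad$ad_wrap(mk)
    ))
  }, flat0)
  mkf <- matrix(rnorm(B * L * D), B, L * D)
  check_grad(function(x) {
    ad$ad_mean_all(ad$ad_mul(ad$ad_from_tokens(x, B, L), ad$ad_wrap(mkf)))
  }, q0)
})

test_that("batchnorm in both modes and dropout scaling are consistent", {
  ad <- asNamespace("castehub")
  set.seed(103)
  n <- 6; d <- 4
  x0 <- matrix(rnorm(n * d), n, d)
  gam <- rnorm(d); bet <- rnorm(d)
  mask <- matrix(rnorm(n * d), n, d)

  # training mode gradient
  check_grad(function(x) {
    st <- new.env(); st$mean <- numeric(d); st$var <- rep(1, d); st$momentum <- 0.1
    ad$ad_mean_all(ad$ad_mul(
      ad$ad_batchnorm(x, ad$ad_wrap(gam), ad$ad_wrap(bet), st, TRUE), ad$ad_wrap(mask)
    ))
  }, x0, tol = 1e-5)

  # eval mode uses running stats and is affine
  st <- new.env(); st$mean <- rnorm(d); st$var <- runif(d, 0.5, 2); st$momentum <- 0.1
  out <- ad$ad_batchnorm(
    ad$ad_wrap(x0), ad$ad_wrap(gam), ad$ad_wrap(bet), st, FALSE
  )$value
  manual <- sweep(sweep(sweep(sweep(x0, 2, st$mean), 2, sqrt(st$var + 1e-5), "/"), 2, gam, "*"), 2, bet, "+")
  expect_equal(out, manual, tolerance = 1e-12)

  # inverted dropout preserves the expectation
  set.seed(7)
  big <- matrix(1, 2000, 50)
  dropped <- ad$ad_dropout(ad$ad_wrap(big), 0.4, TRUE)$value
  expect_equal(mean(dropped), 1, tolerance = 0.05)
  expect_identical(ad$ad_dropout(ad$ad_wrap(big), 0.4, FALSE)$value, big)
})
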