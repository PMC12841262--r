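test_that("SMOTE synthetics lie on segments between real neighbours", {
  # degenerate: two identical samples -> all synthetics identical to them
  x0 <- matrix(1:4, 2, 4, byrow = TRUE)
  x0[2, ] <- x0[1, ]
  s0 <- smote_interpolate(x0, k = 1, n_new = 5, seed = 1)
  expect_true(all(apply(s0, 1, function(r) all(r == x0[1, ]))))

  # collinear pair: synthetics on the diagonal with equal coordinates
  x1 <- rbind(c(0, 0), c(2, 2))
  s1 <- smote_interpolate(x1, k = 1, n_new = 20, seed = 2)
  expect_equal(s1[, 1], s1[, 2], tolerance = 1e-12)
  expect_true(all(s1 >= 0 & s1 <= 2))

  # general case: each synthetic point is on a segment between some sample
  # and one of its k nearest neighbours (brute-force kNN oracle)
  set.seed(3)
  x <- matrix(rnorm(8 * 5), 8, 5)
  k <- 3
  s <- smote_interpolate(x, k = k, n_new = 40, seed = 4)
  on_segment <- function(p) {
    for (i in seq_len(nrow(x))) {
      for (j in brute_knn(x, i, k)) {
        a <- x[i, ]
        b <- x[j, ]
        ab <- b - a
        t <- sum((p - a) * ab) / sum(ab^2)
        if (t >= -1e-9 && t <= 1 + 1e-9 &&
          sqrt(sum((a + t * ab - p)^2)) < 1e-9) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  expect_true(all(apply(s, 1, on_segment)))

  expect_warning(smote_interpolate(x[1:3, ], k = 5, n_new = 2, seed = 1), "clamped")
  expect_error(smote_interpolate(x[1, , drop = FALSE], k = 1, n_new = 2), "at least 2")
})

test_that("gaussian jitter matches its noise model", {
  set.seed(5)
  x <- matrix(rnorm(6 * 10, sd = 2), 6, 10)

  # zero scale -> exact copies of real samples
  s0 <- gaussian_jitter(x, c(0, 0), n_new = 10, seed = 6)
  expect_true(all(apply(s0, 1, function(r) {
    any(apply(x, 1, function(orig) isTRUE(all.equal(r, orig, tolerance = 1e-12))))
  })))

  # constant gene is never perturbed
  xc <- x
  xc[, 3] <- 7
  sc <- gaussian_jitter(xc, c(0.1, 0.1), n_new = 50, seed = 7)
  expect_true(all(sc[, 3] == 7))

  # at fixed scale 0.1 the per-gene deviation sd is ~0.1 * sigma_g
  sigma <- apply(x, 2, function(col) sqrt(mean((col - mean(col))^2)))
  n_draw <- 1000
  s <- gaussian_jitter(x, c(0.1, 0.1), n_new = n_draw, seed = 8)
  # recover each draw's parent as the nearest real sample
  parents <- apply(s, 1, function(r) which.min(colSums((t(x) - r)^2)))
  dev_sd <- sapply(seq_len(ncol(x)), function(g) stats::sd(s[, g] - x[parents, g]))
  expect_true(all(abs(dev_sd / (0.1 * sigma) - 1) < 0.2))

  expect_error(gaussian_jitter(x[1, , drop = FALSE], c(0, 0.1), 2), "single-sample")
})

test_that("mixup produces convex combinations with the Beta(0.4, 0.4) mean", {
  x <- rbind(c(0, 2), c(2, 0))
  s <- mixup_augment(x, c(0.4, 0.4), n_new = 200, seed = 9)
  # all points on the segment x1-x2: coordinates sum to 2
  expect_equal(rowSums(s), rep(2, 200), tolerance = 1e-12)

  # forced endpoint: Beta(a, b) with huge a -> lambda ~ 1 returns x_i
  s1 <- mixup_augment(x, c(1e8, 1e-8), n_new = 10, seed = 10)
  expect_true(all(apply(s1, 1, function(r) {
    isTRUE(all.equal(r, x[1, ], tolerance = 1e-3)) ||
      isTRUE(all.equal(r, x[2, ], tolerance = 1e-3))
  })))

  # direct convex combination: lambda = 0.25 of (0,2) and (2,0) -> (1.5, 0.5)
  expect_equal(0.25 * c(0, 2) + 0.75 * c(2, 0), c(1.5, 0.5))

  # empirical mean of Beta(0.4, 0.4) draws is 1/2
  set.seed(11)
  draws <- stats::rbeta(1e5, 0.4, 0.4)
  expect_equal(mean(draws), 0.5, tolerance = 0.01)
})

test_that("distance filter equals the brute-force rule", {
  set.seed(12)
  real <- matrix(rnorm(5 * 3), 5, 3)
  cand <- matrix(rnorm(8 * 3), 8, 3)

  out <- distance_filter(cand, real, multiplier = 2)
  # brute force: median pairwise real distance, candidate median distances
  r <- stats::median(apply(utils::combn(5, 2), 2, function(p) {
    sqrt(sum((real[p[1], ] - real[p[2], ])^2))
  }))
  expected_mask <- apply(cand, 1, function(cc) {
    stats::median(apply(real, 1, function(rr) sqrt(sum((cc - rr)^2)))) < 2 * r
  })
  expect_identical(out$mask, unname(expected_mask))
  expect_equal(out$retained, cand[expected_mask, , drop = FALSE])

  # a real sample itself is within the cloud -> retained
  out2 <- distance_filter(real[1, , drop = FALSE], real, multiplier = 2)
  expect_true(out2$mask)
  # an absurdly distant candidate is rejected
  out3 <- distance_filter(matrix(1e6, 1, 3), real, multiplier = 2)
  expect_false(out3$mask)

  expect_error(distance_filter(cand, real[1, , drop = FALSE]), "at least 2")
})

test_that("largest-remainder split of the printed fractions is exact", {
  # 6 real per class, target 100 -> 94 synthetic: 28 wgan, 14 smote,
  # 33 noise, 19 mixup
  counts <- castehub:::largest_remainder(94, c(0.30, 0.15, 0.35, 0.20))
  expect_identical(counts, c(28L, 14L, 33L, 19L))
  expect_equal(sum(counts), 94)
  # always sums to the budget
  for (n in c(0, 1, 17, 44, 73)) {
    expect_equal(sum(castehub:::largest_remainder(n, c(0.30, 0.15, 0.35, 0.20))), n)
  }
})

test_that("composed dataset respects targets, fractions and provenance", {
  ds <- tiny_dataset(n_genes = 30, seed = 41)
  z <- zscore_normalize(ds$expr)
  cfg <- augmentation_config(seed = 3)
  aug <- compose_augmented_dataset(z, ds$meta, cfg, wgan_config(epochs = 15, seed = 3))

  tab <- table(aug$labels$class_label, aug$labels$provenance)
  totals <- rowSums(tab)
  expect_true(all(totals >= 50 & totals <= 100))
  expect_equal(sort(unname(totals)), sort(unname(aug$targets)))

  # real samples present unchanged
  expect_equal(aug$expr[, colnames(z)], z)
  expect_true(all(tab[, "real"] == 6))

  # provenance counts follow largest-remainder of the fractions per class
  for (cl in rownames(tab)) {
    budget <- totals[cl] - 6
    expected <- castehub:::largest_remainder(budget, c(0.30, 0.15, 0.35, 0.20))
    expect_identical(
      unname(tab[cl, c("wgan", "smote", "noise", "mixup")]),
      as.integer(expected)
    )
  }

  # determinism end to end
  aug2 <- compose_augmented_dataset(z, ds$meta, cfg, wgan_config(epochs = 15, seed = 3))
  expect_identical(aug$expr, aug2$expr)
  expect_identical(aug$labels, aug2$labels)
})

test_that("degenerate mixtures and impossible budgets are handled", {
  ds <- tiny_dataset(n_genes = 30, seed = 42)
  z <- zscore_normalize(ds$expr)
  # pure-WGAN mixture with no filtering: only real + wgan samples
  cfg <- augmentation_config(
    frac_wgan = 1, frac_smote = 0, frac_noise = 0, frac_mixup = 0,
    target_min_per_class = 10, target_max_per_class = 12,
    distance_multiplier = Inf, seed = 4
  )
  aug <- compose_augmented_dataset(z, ds$meta, cfg, wgan_config(epochs = 5, seed = 4))
  expect_setequal(unique(aug$labels$provenance), c("real", "wgan"))

  cfg_bad <- augmentation_config(target_min_per_class = 2, target_max_per_class = 4)
  expect_error(
    compose_augmented_dataset(z, ds$meta, cfg_bad, wgan_config(epochs = 2)),
    "raise target_max"
  )

  expect_error(augmentation_config(frac_wgan = 0.5), "sum to 1")
})
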