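#' Augmentation configuration
#'
#' The four-way augmentation mixture: WGAN-GP synthesis (30%), SMOTE
#' interpolation (15%), Gaussian jitter scaled to 5--15% of the feature-wise
#' standard deviation (35%) and within-class Mixup with a Beta(0.4, 0.4)
#' coefficient (20%). Each class is expanded to a target drawn uniformly in
#' `[target_min_per_class, target_max_per_class]`; WGAN-GP candidates are
#' kept only if their median distance to the class's real samples is below
#' `distance_multiplier` times the median within-class distance.
#'
#' @param frac_wgan,frac_smote,frac_noise,frac_mixup Mixture fractions
#'   (must sum to 1).
#' @param target_min_per_class,target_max_per_class Per-class sample-count
#'   bounds after augmentation (defaults 50 and 100).
#' @param noise_scale_range Length-2 vector: jitter scale range as a fraction
#'   of the feature-wise sd (default `c(0.05, 0.15)`).
#' @param mixup_beta Length-2 vector of Beta parameters (default `c(0.4, 0.4)`).
#' @param distance_multiplier Plausibility-filter multiplier (default 2).
#' @param smote_k Number of nearest neighbours for SMOTE (default 5).
#' @param seed Integer seed.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(frac_wgan = 0.30, frac_smote = 0.15,
                                frac_noise = 0.35, frac_mixup = 0.20,
                                target_min_per_class = 50,
                                target_max_per_class = 100,
                                noise_scale_range = c(0.05, 0.15),
                                mixup_beta = c(0.4, 0.4),
                                distance_multiplier = 2.0,
                                smote_k = 5, seed = 1) {
  cfg <- list(
    frac_wgan = frac_wgan, frac_smote = frac_smote,
    frac_noise = frac_noise, frac_mixup = frac_mixup,
    target_min_per_class = target_min_per_class,
    target_max_per_class = target_max_per_class,
    noise_scale_range = noise_scale_range,
    mixup_beta = mixup_beta,
    distance_multiplier = distance_multiplier,
    smote_k = smote_k, seed = seed
  )
  fr <- c(frac_wgan, frac_smote, frac_noise, frac_mixup)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("augmentation fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  if (target_min_per_class > target_max_per_class) {
    stop("target_min_per_class must be <= target_max_per_class", call. = FALSE)
  }
  structure(cfg, class = "augmentation_config")
}

#' SMOTE interpolation within a class
#'
#' Each synthetic sample is `x + u * (x_nn - x)` where `x` is a random class
#' sample, `x_nn` one of its `k` nearest same-class neighbours (Euclidean)
#' and `u ~ Uniform(0, 1)`, so every synthetic point lies on a segment
#' between two real samples.
#'
#' @param class_samples Matrix (samples x genes), at least 2 rows.
#' @param k Neighbourhood size; clamped to `n - 1` with a warning if too large.
#' @param n_new Number of synthetic samples.
#' @param seed Integer seed.
#' @return Matrix (`n_new` x genes).
#' @export
smote_interpolate <- function(class_samples, k = 5, n_new, seed = 1) {
  x <- as.matrix(class_samples)
  n <- nrow(x)
  if (n < 2) stop("SMOTE needs at least 2 class samples", call. = FALSE)
  if (k >= n) {
    warning(sprintf("k = %d >= class size %d; clamped to %d", k, n, n - 1), call. = FALSE)
    k <- n - 1
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn_raw <- apply(d, 1, function(row) order(row)[seq_len(k)])
  nn <- if (k == 1) matrix(nn_raw, ncol = 1) else t(nn_raw)
  with_seed(seed, {
    base <- sample.int(n, n_new, replace = TRUE)
    pick <- vapply(base, function(i) nn[i, sample.int(k, 1)], integer(1))
    u <- stats::runif(n_new)
  })
  x[base, , drop = FALSE] + u * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
}

#' Gaussian jitter augmentation
#'
#' Each synthetic sample is a random real class sample plus noise with
#' per-gene standard deviation `s * sigma_g`, where `sigma_g` is the
#' feature-wise (population) sd within the class and `s` is drawn uniformly
#' from `scale_range` per synthetic sample. Constant genes stay unchanged.
#'
#' @param class_samples Matrix (samples x genes), at least 2 rows.
#' @param scale_range Length-2 nonnegative vector `(low, high)`, `low <= high`.
#' @param n_new Number of synthetic samples.
#' @param seed Integer seed.
#' @return Matrix (`n_new` x genes).
#' @export
gaussian_jitter <- function(class_samples, scale_range = c(0.05, 0.15), n_new, seed = 1) {
  x <- as.matrix(class_samples)
  if (nrow(x) < 2) {
    stop("feature-wise sd undefined for a single-sample class", call. = FALSE)
  }
  stopifnot(length(scale_range) == 2, scale_range[1] >= 0, scale_range[1] <= scale_range[2])
  sigma <- apply(x, 2, pop_sd)
  with_seed(seed, {
    base <- sample.int(nrow(x), n_new, replace = TRUE)
    s <- stats::runif(n_new, scale_range[1], scale_range[2])
    eps <- matrix(stats::rnorm(n_new * ncol(x)), n_new) *
      (s %o% sigma)
  })
  x[base, , drop = FALSE] + eps
}

#' Within-class Mixup augmentation
#'
#' Each synthetic sample is `lambda * x_i + (1 - lambda) * x_j` for two
#' distinct same-class samples and `lambda ~ Beta(a, b)`. Pairs stay within
#' one class so synthetic samples carry hard labels; cross-class Mixup is a
#' separate training-time regularizer (see [train_config()]).
#'
#' @param class_samples Matrix (samples x genes), at least 2 rows.
#' @param beta_params Length-2 vector `(a, b)` (default `c(0.4, 0.4)`).
#' @param n_new Number of synthetic samples.
#' @param seed Integer seed.
#' @return Matrix (`n_new` x genes).
#' @export
mixup_augment <- function(class_samples, beta_params = c(0.4, 0.4), n_new, seed = 1) {
  x <- as.matrix(class_samples)
  n <- nrow(x)
  if (n < 2) stop("Mixup needs at least 2 class samples", call. = FALSE)
  with_seed(seed, {
    i <- sample.int(n, n_new, replace = TRUE)
    j <- vapply(i, function(ii) sample(setdiff(seq_len(n), ii), 1), integer(1))
    lam <- stats::rbeta(n_new, beta_params[1], beta_params[2])
  })
  lam * x[i, , drop = FALSE] + (1 - lam) * x[j, , drop = FALSE]
}

#' Distance-based plausibility filter
#'
#' Retains a candidate synthetic sample iff its median Euclidean distance to
#' the class's real samples is below `multiplier` times the median of all
#' pairwise distances among the real samples.
#'
#' @param candidates Matrix (candidates x genes).
#' @param real_class_samples Matrix (real samples x genes), at least 2 rows.
#' @param multiplier Distance multiplier (default 2).
#' @return A list: `retained` (filtered candidate matrix) and `mask`
#'   (logical vector aligned to candidate rows).
#' @export
distance_filter <- function(candidates, real_class_samples, multiplier = 2.0) {
  cand <- as.matrix(candidates)
  real <- as.matrix(real_class_samples)
  if (nrow(real) < 2) {
    stop("distance filter needs at least 2 real samples", call. = FALSE)
  }
  r <- stats::median(pairwise_dists(real))
  d <- cross_dists(cand, real)
  med <- apply(d, 1, stats::median)
  mask <- med < multiplier * r
  list(retained = cand[mask, , drop = FALSE], mask = mask)
}

#' Compose the augmented dataset
#'
#' Expands every phenotype class to a target size drawn uniformly in
#' `[target_min_per_class, target_max_per_class]`, splitting the synthetic
#' budget across the four strategies by the configured fractions
#' (largest-remainder rounding). WGAN-GP candidates are oversampled, passed
#' through [distance_filter()] and topped up by re-generation; any remaining
#' shortfall after a bounded number of retries is reallocated to Gaussian
#' jitter with a warning. All real samples are kept unchanged with
#' provenance `"real"`.
#'
#' @param expr Genes x samples expression matrix (typically z-scored).
#' @param meta Sample metadata tibble (`sample_id`, `class_label`).
#' @param cfg An [augmentation_config()].
#' @param wgan_cfg A [wgan_config()]; one WGAN-GP is trained per class.
#' @param max_retries Rounds of WGAN re-generation before reallocating
#'   (default 5).
#' @return An `augmented_dataset` list: `expr` (genes x samples matrix
#'   including synthetic samples), `labels` (tibble `sample_id`,
#'   `class_label`, `provenance`), `diagnostics` (per-class GAN diagnostics
#'   tibble), `targets` (per-class totals).
#' @export
compose_augmented_dataset <- function(expr, meta, cfg = augmentation_config(),
                                      wgan_cfg = wgan_config(),
                                      max_retries = 5) {
  validate_expression_matrix(expr)
  stopifnot(all(colnames(expr) %in% meta$sample_id))
  classes <- unique(meta$class_label)
  frs <- c(cfg$frac_wgan, cfg$frac_smote, cfg$frac_noise, cfg$frac_mixup)

  out_blocks <- list(t(expr))
  label_rows <- list(tibble::tibble(
    sample_id = colnames(expr),
    class_label = meta$class_label[match(colnames(expr), meta$sample_id)],
    provenance = "real"
  ))
  diag_all <- list()
  targets <- integer(0)

  for (cl in classes) {
    ids <- meta$sample_id[meta$class_label == cl]
    real <- t(expr[, ids, drop = FALSE]) # samples x genes
    n_real <- nrow(real)
    if (n_real < 2) stop(sprintf("class '%s' has fewer than 2 real samples", cl), call. = FALSE)
    if (n_real > cfg$target_max_per_class) {
      stop(sprintf(
        "class '%s' already has %d > target_max_per_class = %d samples; raise target_max_per_class",
        cl, n_real, cfg$target_max_per_class
      ), call. = FALSE)
    }
    target <- with_seed(derive_seed(cfg$seed, paste0("target_", cl)), {
      rng <- seq(max(cfg$target_min_per_class, n_real), cfg$target_max_per_class)
      rng[sample.int(length(rng), 1)]
    })
    targets[cl] <- target
    budget <- target - n_real
    counts <- largest_remainder(budget, frs)
    names(counts) <- c("wgan", "smote", "noise", "mixup")

    blocks <- list()

    # WGAN-GP with distance filter and bounded re-generation
    if (counts[["wgan"]] > 0) {
      wcfg <- wgan_cfg
      wcfg$seed <- derive_seed(cfg$seed, paste0("wgan_", cl))
      fit <- train_wgan_gp(real, wcfg)
      diag_all[[cl]] <- dplyr::mutate(fit$diagnostics, class_label = cl)
      kept <- matrix(0, 0, ncol(real))
      tries <- 0
      while (nrow(kept) < counts[["wgan"]] && tries < max_retries) {
        tries <- tries + 1
        cand <- fit$generate(
          3 * counts[["wgan"]],
          seed = derive_seed(cfg$seed, paste0("wgen_", cl, "_", tries))
        )
        if (is.finite(cfg$distance_multiplier)) {
          cand <- distance_filter(cand, real, cfg$distance_multiplier)$retained
        }
        kept <- rbind(kept, cand)
      }
      got <- min(nrow(kept), counts[["wgan"]])
      shortfall <- counts[["wgan"]] - got
      if (shortfall > 0) {
        warning(sprintf(
          "class '%s': %d WGAN-GP candidates survived filtering (quota %d); shortfall reallocated to Gaussian jitter",
          cl, got, counts[["wgan"]]
        ), call. = FALSE)
        counts[["noise"]] <- counts[["noise"]] + shortfall
        counts[["wgan"]] <- got
      }
      if (got > 0) {
        blocks$wgan <- kept[seq_len(got), , drop = FALSE]
      }
    }

    if (counts[["smote"]] > 0) {
      blocks$smote <- smote_interpolate(real, cfg$smote_k, counts[["smote"]],
        seed = derive_seed(cfg$seed, paste0("smote_", cl))
      )
    }
    if (counts[["noise"]] > 0) {
      blocks$noise <- gaussian_jitter(real, cfg$noise_scale_range, counts[["noise"]],
        seed = derive_seed(cfg$seed, paste0("noise_", cl))
      )
    }
    if (counts[["mixup"]] > 0) {
      blocks$mixup <- mixup_augment(real, cfg$mixup_beta, counts[["mixup"]],
        seed = derive_seed(cfg$seed, paste0("mixup_", cl))
      )
    }

    for (prov in names(blocks)) {
      b <- blocks[[prov]]
      if (is.null(b) || nrow(b) == 0) next
      ids_new <- sprintf("%s_%s_%03d", cl, prov, seq_len(nrow(b)))
      rownames(b) <- ids_new
      out_blocks[[length(out_blocks) + 1]] <- b
      label_rows[[length(label_rows) + 1]] <- tibble::tibble(
        sample_id = ids_new, class_label = cl, provenance = prov
      )
    }
  }

  all_samples <- do.call(rbind, out_blocks)
  labels <- dplyr::bind_rows(label_rows)
  aug_expr <- t(all_samples)
  rownames(aug_expr) <- rownames(expr)
  colnames(aug_expr) <- labels$sample_id

  structure(
    list(
      expr = aug_expr,
      labels = labels,
      diagnostics = if (length(diag_all)) dplyr::bind_rows(diag_all) else NULL,
      targets = targets,
      config = cfg
    ),
    class = "augmented_dataset"
  )
}

#' @export
print.augmented_dataset <- function(x, ...) {
  tab <- table(x$labels$class_label, x$labels$provenance)
  cat(sprintf(
    "<augmented_dataset> %d genes x %d samples (%d real)\n",
    nrow(x$expr), ncol(x$expr), sum(x$labels$provenance == "real")
  ))
  print(tab)
  invisible(x)
}
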