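#' Generate a caste-structured synthetic expression dataset
#'
#' Emulates the downstream form of a small bulk RNA-seq caste study after
#' standardization: Gaussian background expression, a disjoint set of marker
#' genes per class carrying a mean shift in their class only, and
#' block-correlated gene modules driven by a shared latent factor whose mean
#' shifts in the module's trait class. Everything is recorded as ground truth
#' so downstream recovery can be measured.
#'
#' Module genes follow `gene = noise_sd * (sqrt(rho) * factor + sqrt(1 - rho) * noise)`
#' with one factor per module per sample, giving an expected within-module
#' correlation of exactly `rho`.
#'
#' @param n_genes Total number of genes (default 300).
#' @param classes Character vector of class labels.
#' @param n_per_class Replicates per class (default 6, the study design).
#' @param n_markers_per_class Marker genes per class (default 10).
#' @param effect_size Marker mean shift in units of `noise_sd` (default 3).
#' @param n_modules Number of co-expression modules (default 3, one per caste).
#' @param module_size Genes per module (default 30).
#' @param within_module_cor Expected within-module correlation rho (default 0.7).
#' @param module_trait_shift Mean shift of a module's latent factor in its
#'   trait class, in `noise_sd` units (default `effect_size / 2`): modules
#'   carry a milder trait association than the dedicated marker genes, which
#'   stay the dominant class-discriminating features.
#' @param noise_sd Background standard deviation (default 1).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A list with elements `expr` (genes x samples matrix), `meta`
#'   (sample metadata tibble) and `truth` (a `caste_truth` list holding
#'   `markers_per_class`, `effect_size`, `module_assignment`,
#'   `module_trait_class` and `seed`).
#' @export
generate_caste_dataset <- function(n_genes = 300,
                                   classes = c("queen", "worker", "drone"),
                                   n_per_class = 6,
                                   n_markers_per_class = 10,
                                   effect_size = 3,
                                   n_modules = 3,
                                   module_size = 30,
                                   within_module_cor = 0.7,
                                   module_trait_shift = effect_size / 2,
                                   noise_sd = 1,
                                   seed = 1) {
  stopifnot(n_per_class >= 2, noise_sd > 0)
  stopifnot(within_module_cor > 0, within_module_cor < 1)
  k <- length(classes)
  need <- n_markers_per_class * k + n_modules * module_size
  if (need > n_genes) {
    stop(sprintf(
      "infeasible gene budget: %d markers x %d classes + %d modules x %d genes = %d > n_genes = %d",
      n_markers_per_class, k, n_modules, module_size, need, n_genes
    ), call. = FALSE)
  }

  n_samples <- k * n_per_class
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- as.vector(vapply(
    classes,
    function(cl) paste0(cl, "_", seq_len(n_per_class)),
    character(n_per_class)
  ))
  class_of_sample <- rep(classes, each = n_per_class)

  with_seed(derive_seed(seed, "simulate"), {
    expr <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
      nrow = n_genes,
      dimnames = list(gene_ids, sample_ids)
    )

    # disjoint marker blocks, then module blocks, rest is background
    idx <- seq_len(n_genes)
    markers_per_class <- list()
    cursor <- 0
    for (cl in classes) {
      take <- idx[cursor + seq_len(n_markers_per_class)]
      markers_per_class[[cl]] <- gene_ids[take]
      expr[take, class_of_sample == cl] <-
        expr[take, class_of_sample == cl] + effect_size * noise_sd
      cursor <- cursor + n_markers_per_class
    }

    module_assignment <- stats::setNames(rep("grey", n_genes), gene_ids)
    module_trait_class <- character(0)
    rho <- within_module_cor
    if (n_modules > 0) {
      for (m in seq_len(n_modules)) {
        label <- paste0("M", m)
        trait_class <- classes[((m - 1) %% k) + 1]
        module_trait_class[label] <- trait_class
        take <- idx[cursor + seq_len(module_size)]
        module_assignment[take] <- label
        factor_scores <- stats::rnorm(n_samples)
        factor_scores[class_of_sample == trait_class] <-
          factor_scores[class_of_sample == trait_class] + module_trait_shift
        loadings <- matrix(rep(factor_scores, each = module_size), nrow = module_size)
        noise <- matrix(stats::rnorm(module_size * n_samples), nrow = module_size)
        expr[take, ] <- noise_sd * (sqrt(rho) * loadings + sqrt(1 - rho) * noise)
        cursor <- cursor + module_size
      }
    }
  })

  meta <- tibble::tibble(
    sample_id = sample_ids,
    class_label = class_of_sample,
    replicate = rep(seq_len(n_per_class), times = k)
  )
  truth <- structure(
    list(
      markers_per_class = markers_per_class,
      effect_size = effect_size,
      module_assignment = module_assignment,
      module_trait_class = module_trait_class,
      classes = classes,
      seed = seed
    ),
    class = "caste_truth"
  )
  list(expr = expr, meta = meta, truth = truth)
}

#' Ground-truth network scores for a synthetic dataset
#'
#' Computes gene significance (GS) and module membership (MM) from the
#' generator's recorded module structure. GS is the absolute Pearson
#' correlation with a one-vs-rest indicator of the gene's associated class
#' (markers use their own class, module genes their module's trait class,
#' background genes the first class as a null reference). MM is the
#' correlation with the gene's module eigengene; unassigned ("grey") genes
#' get MM 0.
#'
#' @param expr Genes x samples expression matrix from [generate_caste_dataset()].
#' @param meta Matching sample metadata tibble.
#' @param truth Matching `caste_truth` object.
#' @return A network-score tibble (`gene_id`, `GS`, `MM`, `module`).
#' @export
true_network_scores <- function(expr, meta, truth) {
  stopifnot(inherits(truth, "caste_truth"))
  stopifnot(identical(colnames(expr), meta$sample_id))
  genes <- rownames(expr)
  classes <- truth$classes

  gene_class <- stats::setNames(rep(classes[1], length(genes)), genes)
  for (cl in names(truth$markers_per_class)) {
    gene_class[truth$markers_per_class[[cl]]] <- cl
  }
  modules <- truth$module_assignment[genes]
  assigned <- modules != "grey"
  gene_class[assigned] <- truth$module_trait_class[modules[assigned]]

  gs <- vapply(seq_along(genes), function(i) {
    trait <- as.numeric(meta$class_label == gene_class[i])
    gene_significance_one(expr[i, ], trait)
  }, numeric(1))

  mm <- rep(0, length(genes))
  for (label in unique(modules[assigned])) {
    members <- genes[modules == label]
    eig <- module_eigengene(expr, members)
    mm[modules == label] <- vapply(
      members,
      function(g) stats::cor(expr[g, ], eig),
      numeric(1)
    )
  }

  tibble::tibble(
    gene_id = genes,
    GS = gs,
    MM = pmin(pmax(mm, -1), 1),
    module = unname(modules)
  )
}
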