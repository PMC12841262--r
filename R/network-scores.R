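#' Gene significance
#'
#' Absolute Pearson correlation of each gene's expression with a per-sample
#' trait vector (for categorical phenotypes, a one-vs-rest indicator).
#' Constant genes get GS 0.
#'
#' @param expr Genes x samples expression matrix.
#' @param trait Numeric per-sample trait vector (length = sample count).
#' @return Named numeric vector of GS values in \[0, 1\].
#' @export
gene_significance <- function(expr, trait) {
  if (length(trait) != ncol(expr)) {
    stop("trait length must equal the number of samples", call. = FALSE)
  }
  if (stats::sd(trait) == 0) stop("trait is constant; GS undefined", call. = FALSE)
  out <- apply(expr, 1, gene_significance_one, trait = trait)
  stats::setNames(pmin(out, 1), rownames(expr))
}

gene_significance_one <- function(x, trait) {
  if (stats::sd(x) == 0) return(0)
  abs(stats::cor(x, trait))
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix, one value
#' per sample, scaled to unit variance and sign-oriented so that the mean
#' correlation with member genes is positive.
#'
#' @param expr Genes x samples expression matrix.
#' @param module_genes Character vector of member gene ids (length >= 2).
#' @return Numeric per-sample eigengene vector (unit variance).
#' @export
module_eigengene <- function(expr, module_genes) {
  missing_g <- setdiff(module_genes, rownames(expr))
  if (length(missing_g) > 0) {
    stop(sprintf("module gene absent from matrix: %s", missing_g[1]), call. = FALSE)
  }
  if (length(module_genes) < 2) stop("a module needs at least 2 genes", call. = FALSE)
  sub <- zscore_normalize(expr[module_genes, , drop = FALSE])
  sv <- svd(sub, nu = 0, nv = 1)
  eig <- sv$v[, 1]
  s <- stats::sd(eig)
  if (s < .Machine$double.eps) stop("degenerate module: eigengene is constant", call. = FALSE)
  eig <- eig / s
  orient <- mean(apply(sub, 1, function(g) {
    if (stats::sd(g) == 0) 0 else stats::cor(g, eig)
  }))
  if (orient < 0) eig <- -eig
  eig
}

#' Module membership
#'
#' Pearson correlation of each gene's expression with a module eigengene.
#'
#' @param expr Genes x samples expression matrix.
#' @param eigengene Per-sample eigengene vector.
#' @return Named numeric vector of MM values in \[-1, 1\].
#' @export
module_membership <- function(expr, eigengene) {
  if (length(eigengene) != ncol(expr)) {
    stop("eigengene length must equal the number of samples", call. = FALSE)
  }
  if (stats::sd(eigengene) == 0) stop("eigengene is constant; MM undefined", call. = FALSE)
  out <- apply(expr, 1, function(x) {
    if (stats::sd(x) == 0) return(0)
    stats::cor(x, eigengene)
  })
  stats::setNames(pmin(pmax(out, -1), 1), rownames(expr))
}

#' Compute a network-score table from a module assignment
#'
#' Convenience wrapper producing the per-gene GS/MM table consumed by hub
#' scoring. GS uses a one-vs-rest indicator of `trait_class` per module (or a
#' single global trait); MM is the correlation with each gene's own module
#' eigengene; genes labelled `"grey"` get MM 0 and GS against `default_class`.
#'
#' @param expr Genes x samples expression matrix.
#' @param meta Sample metadata tibble.
#' @param module_assignment Named character vector, gene id -> module label
#'   (`"grey"` allowed for unassigned genes).
#' @param module_trait_class Named character vector, module label -> class
#'   whose one-vs-rest indicator serves as that module's trait.
#' @param default_class Class used as trait for unassigned genes (default:
#'   first class in `meta`).
#' @return A network-score tibble (`gene_id`, `GS`, `MM`, `module`).
#' @export
compute_network_scores <- function(expr, meta, module_assignment,
                                   module_trait_class,
                                   default_class = NULL) {
  genes <- rownames(expr)
  modules <- module_assignment[genes]
  modules[is.na(modules)] <- "grey"
  default_class <- default_class %||% meta$class_label[1]

  trait_class <- ifelse(modules == "grey", default_class,
    module_trait_class[modules]
  )
  gs <- vapply(seq_along(genes), function(i) {
    gene_significance_one(expr[i, ], as.numeric(meta$class_label == trait_class[i]))
  }, numeric(1))

  mm <- rep(0, length(genes))
  for (label in setdiff(unique(modules), "grey")) {
    members <- genes[modules == label]
    if (length(members) < 2) next
    eig <- module_eigengene(expr, members)
    mm[modules == label] <- module_membership(
      expr[members, , drop = FALSE], eig
    )
  }

  tibble::tibble(
    gene_id = genes,
    GS = pmin(gs, 1),
    MM = pmin(pmax(mm, -1), 1),
    module = unname(modules)
  )
}
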