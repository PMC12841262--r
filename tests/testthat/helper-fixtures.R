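# Shared fixtures built in code.

# A tiny labeled expression matrix with clearly separated class means.
tiny_dataset <- function(n_genes = 40, n_per_class = 6, effect = 3, seed = 11) {
  generate_caste_dataset(
    n_genes = n_genes, n_per_class = n_per_class,
    n_markers_per_class = 4, effect_size = effect,
    n_modules = 2, module_size = 6, within_module_cor = 0.7,
    seed = seed
  )
}

# Write a small expression TSV and return its path.
write_tiny_expr <- function(m, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "expr.tsv")
  write_expression_matrix(m, path)
  path
}

# Deterministic small matrix with dimnames.
named_matrix <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
    dimnames = list(
      sprintf("g%02d", seq_len(n_genes)),
      sprintf("s%02d", seq_len(n_samples))
    )
  )
}

# Brute-force k nearest neighbours (Euclidean) for SMOTE oracle checks.
brute_knn <- function(x, i, k) {
  d <- sqrt(colSums((t(x) - x[i, ])^2))
  d[i] <- Inf
  order(d)[seq_len(k)]
}

# Dense single-window attention oracle for one head.
dense_attention_oracle <- function(Q, K, V, bias_mat, dk) {
  S <- Q %*% t(K) / sqrt(dk) + bias_mat
  A <- exp(S - apply(S, 1, max))
  A <- A / rowSums(A)
  A %*% V
}
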