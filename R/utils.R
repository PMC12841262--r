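# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a reproducible child seed from a parent seed and a stream name.
# Keeps results independent across stages while driven by one global seed.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483647)
}

# Evaluate an expression under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Min-max rescale to [0, 1]; constant vectors map to all zeros.
minmax_rescale <- function(x) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] < .Machine$double.eps) {
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Split an integer budget across fractions so the parts sum exactly to the
# budget (largest-remainder method; ties go to the larger fraction, then to
# earlier position).
largest_remainder <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  raw <- n * fractions
  base <- floor(raw)
  rem <- raw - base
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(-rem, -fractions, seq_along(fractions))
    take <- ord[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# All pairwise Euclidean distances between rows of a matrix (vector).
pairwise_dists <- function(x) {
  as.numeric(stats::dist(x))
}

# Euclidean distances from each row of a to each row of b (nrow(a) x nrow(b)).
cross_dists <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

assert_matrix_samples_by_genes <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (samples x genes)", name), call. = FALSE)
  }
  invisible(x)
}
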