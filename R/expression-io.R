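#' Read an expression matrix from delimited text
#'
#' Reads a genes-by-samples expression table (TSV or CSV). The first column
#' holds gene identifiers and the header row holds sample identifiers; set
#' `genes_in_rows = FALSE` for the transposed layout. The returned matrix is
#' always oriented genes x samples with identifiers as dimnames.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#' @param genes_in_rows If `TRUE` (default) rows are genes; otherwise the
#'   table is transposed after reading.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path, delimiter = "\t", genes_in_rows = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path,
    header = TRUE, sep = delimiter, check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = "", quote = "\""
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop(sprintf("empty or malformed expression table: %s", path), call. = FALSE)
  }
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0) {
        stop(sprintf(
          "non-numeric value '%s' at row %d, column '%s'",
          col[bad[1]], bad[1], names(body)[j]
        ), call. = FALSE)
      }
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix to delimited text
#'
#' @param m Numeric genes x samples matrix with dimnames.
#' @param path Output file path.
#' @param delimiter Field separator (default TAB).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, delimiter = "\t") {
  validate_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path,
    sep = delimiter, quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

validate_expression_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry gene and sample identifiers", call. = FALSE)
  }
  dup_g <- rownames(m)[duplicated(rownames(m))]
  if (length(dup_g) > 0) {
    stop(sprintf("duplicate gene identifier: %s", dup_g[1]), call. = FALSE)
  }
  dup_s <- colnames(m)[duplicated(colnames(m))]
  if (length(dup_s) > 0) {
    stop(sprintf("duplicate sample identifier: %s", dup_s[1]), call. = FALSE)
  }
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values", call. = FALSE)
  invisible(m)
}

#' Read sample metadata
#'
#' Expects a delimited table with columns `sample_id`, `class_label` and
#' optionally `replicate`.
#'
#' @param path Path to delimited text.
#' @param delimiter Field separator (default TAB).
#' @param expr Optional expression matrix to validate sample coverage against.
#' @return A tibble with columns `sample_id`, `class_label`, `replicate`.
#' @export
read_sample_metadata <- function(path, delimiter = "\t", expr = NULL) {
  df <- utils::read.table(path,
    header = TRUE, sep = delimiter,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  need <- c("sample_id", "class_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("metadata is missing column(s): %s", paste(missing_cols, collapse = ", ")),
      call. = FALSE
    )
  }
  if (!"replicate" %in% names(df)) {
    df$replicate <- stats::ave(seq_len(nrow(df)), df$class_label, FUN = seq_along)
  }
  meta <- tibble::tibble(
    sample_id = as.character(df$sample_id),
    class_label = as.character(df$class_label),
    replicate = as.integer(df$replicate)
  )
  validate_sample_metadata(meta, expr)
  meta
}

validate_sample_metadata <- function(meta, expr = NULL) {
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  counts <- table(meta$class_label)
  if (any(counts < 2)) {
    stop(sprintf(
      "class '%s' has fewer than 2 samples",
      names(counts)[which(counts < 2)[1]]
    ), call. = FALSE)
  }
  if (!is.null(expr)) {
    missing_s <- setdiff(colnames(expr), meta$sample_id)
    if (length(missing_s) > 0) {
      stop(sprintf("sample '%s' absent from metadata", missing_s[1]), call. = FALSE)
    }
  }
  invisible(meta)
}

#' Write sample metadata
#'
#' @param meta Tibble with `sample_id`, `class_label` and optional `replicate`.
#' @param path Output file path.
#' @param delimiter Field separator (default TAB).
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path, delimiter = "\t") {
  utils::write.table(meta, path,
    sep = delimiter, quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Z-score normalize an expression matrix
#'
#' Standardizes each gene (row) to mean 0 and population standard deviation 1
#' across samples. Constant genes are mapped to all-zero rows rather than
#' dropped, so gene indexing stays stable through the pipeline.
#'
#' @param m Numeric genes x samples matrix.
#' @return A matrix of the same shape and dimnames.
#' @export
zscore_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix", call. = FALSE)
  if (ncol(m) < 2) {
    stop("z-scoring needs at least 2 samples (sd undefined for one)", call. = FALSE)
  }
  mu <- rowMeans(m)
  centered <- m - mu
  s <- sqrt(rowMeans(centered^2)) # population sd
  constant <- s < .Machine$double.eps * 100
  s[constant] <- 1
  out <- centered / s
  out[constant, ] <- 0
  out
}

#' Read a per-gene network-score table
#'
#' Expects columns `gene_id`, `GS` (gene significance, absolute trait
#' correlation in \[0, 1\]), `MM` (module membership, eigengene correlation in
#' \[-1, 1\]) and `module`.
#'
#' @param path Path to delimited text.
#' @param delimiter Field separator (default TAB).
#' @param expr Optional companion expression matrix; genes in the table but
#'   absent from the matrix trigger a warning (rows are kept).
#' @return A tibble with columns `gene_id`, `GS`, `MM`, `module`.
#' @export
read_network_scores <- function(path, delimiter = "\t", expr = NULL) {
  df <- utils::read.table(path,
    header = TRUE, sep = delimiter,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  need <- c("gene_id", "GS", "MM", "module")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("network-score table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  scores <- tibble::tibble(
    gene_id = as.character(df$gene_id),
    GS = as.numeric(df$GS),
    MM = as.numeric(df$MM),
    module = as.character(df$module)
  )
  validate_network_scores(scores)
  if (!is.null(expr)) {
    extra <- setdiff(scores$gene_id, rownames(expr))
    if (length(extra) > 0) {
      warning(sprintf(
        "%d network-score gene(s) absent from the expression matrix (e.g. %s); rows kept",
        length(extra), extra[1]
      ), call. = FALSE)
    }
  }
  scores
}

validate_network_scores <- function(scores) {
  if (anyDuplicated(scores$gene_id)) stop("duplicate gene_id in network scores", call. = FALSE)
  if (any(scores$GS < 0 | scores$GS > 1 | !is.finite(scores$GS))) {
    bad <- scores$gene_id[which(scores$GS < 0 | scores$GS > 1 | !is.finite(scores$GS))[1]]
    stop(sprintf("GS outside [0, 1] for gene %s", bad), call. = FALSE)
  }
  if (any(abs(scores$MM) > 1 | !is.finite(scores$MM))) {
    bad <- scores$gene_id[which(abs(scores$MM) > 1 | !is.finite(scores$MM))[1]]
    stop(sprintf("MM outside [-1, 1] for gene %s", bad), call. = FALSE)
  }
  invisible(scores)
}

#' Write a network-score table
#'
#' @param scores Tibble as returned by [read_network_scores()].
#' @param path Output file path.
#' @param delimiter Field separator (default TAB).
#' @return `path`, invisibly.
#' @export
write_network_scores <- function(scores, path, delimiter = "\t") {
  validate_network_scores(scores)
  utils::write.table(scores, path,
    sep = delimiter, quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
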