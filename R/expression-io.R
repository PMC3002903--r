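#' Read and write expression matrices as TSV
#'
#' The on-disk format is tab-separated text with a header row of sample
#' identifiers and gene identifiers in the first column. `write_expression()`
#' rounds to `digits` significant digits (default 6); a matrix written and
#' re-read is equal within that formatting precision.
#'
#' @param path File path.
#' @param mode Measurement scale; see [as_expr_mat()].
#' @return `read_expression()` returns an [as_expr_mat()] tibble.
#' @export
read_expression <- function(path, mode = c("log_expression", "log_ratio")) {
  mode <- match.arg(mode)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  if (ncol(df) < 2L) abort(paste0("Malformed expression file (", path, "): need gene + sample columns."))
  vals <- df[-1L]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1L))]
  if (length(bad) > 0L) {
    abort(paste0("Non-numeric cells in column(s) ", paste(bad, collapse = ", "), " of ", path))
  }
  names(df)[1L] <- "gene_id"
  as_expr_mat(df, mode = mode)
}

#' @rdname read_expression
#' @param x An `expr_mat`.
#' @param digits Significant digits used when formatting values.
#' @export
write_expression <- function(x, path, digits = 6L) {
  stopifnot(is_expr_mat(x))
  out <- x
  out[-1L] <- lapply(out[-1L], signif, digits = digits)
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Read and write sample-to-condition maps
#'
#' Two-column TSV: `sample_id`, `condition`.
#'
#' @param path File path.
#' @return A [condition_map()] tibble.
#' @export
read_condition_map <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE, show_col_types = FALSE)
  if (!all(c("sample_id", "condition") %in% names(df))) {
    names(df)[1:2] <- c("sample_id", "condition")
  }
  condition_map(df$sample_id, df$condition)
}

#' @rdname read_condition_map
#' @param map A condition map tibble.
#' @export
write_condition_map <- function(map, path) {
  readr::write_tsv(map[c("sample_id", "condition")], path, progress = FALSE)
  invisible(path)
}

#' Quantile normalization across samples and batches
#'
#' Forces every sample (column) to share the same empirical distribution —
#' the mean of the sorted columns — so that cross-batch location/scale
#' differences are removed while within-sample gene ranks are preserved.
#' Given a list of matrices (batches normalized separately upstream), the
#' batches are normalized jointly against a common reference and returned as
#' a list. Ties within a sample receive the mean of the corresponding
#' reference quantiles.
#'
#' The transform is idempotent and equalizes column means exactly.
#'
#' @param x An `expr_mat`, or a list of `expr_mat`s sharing an identical
#'   gene set (same order).
#' @return Object of the same shape as `x`, quantile-normalized.
#' @examples
#' m1 <- as_expr_mat(data.frame(gene_id = c("a", "b", "c"), s1 = c(1, 2, 3)))
#' m2 <- as_expr_mat(data.frame(gene_id = c("a", "b", "c"), s2 = c(4, 5, 6)))
#' quantile_normalize(list(m1, m2))
#' @export
quantile_normalize <- function(x) {
  single <- is_expr_mat(x)
  mats <- if (single) list(x) else x
  if (length(mats) == 0L) abort("Empty input.")
  if (!all(vapply(mats, is_expr_mat, logical(1L)))) {
    abort("All elements must be expression matrices (see as_expr_mat()).")
  }
  modes <- vapply(mats, expr_mode, character(1L))
  if (any(modes != "log_expression")) {
    abort("Quantile normalization is defined for log_expression mode only.")
  }
  genes <- expr_genes(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(expr_genes(m), genes)) abort("All matrices must share the same gene set, in the same order.")
  }
  values <- do.call(cbind, lapply(mats, expr_values))
  if (ncol(values) > 1L) {
    norm <- limma::normalizeQuantiles(values, ties = TRUE)
    dimnames(norm) <- dimnames(values)
  } else {
    norm <- values  # single sample: nothing to equalize against
  }
  sizes <- vapply(mats, function(m) length(expr_samples(m)), integer(1L))
  idx <- split(seq_len(ncol(norm)), rep(seq_along(mats), sizes))
  out <- lapply(seq_along(mats), function(i) {
    new_expr_mat_from_values(norm[, idx[[i]], drop = FALSE], mode = "log_expression")
  })
  if (single) out[[1L]] else out
}
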