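#' Expression matrix container
#'
#' An expression matrix is a tibble whose first column, `gene_id`, holds
#' unique gene (probe set) identifiers and whose remaining columns hold
#' finite numeric log-scale values, one column per sample. The `mode`
#' attribute records the measurement scale:
#'
#' * `"log_expression"` — single-color log2 expression (e.g. GCRMA-style
#'   output), strictly interpretable as log-abundance;
#' * `"log_ratio"` — two-color log ratio against a common reference pool,
#'   which may be negative.
#'
#' @param x A data frame with a `gene_id` column (or gene identifiers in the
#'   first column) and numeric sample columns.
#' @param mode Measurement scale, `"log_expression"` or `"log_ratio"`.
#' @return A tibble of class `expr_mat` with attribute `mode`.
#' @examples
#' m <- as_expr_mat(
#'   data.frame(gene_id = c("g1", "g2"), s1 = c(7.1, 8.2), s2 = c(7.3, 8.0))
#' )
#' expr_mode(m)
#' @export
as_expr_mat <- function(x, mode = c("log_expression", "log_ratio")) {
  mode <- match.arg(mode)
  x <- as_tibble(x)
  if (ncol(x) < 2L) {
    abort("An expression matrix needs a gene column plus at least one sample column.")
  }
  if (!"gene_id" %in% names(x)) names(x)[1L] <- "gene_id"
  x <- dplyr::relocate(x, "gene_id")
  x$gene_id <- as.character(x$gene_id)
  vals <- x[-1L]
  if (!all(vapply(vals, is.numeric, logical(1L)))) {
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1L))]
    abort(paste0("Non-numeric sample column(s): ", paste(bad, collapse = ", ")))
  }
  if (anyNA(x$gene_id) || any(x$gene_id == "")) abort("Missing gene identifiers.")
  if (anyDuplicated(x$gene_id)) {
    dup <- unique(x$gene_id[duplicated(x$gene_id)])
    abort(paste0("Duplicate gene identifier(s): ", paste(head(dup, 5L), collapse = ", ")))
  }
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1L)))) {
    abort("Expression values must be finite (no NA/NaN/Inf).")
  }
  structure(x, mode = mode, class = c("expr_mat", class(x)))
}

#' @rdname as_expr_mat
#' @export
is_expr_mat <- function(x) inherits(x, "expr_mat")

#' @rdname as_expr_mat
#' @export
expr_mode <- function(x) {
  attr(x, "mode") %||% "log_expression"
}

#' Extract the numeric value matrix of an expression matrix
#'
#' @param x An `expr_mat` (or any tibble with a `gene_id` first column).
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @export
expr_values <- function(x) {
  m <- as.matrix(as.data.frame(x[-1L]))
  rownames(m) <- x$gene_id
  m
}

#' @rdname expr_values
#' @export
expr_genes <- function(x) x$gene_id

#' @rdname expr_values
#' @export
expr_samples <- function(x) names(x)[-1L]

# Rebuild an expr_mat from a value matrix, preserving mode.
new_expr_mat_from_values <- function(values, mode) {
  as_expr_mat(
    tibble(gene_id = rownames(values), as_tibble(values)),
    mode = mode
  )
}

#' Condition map constructor
#'
#' A condition map pairs each sample identifier with the experimental
#' condition under which it was collected.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param condition Vector of condition labels, recycled against `sample_id`
#'   if of length one.
#' @return A tibble with columns `sample_id` and `condition`.
#' @export
condition_map <- function(sample_id, condition) {
  if (length(condition) == 1L) condition <- rep(condition, length(sample_id))
  if (length(sample_id) != length(condition)) {
    abort("`sample_id` and `condition` must have equal length.")
  }
  if (anyDuplicated(sample_id)) abort("Duplicate sample_id in condition map.")
  tibble(sample_id = as.character(sample_id), condition = as.character(condition))
}

# Align a condition map against an expr_mat; every sample must appear once.
match_conditions <- function(x, conditions) {
  samples <- expr_samples(x)
  if (!all(samples %in% conditions$sample_id)) {
    missing <- setdiff(samples, conditions$sample_id)
    abort(paste0("Samples missing from condition map: ", paste(head(missing, 5L), collapse = ", ")))
  }
  conditions$condition[match(samples, conditions$sample_id)]
}
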