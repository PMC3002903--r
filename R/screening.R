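#' Kruskal-Wallis test of a single gene across conditions
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected mid-ranks,
#' chi-square approximation with `k - 1` degrees of freedom) returning the
#' statistic and p-value as a one-row tibble.
#'
#' @param values_by_group A list of numeric vectors (one per condition), or
#'   a numeric vector when `groups` is given.
#' @param groups Optional grouping factor matching `values_by_group`.
#' @return A one-row tibble: `statistic` (H), `p_value`, `df`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H ~= 3.857
#' @export
kruskal_wallis <- function(values_by_group, groups = NULL) {
  if (is.list(values_by_group)) {
    if (length(values_by_group) < 2L) abort("Need at least 2 groups.")
    if (any(lengths(values_by_group) == 0L)) abort("Empty group supplied.")
    kt <- kruskal.test(values_by_group)
  } else {
    if (is.null(groups)) abort("Supply a list of vectors, or values plus groups.")
    if (length(unique(groups)) < 2L) abort("Need at least 2 groups.")
    kt <- kruskal.test(values_by_group, g = as.factor(groups))
  }
  tibble(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
         df = unname(kt$parameter))
}

#' Screen for genes unaffected by experimental conditions
#'
#' Applies the Kruskal-Wallis test to each gene across the condition groups
#' and retains genes whose p-value exceeds `alpha` (a deliberately liberal
#' default of 0.1): the retained set is the genes for which there is no
#' evidence that any condition shifted their expression, the population on
#' which the distributional characterization is performed.
#'
#' @param x An `expr_mat` of log-scale values.
#' @param conditions A [condition_map()] covering every sample of `x`.
#' @param alpha Retention cutoff: genes with `p_value > alpha` are retained.
#' @return A tibble with one row per gene: `gene_id`, `statistic`,
#'   `p_value`, `retained`. With a single condition the test is undefined:
#'   all genes are retained with `NA` statistics and a warning.
#' @export
screen_unaffected <- function(x, conditions, alpha = 0.1) {
  stopifnot(is_expr_mat(x))
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1].")
  g <- as.factor(match_conditions(x, conditions))
  genes <- expr_genes(x)
  if (nlevels(g) < 2L) {
    warn("Single condition: Kruskal-Wallis is undefined; retaining all genes.")
    return(tibble(gene_id = genes, statistic = NA_real_, p_value = NA_real_,
                  retained = TRUE))
  }
  vals <- expr_values(x)
  res <- apply(vals, 1L, function(v) {
    kt <- kruskal.test(v, g = g)
    c(kt$statistic, kt$p.value)
  })
  out <- tibble(gene_id = genes, statistic = res[1L, ], p_value = res[2L, ],
                retained = res[2L, ] > alpha)
  inform(sprintf("screen_unaffected: %d/%d genes retained at alpha = %g.",
                 sum(out$retained), nrow(out), alpha))
  out
}

#' Partition genes into signal and noise strata by a mean-expression floor
#'
#' Low-intensity measurements behave as optical noise (single-color) or
#' unstable ratios (two-color) and show inflated higher moments. Genes are
#' assigned to the signal stratum when the per-gene mean strictly exceeds
#' the floor: `mean > cutoff` for log-expression data, `|mean| > cutoff`
#' for log-ratio data; everything else (including means exactly at the
#' cutoff) is the noise stratum.
#'
#' @param moments A per-gene tibble with columns `gene_id` and `mean`
#'   (e.g. from [moment_summary()]).
#' @param mode `"log_expression"` or `"log_ratio"`.
#' @param cutoff The floor; defaults to 6 (log-expression) or 0.05
#'   (absolute log-ratio).
#' @return `moments` with an added `stratum` column (`"signal"`/`"noise"`).
#' @export
noise_floor_filter <- function(moments, mode = c("log_expression", "log_ratio"),
                               cutoff = NULL) {
  mode <- match.arg(mode)
  if (!all(c("gene_id", "mean") %in% names(moments))) {
    abort("moments must have gene_id and mean columns.")
  }
  cutoff <- cutoff %||% if (mode == "log_expression") 6 else 0.05
  crit <- if (mode == "log_expression") moments$mean else abs(moments$mean)
  dplyr::mutate(as_tibble(moments),
                stratum = ifelse(crit > cutoff, "signal", "noise"))
}

#' Expand an active-gene set by Pearson correlation
#'
#' For two-color data, grows a seed set of transcriptionally active genes by
#' adding every gene whose Pearson correlation with at least one seed gene
#' is significant at `p_cutoff` (two-sided p-value from the t
#' transformation `t = r sqrt((n-2)/(1-r^2))`).
#'
#' @param x An `expr_mat`.
#' @param seed_genes Nonempty character vector of seed gene ids.
#' @param p_cutoff Two-sided p-value threshold (default `1e-5`).
#' @return Character vector: the union of `seed_genes` and the correlated
#'   genes, in matrix order.
#' @export
expand_active <- function(x, seed_genes, p_cutoff = 1e-5) {
  stopifnot(is_expr_mat(x))
  if (length(seed_genes) == 0L) abort("seed_genes must be nonempty.")
  genes <- expr_genes(x)
  if (!all(seed_genes %in% genes)) abort("Unknown seed gene id(s).")
  vals <- expr_values(x)
  n <- ncol(vals)
  if (n < 3L) abort("Need at least 3 samples for correlation p-values.")
  others <- setdiff(genes, seed_genes)
  if (length(others) == 0L) return(genes)
  r <- cor(t(vals[others, , drop = FALSE]), t(vals[seed_genes, , drop = FALSE]))
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  hit <- others[apply(p < p_cutoff, 1L, any)]
  genes[genes %in% c(seed_genes, hit)]
}
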