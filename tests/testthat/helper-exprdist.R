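# shared fixtures, all built in code

# wrap a plain numeric matrix as an expr_mat
make_mat <- function(values, mode = "log_expression", genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  as_expr_mat(tibble::tibble(gene_id = genes, tibble::as_tibble(values)),
              mode = mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small null study: normal genes, no condition effects
null_sim <- function(n_genes = 100, n_per_group = 10, n_groups = 3, seed = 42,
                     affected_fraction = 0, noise_fraction = 0,
                     mixture_fraction = 0, ...) {
  counts <- stats::setNames(rep(n_per_group, n_groups), LETTERS[seq_len(n_groups)])
  simulate_expression(synthetic_spec(
    n_genes = n_genes, conditions = counts,
    affected_fraction = affected_fraction, noise_fraction = noise_fraction,
    mixture_fraction = mixture_fraction, seed = seed, ...
  ))
}
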