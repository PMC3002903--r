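#' Parametric-bootstrap goodness-of-fit test with estimated parameters
#'
#' Calibrates the KS/AD statistics under the composite null (parameters
#' estimated from the tested data) by the Lilliefors-style parametric
#' bootstrap: fit the family by ML, compute the observed statistic, then
#' for each of `B` replicates simulate `n` draws from the fitted
#' distribution, refit, and recompute the statistic. The p-value is
#' `(1 + #\{bootstrap >= observed\}) / (B + 1)`, which cannot be zero.
#' Rejection flags are reported at both the 90% and 95% confidence levels.
#'
#' For the normal and lognormal families the refit and statistic are
#' computed in closed form for all replicates at once; other families refit
#' per replicate.
#'
#' @param values Numeric data vector.
#' @param family One of [dist_families()].
#' @param stats Statistics to compute: subset of `c("ad", "ks")`.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Optional integer seed.
#' @param gumbel Extreme-value orientation, see [fit_mle()].
#' @return A tibble with one row per statistic: `family`, `statistic`,
#'   `value`, `p_value`, `reject_90`, `reject_95`, `B`, `n`, `seed`.
#' @examples
#' bootstrap_gof(rnorm(50), "normal", B = 200, seed = 1)
#' @export
bootstrap_gof <- function(values, family = dist_families(),
                          stats = c("ad", "ks"), B = 1000L, seed = NULL,
                          gumbel = c("min", "max")) {
  family <- match.arg(family)
  gumbel <- match.arg(gumbel)
  stats <- match.arg(stats, c("ad", "ks"), several.ok = TRUE)
  if (B < 100L) abort("B must be at least 100 for a usable bootstrap p-value.")
  x <- as.numeric(values)
  n <- length(x)
  fit <- fit_mle(x, family, gumbel = gumbel)
  cdf <- dist_cdf(fit)
  obs <- c(ad = if ("ad" %in% stats) ad_statistic(x, cdf) else NA_real_,
           ks = if ("ks" %in% stats) ks_statistic(x, cdf) else NA_real_)

  if (!is.null(seed)) withr::local_seed(seed)

  boot <- if (family %in% c("normal", "lognormal")) {
    # location-scale in (log-)space: null distribution of the statistic is
    # parameter-free, so simulate standard normals and standardize by the
    # per-column MLE.
    m <- matrix(rnorm(n * B), n, B)
    mu <- colMeans(m)
    s <- sqrt(colMeans(m^2) - mu^2)
    u <- pnorm((m - rep(mu, each = n)) / rep(s, each = n))
    u <- apply(u, 2L, sort)
    column_gof_stats(u, stats)
  } else {
    res <- matrix(NA_real_, B, 2L, dimnames = list(NULL, c("ad", "ks")))
    for (b in seq_len(B)) {
      xb <- dist_rand(fit, n)
      fb <- tryCatch(fit_mle(xb, family, gumbel = gumbel), error = function(e) NULL)
      if (is.null(fb)) {
        res[b, ] <- Inf  # degenerate replicate counts against the null
        next
      }
      cb <- dist_cdf(fb)
      if ("ad" %in% stats) res[b, "ad"] <- ad_statistic(xb, cb)
      if ("ks" %in% stats) res[b, "ks"] <- ks_statistic(xb, cb)
    }
    list(ad = res[, "ad"], ks = res[, "ks"])
  }

  rows <- lapply(stats, function(st) {
    p <- (1 + sum(boot[[st]] >= obs[[st]])) / (B + 1)
    tibble(family = family, statistic = st, value = obs[[st]],
           p_value = p, reject_90 = p <= 0.10, reject_95 = p <= 0.05,
           B = as.integer(B), n = n,
           seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
  dplyr::bind_rows(rows)
}

#' Batch goodness-of-fit testing over an expression matrix
#'
#' Runs [bootstrap_gof()] for every requested gene and family and summarizes
#' rejection fractions per family at the 95% level, together with the
#' fraction of genes for which at least one family is not rejected.
#' Positive-support families are not applicable to log-ratio data (which can
#' be negative) and are recorded as `NA` rows rather than being tested.
#'
#' Per-gene bootstrap seeds are derived as `seed + gene index` so results
#' are reproducible and independent of iteration order.
#'
#' @param x An `expr_mat`.
#' @param genes Optional character vector of gene ids to test (default all).
#' @param families Families to test.
#' @param stats Statistics, subset of `c("ad", "ks")`.
#' @param B Bootstrap replicates per gene and family.
#' @param seed Master integer seed.
#' @return A list of class `gof_batch`: `results` (per gene/family/statistic
#'   tibble) and `summary` (per family/statistic rejection fractions, with an
#'   `any_not_rejected` attribute column family = "(any)").
#' @export
batch_gof <- function(x, genes = NULL, families = "normal",
                      stats = "ad", B = 1000L, seed = 1L) {
  stopifnot(is_expr_mat(x))
  families <- vapply(families, function(f) match.arg(f, dist_families()), character(1L))
  stats <- match.arg(stats, c("ad", "ks"), several.ok = TRUE)
  genes <- genes %||% expr_genes(x)
  if (length(genes) == 0L) abort("Empty gene set.")
  if (!all(genes %in% expr_genes(x))) abort("Unknown gene id(s) requested.")
  vals <- expr_values(x)[genes, , drop = FALSE]
  log_ratio <- expr_mode(x) == "log_ratio"

  rows <- vector("list", length(genes) * length(families))
  k <- 0L
  for (i in seq_along(genes)) {
    xi <- vals[i, ]
    gene_seed <- as.integer((as.numeric(seed) + i) %% .Machine$integer.max)
    for (fam in families) {
      k <- k + 1L
      if (family_requires_positive(fam) && (log_ratio || any(xi <= 0))) {
        rows[[k]] <- tibble(gene_id = genes[i], family = fam, statistic = stats,
                            value = NA_real_, p_value = NA_real_,
                            reject_90 = NA, reject_95 = NA,
                            B = as.integer(B), n = length(xi),
                            seed = gene_seed)
        next
      }
      r <- bootstrap_gof(xi, fam, stats = stats, B = B, seed = gene_seed)
      rows[[k]] <- dplyr::mutate(r, gene_id = genes[i], .before = 1L)
    }
  }
  results <- dplyr::bind_rows(rows)

  summary <- results |>
    dplyr::group_by(.data$family, .data$statistic) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_tested = sum(!is.na(.data$p_value)),
      frac_rejected_95 = mean(.data$reject_95[!is.na(.data$p_value)]),
      frac_rejected_90 = mean(.data$reject_90[!is.na(.data$p_value)]),
      .groups = "drop"
    )
  any_ok <- results |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::group_by(.data$gene_id, .data$statistic) |>
    dplyr::summarise(ok = any(!.data$reject_95), .groups = "drop") |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(frac_any_not_rejected_95 = mean(.data$ok), .groups = "drop")

  structure(list(results = results, summary = summary,
                 any_not_rejected = any_ok),
            class = "gof_batch")
}

#' @export
print.gof_batch <- function(x, ...) {
  cat("<gof_batch>", dplyr::n_distinct(x$results$gene_id), "genes\n")
  print(x$summary)
  print(x$any_not_rejected)
  invisible(x)
}

#' Chi-square goodness-of-fit with equal-probability bins
#'
#' Bins the data into `bins` cells of equal probability under the fitted
#' model (bin edges at the model quantiles), computes
#' \eqn{\chi^2 = \sum (O - E)^2 / E}, and evaluates it against a chi-square
#' distribution with `bins - 1 - n_params` degrees of freedom, the
#' conventional correction when parameters are estimated from the data.
#'
#' @param values Numeric data vector.
#' @param fit A `dist_fit` or `mixture_fit`, or `NULL` when `quantile_fun`
#'   and `n_params` are supplied directly.
#' @param bins Number of equal-probability bins; default
#'   `min(25, max(4, floor(n / 10)))`, constrained so expected counts are
#'   at least 5 and the degrees of freedom at least 1.
#' @param quantile_fun Optional quantile function overriding `fit`.
#' @param n_params Number of estimated parameters (required with
#'   `quantile_fun`; a k-component mixture counts `3k - 1`).
#' @return A one-row tibble: `statistic`, `df`, `bins`, `p_value`,
#'   `reject_90`, `reject_95`, `n`.
#' @examples
#' x <- rnorm(200)
#' chisq_gof(x, fit_mle(x, "normal"))
#' @export
chisq_gof <- function(values, fit = NULL, bins = NULL,
                      quantile_fun = NULL, n_params = NULL) {
  x <- as.numeric(values)
  n <- length(x)
  if (is.null(quantile_fun)) {
    if (is.null(fit)) abort("Supply a fitted model or a quantile function.")
    if (inherits(fit, "mixture_fit")) {
      quantile_fun <- mixture_quantile(fit)
      n_params <- 3L * fit$k - 1L
    } else {
      quantile_fun <- dist_quantile(fit)
      n_params <- length(fit$params)
    }
  } else if (is.null(n_params)) {
    abort("n_params is required when quantile_fun is supplied.")
  }
  if (is.null(bins)) bins <- min(25L, max(4L, floor(n / 10)))
  if (bins < 4L) abort("Need at least 4 bins.")
  if (n / bins < 5) abort("Too few data for >= 5 expected counts per bin.")
  df <- bins - 1L - n_params
  if (df < 1L) abort("Degrees of freedom would be < 1; use more bins or fewer parameters.")
  edges <- quantile_fun((1:(bins - 1L)) / bins)
  observed <- tabulate(findInterval(x, edges) + 1L, nbins = bins)
  expected <- n / bins
  stat <- sum((observed - expected)^2 / expected)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  tibble(statistic = stat, df = as.integer(df), bins = as.integer(bins),
         p_value = p, reject_90 = p <= 0.10, reject_95 = p <= 0.05, n = n)
}
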