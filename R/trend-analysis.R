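#' Linear trend of log10(CV) against mean expression
#'
#' Ordinary least squares of `log10(cv)` on `mean` over the signal-stratum
#' genes, the empirical regularity that the relative dispersion of
#' log-expression decreases with abundance. Genes with nonpositive CV (or
#' degenerate rows) are excluded and counted.
#'
#' @param moments A per-gene tibble with at least `mean` and `cv`; if a
#'   `stratum` column is present (see [noise_floor_filter()]) only
#'   `"signal"` rows are used.
#' @return A `trend_fit` object wrapping the [stats::lm()] fit, with
#'   `model = "linear_logcv_mean"`, the coefficient table, `r_squared`,
#'   the overall F-test p-value, `n`, and `n_excluded`.
#' @export
fit_log_cv_vs_mean <- function(moments) {
  d <- as_tibble(moments)
  if ("stratum" %in% names(d)) d <- dplyr::filter(d, .data$stratum == "signal")
  usable <- is.finite(d$cv) & d$cv > 0 & is.finite(d$mean)
  n_excluded <- sum(!usable)
  d <- d[usable, ]
  if (nrow(d) < 3L) abort("Need at least 3 signal-stratum genes with positive CV.")
  if (n_excluded > 0L) {
    inform(sprintf("fit_log_cv_vs_mean: excluded %d gene(s) with nonpositive CV.",
                   n_excluded))
  }
  fit <- lm(log10(cv) ~ mean, data = d)
  new_trend_fit(fit, "linear_logcv_mean", d, n_excluded = n_excluded)
}

#' Quadratic trend of kurtosis against skewness
#'
#' Ordinary least squares of plug-in kurtosis `K` on `(1, S, S^2)` over the
#' signal stratum. Because plug-in sample moments obey `K >= S^2 + 1`
#' exactly, the reported `bound_violations` count is expected to be zero on
#' any input produced by [product_moments()]/[moment_summary()].
#'
#' @param moments Per-gene tibble with `skewness` and `kurtosis` (plus
#'   optional `stratum`).
#' @return A `trend_fit` with `model = "quadratic_kurt_skew"` and a
#'   `bound_violations` element.
#' @export
fit_kurt_vs_skew <- function(moments) {
  d <- as_tibble(moments)
  if ("stratum" %in% names(d)) d <- dplyr::filter(d, .data$stratum == "signal")
  usable <- is.finite(d$skewness) & is.finite(d$kurtosis)
  d <- d[usable, ]
  if (nrow(d) < 4L) abort("Need at least 4 signal-stratum genes.")
  fit <- lm(kurtosis ~ skewness + I(skewness^2), data = d)
  violations <- sum(d$kurtosis < kurtosis_lower_bound(d$skewness) - 1e-10)
  new_trend_fit(fit, "quadratic_kurt_skew", d, bound_violations = violations)
}

new_trend_fit <- function(fit, model, data, ...) {
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(
    list(
      model = model,
      fit = fit,
      coefficients = tibble(
        term = rownames(sm$coefficients),
        estimate = unname(sm$coefficients[, "Estimate"]),
        std_error = unname(sm$coefficients[, "Std. Error"]),
        t_value = unname(sm$coefficients[, "t value"]),
        p_value = unname(sm$coefficients[, "Pr(>|t|)"])
      ),
      r_squared = sm$r.squared,
      f_p_value = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                   lower.tail = FALSE)),
      n = nrow(data),
      data = data,
      ...
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit>", x$model, " n =", x$n, "\n")
  print(x$coefficients)
  cat("R^2 =", format(x$r_squared, digits = 4),
      " F-test p =", format(x$f_p_value, digits = 4), "\n")
  if (!is.null(x$bound_violations)) {
    cat("kurtosis bound violations:", x$bound_violations, "\n")
  }
  invisible(x)
}

#' Loess-style smooth on an even grid
#'
#' Local linear regression with tricube weights over the `span` fraction of
#' nearest neighbors, evaluated on an even grid over `range(x)` — no
#' robustness iterations. In the pipeline this describes the noise-stratum
#' moment trends, where no parametric form is assumed. Windows containing
#' fewer than two distinct design points are widened with a warning.
#'
#' @param x,y Numeric vectors (at least 10 points).
#' @param span Smoothing span in (0, 1]: fraction of points in each window.
#' @param n_grid Number of grid points.
#' @return A tibble with columns `x` and `fitted`.
#' @export
loess_smooth <- function(x, y, span = 0.75, n_grid = 100L) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) abort("Need at least 10 finite points.")
  if (span <= 0 || span > 1) abort("span must be in (0, 1].")
  q <- max(3L, floor(span * n))
  grid <- seq(min(x), max(x), length.out = n_grid)
  fitted <- vapply(grid, function(x0) {
    d <- abs(x - x0)
    dmax <- sort(d)[q]
    if (dmax == 0 || sum(d < dmax & !duplicated(x)) < 2L) {
      warn("loess_smooth: widened a degenerate window.")
      dmax <- max(sort(unique(d))[min(q, length(unique(d)))], max(d) * 1e-8)
    }
    w <- (1 - pmin(d / dmax, 1)^3)^3
    tricube_local_linear(x, y, w, x0)
  }, numeric(1L))
  tibble(x = grid, fitted = fitted)
}

# weighted least squares of y on (1, x), evaluated at x0
tricube_local_linear <- function(x, y, w, x0) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx < .Machine$double.eps * sw * max(1, mean(x^2))) return(yb)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  yb + slope * (x0 - xb)
}

#' Residual diagnostics of a trend fit
#'
#' Pearson correlation between the absolute residuals and each covariate —
#' a nonzero correlation indicates heteroscedasticity — plus a
#' bootstrap-calibrated normality goodness-of-fit p-value on the residuals.
#'
#' @param trend A `trend_fit`.
#' @param covariates Optional named list / data frame of per-gene numeric
#'   covariates aligned with the genes used in the fit; defaults to the
#'   model's predictor and response.
#' @param B Bootstrap replicates for the residual normality test.
#' @param seed Seed for the normality bootstrap.
#' @return A tibble with one row per covariate: `covariate`, `rho`,
#'   `normality_p` (same value in every row).
#' @export
residual_diagnostics <- function(trend, covariates = NULL, B = 200L, seed = 1L) {
  stopifnot(inherits(trend, "trend_fit"))
  res <- residuals(trend$fit)
  if (is.null(covariates)) {
    covariates <- switch(
      trend$model,
      linear_logcv_mean = list(mean = trend$data$mean,
                               log10_cv = log10(trend$data$cv)),
      quadratic_kurt_skew = list(skewness = trend$data$skewness,
                                 kurtosis = trend$data$kurtosis)
    )
  }
  covariates <- as.list(covariates)
  norm_p <- bootstrap_gof(res, "normal", stats = "ad", B = B, seed = seed)$p_value
  purrr::imap_dfr(covariates, function(v, nm) {
    tibble(covariate = nm, rho = cor(abs(res), v), normality_p = norm_p)
  })
}

#' Spearman rank correlation between per-gene mean and SD
#'
#' @param moments Per-gene tibble with `mean` and `sd` (>= 3 genes).
#' @return Scalar Spearman rho (mid-rank ties); `NA` with a warning when
#'   either variable has constant ranks.
#' @export
spearman_mean_sd <- function(moments) {
  d <- as_tibble(moments)
  if (nrow(d) < 3L) abort("Need at least 3 genes.")
  if (length(unique(d$mean)) < 2L || length(unique(d$sd)) < 2L) {
    warn("Constant ranks: Spearman correlation undefined.")
    return(NA_real_)
  }
  cor(d$mean, d$sd, method = "spearman")
}
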