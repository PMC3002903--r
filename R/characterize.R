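#' End-to-end distributional characterization of an expression matrix
#'
#' Convenience pipeline chaining the analysis stages: Kruskal-Wallis
#' screening for condition-unaffected genes, per-gene product and
#' L-moments, noise-floor stratification, the linear log10(CV)-vs-mean and
#' quadratic kurtosis-vs-skewness trend fits on the signal stratum, loess
#' smooths of the higher moments in the noise stratum, and the Spearman
#' mean-SD correlation.
#'
#' @param x An `expr_mat`.
#' @param conditions A [condition_map()]; with `NULL` screening is skipped
#'   and all genes are used.
#' @param alpha Kruskal-Wallis retention cutoff.
#' @param cutoff Noise-floor cutoff (see [noise_floor_filter()]).
#' @param loess_span Span of the noise-stratum loess smooths.
#' @return A list of class `expr_characterization`: `screen`, `moments`
#'   (retained genes, with `stratum`), `cv_trend`, `kurt_skew_trend`
#'   (`trend_fit`s, `NULL` when the signal stratum is too small),
#'   `noise_loess` (tibble of smoothed CV/skewness/kurtosis curves, `NULL`
#'   when the noise stratum is too small), and `spearman_rho`.
#' @export
characterize_expression <- function(x, conditions = NULL, alpha = 0.1,
                                    cutoff = NULL, loess_span = 0.75) {
  stopifnot(is_expr_mat(x))
  screen <- NULL
  keep <- expr_genes(x)
  if (!is.null(conditions)) {
    screen <- screen_unaffected(x, conditions, alpha = alpha)
    keep <- screen$gene_id[screen$retained]
  }
  if (length(keep) < 4L) abort("Fewer than 4 genes retained; nothing to characterize.")
  xr <- new_expr_mat_from_values(expr_values(x)[keep, , drop = FALSE],
                                 mode = expr_mode(x))
  moments <- moment_summary(xr) |>
    noise_floor_filter(mode = expr_mode(x), cutoff = cutoff)

  signal <- dplyr::filter(moments, .data$stratum == "signal")
  noise <- dplyr::filter(moments, .data$stratum == "noise")

  cv_trend <- if (nrow(signal) >= 3L) fit_log_cv_vs_mean(moments) else NULL
  ks_trend <- if (nrow(signal) >= 4L) fit_kurt_vs_skew(moments) else NULL

  noise_loess <- NULL
  if (nrow(noise) >= 10L) {
    pred <- if (expr_mode(x) == "log_ratio") abs(noise$mean) else noise$mean
    noise_loess <- dplyr::bind_rows(
      dplyr::mutate(loess_smooth(pred, noise$cv, span = loess_span), moment = "cv"),
      dplyr::mutate(loess_smooth(pred, noise$skewness, span = loess_span),
                    moment = "skewness"),
      dplyr::mutate(loess_smooth(pred, noise$kurtosis, span = loess_span),
                    moment = "kurtosis")
    )
  }

  structure(
    list(screen = screen, moments = moments, cv_trend = cv_trend,
         kurt_skew_trend = ks_trend, noise_loess = noise_loess,
         spearman_rho = spearman_mean_sd(moments)),
    class = "expr_characterization"
  )
}

#' @export
print.expr_characterization <- function(x, ...) {
  cat("<expr_characterization>\n")
  if (!is.null(x$screen)) {
    cat("screened:", sum(x$screen$retained), "of", nrow(x$screen),
        "genes retained\n")
  }
  cat("strata:", sum(x$moments$stratum == "signal"), "signal /",
      sum(x$moments$stratum == "noise"), "noise genes\n")
  if (!is.null(x$cv_trend)) {
    co <- x$cv_trend$coefficients$estimate
    cat(sprintf("log10(CV) trend: intercept %.3f, slope %.3f (R^2 %.2f)\n",
                co[1L], co[2L], x$cv_trend$r_squared))
  }
  if (!is.null(x$kurt_skew_trend)) {
    co <- x$kurt_skew_trend$coefficients$estimate
    cat(sprintf("K(S) trend: %.3f %+.3f S %+.3f S^2 (R^2 %.2f)\n",
                co[1L], co[2L], co[3L], x$kurt_skew_trend$r_squared))
  }
  cat(sprintf("Spearman rho(mean, sd): %.3f\n", x$spearman_rho))
  invisible(x)
}
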