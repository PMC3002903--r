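#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for fitted objects
#'
#' `tidy()` returns the per-term (or per-component) estimates as a tibble;
#' `glance()` returns a one-row model-level summary.
#'
#' @param x A `trend_fit`, `dist_fit`, `mixture_fit` or `gof_batch`.
#' @param ... Unused.
#' @return A tibble.
#' @name exprdist-tidiers
NULL

#' @rdname exprdist-tidiers
#' @export
tidy.trend_fit <- function(x, ...) x$coefficients

#' @rdname exprdist-tidiers
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(model = x$model, r_squared = x$r_squared, f_p_value = x$f_p_value,
         n = x$n,
         bound_violations = x$bound_violations %||% NA_integer_,
         n_excluded = x$n_excluded %||% NA_integer_)
}

#' @rdname exprdist-tidiers
#' @export
tidy.dist_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname exprdist-tidiers
#' @export
glance.dist_fit <- function(x, ...) {
  tibble(family = x$family, loglik = x$loglik, n = x$n, converged = x$converged)
}

#' @rdname exprdist-tidiers
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = seq_len(x$k), weight = x$weights, mean = x$means,
         sd = x$sds)
}

#' @rdname exprdist-tidiers
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, n = x$n, converged = x$converged)
}

#' @rdname exprdist-tidiers
#' @export
tidy.gof_batch <- function(x, ...) x$results

#' @rdname exprdist-tidiers
#' @export
glance.gof_batch <- function(x, ...) {
  dplyr::left_join(x$summary, x$any_not_rejected, by = "statistic")
}
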