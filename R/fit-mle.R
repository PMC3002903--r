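#' Maximum-likelihood fit of a candidate family
#'
#' Fits one of the candidate families to a vector of (log-scale) values by
#' maximum likelihood. Closed forms are used where they exist (normal,
#' lognormal, Pareto; log-logistic via the logistic fit of the log values),
#' Newton/profile iterations for gamma, Weibull and the extreme-value
#' family, and a direct likelihood optimization for the logistic.
#'
#' Positive-support families (lognormal, log-logistic, Weibull, gamma,
#' Pareto) require strictly positive data; the normal, logistic and
#' extreme-value families accept any finite values and are therefore the
#' ones applicable to two-color log-ratio data.
#'
#' @param values Numeric vector, length >= 3, no NA.
#' @param family One of [dist_families()].
#' @param gumbel For `family = "extreme_value"`: `"min"` (default) fits the
#'   minimum-type Gumbel, `"max"` the maximum-type.
#' @return A `dist_fit` object: list with elements `family`, `params`
#'   (named numeric), `loglik`, `n`, `converged`.
#' @examples
#' fit_mle(c(1, 2, 3), "normal")          # mean 2, sd sqrt(2/3)
#' fit_mle(c(1, 2, 4), "pareto")          # xmin 1, alpha 1/log(2)
#' @export
fit_mle <- function(values, family = dist_families(), gumbel = c("min", "max")) {
  family <- match.arg(family)
  gumbel <- match.arg(gumbel)
  x <- as.numeric(values)
  if (anyNA(x) || any(!is.finite(x))) abort("Values must be finite and non-missing.")
  n <- length(x)
  if (n < 3L) abort("Need at least 3 values to fit a distribution.")
  if (max(x) == min(x)) abort("Degenerate data: all values identical.")
  if (family_requires_positive(family) && any(x <= 0)) {
    abort(paste0("Family '", family, "' requires strictly positive data."))
  }

  converged <- TRUE
  params <- switch(
    family,
    normal = {
      m <- mean(x)
      c(mean = m, sd = sqrt(mean((x - m)^2)))
    },
    lognormal = {
      lx <- log(x)
      m <- mean(lx)
      c(meanlog = m, sdlog = sqrt(mean((lx - m)^2)))
    },
    logistic = fit_logistic_mle(x),
    loglogistic = {
      p <- fit_logistic_mle(log(x))
      c(location = unname(p["location"]), scale = unname(p["scale"]))
    },
    weibull = fit_weibull_profile(x),
    extreme_value = {
      if (gumbel == "min") {
        p <- fit_gumbel_max(-x)
        c(location = -unname(p["location"]), scale = unname(p["scale"]))
      } else {
        fit_gumbel_max(x)
      }
    },
    gamma = fit_gamma_newton(x),
    pareto = {
      xm <- min(x)
      slog <- sum(log(x / xm))
      if (slog <= 0) abort("Degenerate data for Pareto fit.")
      c(xmin = xm, alpha = n / slog)
    }
  )

  fit <- structure(
    list(family = family, params = params, loglik = NA_real_,
         n = n, converged = converged,
         gumbel = if (family == "extreme_value") gumbel else NULL),
    class = "dist_fit"
  )
  fit$loglik <- dist_loglik(fit, x)
  if (!is.finite(fit$loglik)) fit$converged <- FALSE
  fit
}

#' Log-likelihood, cdf, quantile function and sampler of a fitted family
#'
#' @param fit A `dist_fit` from [fit_mle()].
#' @param values Numeric vector at which to evaluate the log-likelihood.
#' @return `dist_loglik()`: scalar log-likelihood. `dist_cdf()` /
#'   `dist_quantile()`: a function of one argument. `dist_rand()`: `n`
#'   random draws.
#' @export
dist_loglik <- function(fit, values) {
  p <- fit$params
  x <- values
  switch(
    fit$family,
    normal = sum(dnorm(x, p[["mean"]], p[["sd"]], log = TRUE)),
    lognormal = sum(stats::dlnorm(x, p[["meanlog"]], p[["sdlog"]], log = TRUE)),
    logistic = ll_logistic(x, p[["location"]], p[["scale"]]),
    loglogistic = ll_logistic(log(x), p[["location"]], p[["scale"]]) - sum(log(x)),
    weibull = sum(stats::dweibull(x, p[["shape"]], p[["scale"]], log = TRUE)),
    extreme_value = if (identical(fit$gumbel, "max")) {
      ll_gumbel_max(x, p[["location"]], p[["scale"]])
    } else {
      ll_gumbel_min(x, p[["location"]], p[["scale"]])
    },
    gamma = sum(stats::dgamma(x, shape = p[["shape"]], scale = p[["scale"]], log = TRUE)),
    pareto = {
      if (any(x < p[["xmin"]])) -Inf
      else length(x) * (log(p[["alpha"]]) + p[["alpha"]] * log(p[["xmin"]])) -
        (p[["alpha"]] + 1) * sum(log(x))
    }
  )
}

#' @rdname dist_loglik
#' @export
dist_cdf <- function(fit) {
  p <- fit$params
  switch(
    fit$family,
    normal = function(q) pnorm(q, p[["mean"]], p[["sd"]]),
    lognormal = function(q) stats::plnorm(q, p[["meanlog"]], p[["sdlog"]]),
    logistic = function(q) plogis(q, p[["location"]], p[["scale"]]),
    loglogistic = function(q) ifelse(q <= 0, 0, plogis(log(pmax(q, .Machine$double.xmin)),
                                                       p[["location"]], p[["scale"]])),
    weibull = function(q) pweibull(q, p[["shape"]], p[["scale"]]),
    extreme_value = if (identical(fit$gumbel, "max")) {
      function(q) pgumbel_max(q, p[["location"]], p[["scale"]])
    } else {
      function(q) pgumbel_min(q, p[["location"]], p[["scale"]])
    },
    gamma = function(q) pgamma(q, shape = p[["shape"]], scale = p[["scale"]]),
    pareto = function(q) ifelse(q < p[["xmin"]], 0, 1 - (p[["xmin"]] / q)^p[["alpha"]])
  )
}

#' @rdname dist_loglik
#' @export
dist_quantile <- function(fit) {
  p <- fit$params
  switch(
    fit$family,
    normal = function(u) qnorm(u, p[["mean"]], p[["sd"]]),
    lognormal = function(u) stats::qlnorm(u, p[["meanlog"]], p[["sdlog"]]),
    logistic = function(u) qlogis(u, p[["location"]], p[["scale"]]),
    loglogistic = function(u) exp(qlogis(u, p[["location"]], p[["scale"]])),
    weibull = function(u) qweibull(u, p[["shape"]], p[["scale"]]),
    extreme_value = if (identical(fit$gumbel, "max")) {
      function(u) qgumbel_max(u, p[["location"]], p[["scale"]])
    } else {
      function(u) qgumbel_min(u, p[["location"]], p[["scale"]])
    },
    gamma = function(u) qgamma(u, shape = p[["shape"]], scale = p[["scale"]]),
    pareto = function(u) p[["xmin"]] * (1 - u)^(-1 / p[["alpha"]])
  )
}

#' @rdname dist_loglik
#' @param n Number of draws.
#' @export
dist_rand <- function(fit, n) {
  dist_quantile(fit)(runif(n))
}

#' @export
print.dist_fit <- function(x, ...) {
  cat("<dist_fit> family:", x$family, "\n")
  print(signif(x$params, 5))
  cat("loglik:", format(x$loglik), " n:", x$n,
      " converged:", x$converged, "\n")
  invisible(x)
}
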