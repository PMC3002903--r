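#' Fit a normal mixture by EM
#'
#' Fits a k-component univariate normal mixture by expectation-maximization
#' from k-means-style initializations, returning the best restart by
#' log-likelihood. Used to ask whether multimodal gene expression (e.g.
#' genetic segregation in an F2 cross) explains poor single-family fits.
#'
#' EM details: tolerance `1e-8` on the relative log-likelihood change, a
#' 1000-iteration cap (weakly separated components converge slowly, and an
#' unconverged fit biases downstream model comparisons), a component-SD
#' floor of `1e-6` times the data SD to
#' avoid variance collapse, and `n_restarts` seeded initializations (the
#' first from sorted k-means centers, the rest from random starts). With
#' `k = 1` the result equals the closed-form normal MLE.
#'
#' @param values Numeric vector, `length(values) >= 5 * k`.
#' @param k Number of components (>= 1).
#' @param n_restarts Number of EM restarts.
#' @param seed Optional integer seed making restarts reproducible.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return A `mixture_fit` object: list with `k`, `weights`, `means`, `sds`,
#'   `loglik`, `n`, `converged`, `loglik_trace` (of the best restart).
#' @examples
#' x <- c(rnorm(100, 0), rnorm(100, 10))
#' fit_mixture_em(x, k = 2, seed = 1)
#' @export
fit_mixture_em <- function(values, k, n_restarts = 5L, seed = NULL,
                           max_iter = 1000L, tol = 1e-8) {
  x <- as.numeric(values)
  if (anyNA(x) || any(!is.finite(x))) abort("Values must be finite and non-missing.")
  if (k < 1L) abort("k must be >= 1.")
  n <- length(x)
  if (n < 5L * k) abort("Need at least 5*k values to fit a k-component mixture.")
  if (max(x) == min(x)) abort("Degenerate data: all values identical.")

  if (k == 1L) {
    f <- fit_mle(x, "normal")
    return(structure(
      list(k = 1L, weights = 1, means = unname(f$params[["mean"]]),
           sds = unname(f$params[["sd"]]), loglik = f$loglik, n = n,
           converged = TRUE, loglik_trace = f$loglik),
      class = "mixture_fit"
    ))
  }

  if (!is.null(seed)) withr::local_seed(seed)
  sd_floor <- 1e-6 * sd(x)
  best <- NULL
  any_ok <- FALSE

  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) {
      km <- suppressWarnings(kmeans(x, centers = k, nstart = 3L))
      mu <- sort(as.numeric(km$centers))
      list(w = rep(1 / k, k), mu = mu, s = rep(max(sd(x) / k, sd_floor), k))
    } else {
      list(w = rep(1 / k, k), mu = sort(sample(x, k)),
           s = rep(max(sd(x), sd_floor) * runif(1, 0.3, 1), k))
    }
    fit <- em_normal_mixture(x, init$w, init$mu, init$s, sd_floor, max_iter, tol)
    if (is.null(fit)) next
    any_ok <- TRUE
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!any_ok) {
    return(structure(
      list(k = k, weights = rep(1 / k, k), means = rep(mean(x), k),
           sds = rep(sd(x), k), loglik = -Inf, n = n, converged = FALSE,
           loglik_trace = numeric(0)),
      class = "mixture_fit"
    ))
  }
  ord <- order(best$mu)
  structure(
    list(k = k, weights = best$w[ord], means = best$mu[ord], sds = best$s[ord],
         loglik = best$loglik, n = n, converged = best$converged,
         loglik_trace = best$trace),
    class = "mixture_fit"
  )
}

# One EM run; returns NULL on degeneracy.
em_normal_mixture <- function(x, w, mu, s, sd_floor, max_iter, tol) {
  n <- length(x)
  k <- length(mu)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]),
                   numeric(n))
    tot <- rowSums(dens)
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    s <- pmax(s, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # final log-likelihood at the updated parameters
  dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]), numeric(n))
  ll <- sum(log(rowSums(dens)))
  trace <- c(trace, ll)
  list(w = w, mu = mu, s = s, loglik = ll, converged = converged, trace = trace)
}

#' Mixture cdf and quantile function
#'
#' @param fit A `mixture_fit`.
#' @return A function of one argument.
#' @export
mixture_cdf <- function(fit) {
  function(q) {
    out <- 0
    for (j in seq_len(fit$k)) {
      out <- out + fit$weights[j] * pnorm(q, fit$means[j], fit$sds[j])
    }
    out
  }
}

#' @rdname mixture_cdf
#' @export
mixture_quantile <- function(fit) {
  cdf <- mixture_cdf(fit)
  lo0 <- min(fit$means - 10 * max(fit$sds))
  hi0 <- max(fit$means + 10 * max(fit$sds))
  function(u) {
    vapply(u, function(p) {
      lo <- lo0; hi <- hi0
      while (cdf(lo) > p) lo <- lo - (hi0 - lo0)
      while (cdf(hi) < p) hi <- hi + (hi0 - lo0)
      uniroot(function(z) cdf(z) - p, c(lo, hi), tol = 1e-10)$root
    }, numeric(1L))
  }
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> k =", x$k, " loglik =", format(x$loglik),
      " converged:", x$converged, "\n")
  print(tibble(component = seq_len(x$k), weight = x$weights,
               mean = x$means, sd = x$sds))
  invisible(x)
}
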