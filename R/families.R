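# Candidate univariate families for log-scale expression values.
#
# Each family is described by its support, cdf, quantile function, sampler
# and maximum-likelihood estimator. The extreme-value family is the
# minimum-type Gumbel by default (the convention of classical reliability
# fitting routines); the maximum-type is available via `gumbel = "max"`.

#' Candidate distribution families
#'
#' @return Character vector of the supported family names.
#' @export
dist_families <- function() {
  c("normal", "lognormal", "logistic", "loglogistic",
    "weibull", "extreme_value", "gamma", "pareto")
}

#' @rdname dist_families
#' @param family Family name.
#' @export
family_requires_positive <- function(family) {
  family <- match.arg(family, dist_families())
  family %in% c("lognormal", "loglogistic", "weibull", "gamma", "pareto")
}

# ---- Gumbel helpers (location-scale) ---------------------------------------

# Minimum-type Gumbel: F(x) = 1 - exp(-exp((x - location)/scale))
pgumbel_min <- function(q, location, scale) {
  1 - exp(-exp((q - location) / scale))
}
qgumbel_min <- function(p, location, scale) {
  location + scale * log(-log(1 - p))
}
rgumbel_min <- function(n, location, scale) {
  qgumbel_min(runif(n), location, scale)
}
# Maximum-type Gumbel: F(x) = exp(-exp(-(x - location)/scale))
pgumbel_max <- function(q, location, scale) {
  exp(-exp(-(q - location) / scale))
}
qgumbel_max <- function(p, location, scale) {
  location - scale * log(-log(p))
}

# log-likelihoods ------------------------------------------------------------

ll_gumbel_min <- function(x, location, scale) {
  z <- (x - location) / scale
  sum(z - exp(z)) - length(x) * log(scale)
}
ll_gumbel_max <- function(x, location, scale) {
  z <- (x - location) / scale
  sum(-z - exp(-z)) - length(x) * log(scale)
}
ll_logistic <- function(x, location, scale) {
  z <- (x - location) / scale
  sum(-z - 2 * log1p(exp(-z))) - length(x) * log(scale)
}

# Maximum-type Gumbel MLE via the profile-likelihood scale equation:
#   scale = mean(x) - sum(x * w) / sum(w),  w = exp(-x / scale)
fit_gumbel_max <- function(x) {
  xc <- x - mean(x)  # center so exponents can be shifted safely
  wmean <- function(b) {
    e <- -xc / b
    w <- exp(e - max(e))
    sum(xc * w) / sum(w)
  }
  # scale equation b = -weighted.mean(xc); g is negative at 0+, positive at Inf
  g <- function(b) b + wmean(b)
  lo <- sd(x) * 1e-3
  hi <- sd(x) * 2
  while (g(lo) > 0 && lo > sd(x) * 1e-12) lo <- lo / 10
  while (g(hi) < 0 && hi < sd(x) * 1e8) hi <- hi * 4
  b <- uniroot(g, c(lo, hi), tol = 1e-11)$root
  e <- -xc / b
  mu <- -b * (max(e) + log(mean(exp(e - max(e))))) + mean(x)
  c(location = mu, scale = b)
}

# Gamma shape MLE by Newton iteration on  log(k) - digamma(k) = s,
# s = log(mean(x)) - mean(log(x)); scale = mean(x)/shape.
fit_gamma_newton <- function(x, max_iter = 50L, tol = 1e-12) {
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) abort("Degenerate data for gamma fit (zero dispersion of log values).")
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # Minka-style initial value
  for (i in seq_len(max_iter)) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < tol * k) {
      k <- k_new
      break
    }
    k <- k_new
  }
  c(shape = k, scale = mean(x) / k)
}

# Weibull shape MLE: solve  sum(x^k log x)/sum(x^k) - 1/k - mean(log x) = 0.
# Powers are taken of y = x / max(x) <= 1 (the ratio is scale-invariant) so
# large shapes cannot overflow.
fit_weibull_profile <- function(x) {
  lx <- log(x)
  y <- x / max(x)
  g <- function(k) {
    yk <- y^k
    sum(yk * lx) / sum(yk) - 1 / k - mean(lx)
  }
  # moment-based starting bracket from the sd of log values
  k0 <- max(1.2 / (sd(lx) * sqrt(6) / pi), 1e-3)
  lo <- k0 / 20
  hi <- k0 * 20
  while (g(lo) > 0 && lo > 1e-8) lo <- lo / 5
  while (g(hi) < 0 && hi < 1e9) hi <- hi * 5
  k <- uniroot(g, c(lo, hi), tol = 1e-11)$root
  c(shape = k, scale = max(x) * mean(y^k)^(1 / k))
}

fit_logistic_mle <- function(x) {
  init <- c(median(x), sd(x) * sqrt(3) / pi)
  nll <- function(p) {
    if (p[2L] <= 0) return(Inf)
    -ll_logistic(x, p[1L], p[2L])
  }
  opt <- optim(init, nll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000L))
  c(location = opt$par[1L], scale = opt$par[2L])
}
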