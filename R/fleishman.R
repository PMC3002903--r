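# Fleishman cubic-polynomial-of-normal transform: X = a + bZ + cZ^2 + dZ^3
# with Z standard normal and a = -c, giving exact population mean 0, sd 1
# and prescribed skewness/kurtosis. Used by the synthetic generator's
# "polynomial" shape mode to place genes exactly on a kurtosis-skewness
# trend; single-shape families cannot do this (each traces a fixed
# one-parameter curve in the (S, K) plane).

fleishman_system <- function(p, g1, g2) {
  b <- p[1L]; c <- p[2L]; d <- p[3L]
  v <- b^2 + 6 * b * d + 2 * c^2 + 15 * d^2
  s <- 2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2)
  k <- 24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
               d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2))
  c(v - 1, s - g1, k - g2)
}

.fleishman_cache <- new.env(parent = emptyenv())

#' Fleishman polynomial coefficients for target skewness and kurtosis
#'
#' Solves for the coefficients of `X = a + bZ + cZ^2 + dZ^3` (`Z` standard
#' normal, `a = -c`) such that `X` has mean 0, variance 1, skewness `skew`
#' and raw kurtosis `kurt`. Not every (skewness, kurtosis) pair is
#' attainable; infeasible targets raise an error.
#'
#' @param skew Target skewness.
#' @param kurt Target raw kurtosis (normal = 3).
#' @return Named numeric vector `c(a, b, c, d)`.
#' @examples
#' fleishman_coef(0, 3)  # identity: a = c = d = 0, b = 1
#' @export
fleishman_coef <- function(skew, kurt) {
  g1 <- skew
  g2 <- kurt - 3  # the system is written in excess kurtosis
  key <- paste(round(g1, 6), round(g2, 6), sep = "|")
  cached <- .fleishman_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (abs(g1) < 1e-12 && abs(g2) < 1e-12) {
    out <- c(a = 0, b = 1, c = 0, d = 0)
    .fleishman_cache[[key]] <- out
    return(out)
  }
  solve_newton <- function(p) {
    for (it in 1:80) {
      f <- fleishman_system(p, g1, g2)
      if (max(abs(f)) < 1e-12) return(p)
      J <- matrix(0, 3L, 3L)
      h <- 1e-7
      for (j in 1:3) {
        pj <- p
        pj[j] <- pj[j] + h
        J[, j] <- (fleishman_system(pj, g1, g2) - f) / h
      }
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(NULL)
      # damping for large steps keeps the iteration in the basin
      if (max(abs(step)) > 1) step <- step / max(abs(step))
      p <- p - step
    }
    f <- fleishman_system(p, g1, g2)
    if (max(abs(f)) < 1e-9) p else NULL
  }
  starts <- list(c(1, g1 / 6, g2 / 100), c(0.9, g1 / 5, 0.05),
                 c(0.8, sign(g1) * 0.3, 0.1), c(1.05, g1 / 10, -0.02))
  par <- NULL
  for (p0 in starts) {
    par <- solve_newton(p0)
    if (!is.null(par) && par[1L] > 0) break
    par <- NULL
  }
  if (is.null(par)) {
    abort(sprintf("Infeasible skewness/kurtosis target (%.3f, %.3f) for the polynomial transform.",
                  skew, kurt))
  }
  out <- c(a = -par[2L], b = par[1L], c = par[2L], d = par[3L])
  .fleishman_cache[[key]] <- out
  out
}

# Vectorized solve over genes; returns a 4-column matrix (a, b, c, d).
fleishman_coef_matrix <- function(skew, kurt) {
  t(mapply(function(s, k) fleishman_coef(s, k), skew, kurt))
}
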