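#' Kolmogorov-Smirnov and Anderson-Darling statistics
#'
#' Computes the classical one-sample statistics against a fully specified
#' cdf. With estimated parameters these statistics have a non-standard
#' (composite-null) distribution; see [bootstrap_gof()] for calibration.
#'
#' `ks_statistic()` returns
#' \deqn{D = \max_i \max\{ i/n - F(x_{(i)}),\; F(x_{(i)}) - (i-1)/n \}.}
#' `ad_statistic()` returns
#' \deqn{A^2 = -n - \frac1n \sum_i (2i-1)\,[\ln F(x_{(i)}) + \ln(1 - F(x_{(n+1-i)}))].}
#' If any \eqn{F(x_i)} equals 0 or 1 the AD statistic is infinite and `Inf`
#' is returned.
#'
#' @param values Numeric data vector.
#' @param cdf A vectorized cumulative distribution function.
#' @return The scalar statistic.
#' @examples
#' ks_statistic(c(0.1, 0.5, 0.9), identity)  # 7/30 against U(0,1)
#' ad_statistic(c(0.1, 0.5, 0.9), identity)
#' @export
ks_statistic <- function(values, cdf) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 1L) abort("Need at least one value.")
  u <- cdf(x)
  if (is.unsorted(u)) abort("cdf evaluates non-monotonically on the data.")
  if (any(u < 0 | u > 1)) abort("cdf values outside [0, 1].")
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' @rdname ks_statistic
#' @export
ad_statistic <- function(values, cdf) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 1L) abort("Need at least one value.")
  u <- cdf(x)
  if (is.unsorted(u)) abort("cdf evaluates non-monotonically on the data.")
  if (any(u < 0 | u > 1)) abort("cdf values outside [0, 1].")
  if (any(u == 0 | u == 1)) return(Inf)
  i <- seq_len(n)
  -n - sum((2 * i - 1) * (log(u) + log(1 - rev(u)))) / n
}

# Columnwise statistics on an already-sorted matrix of cdf-transformed
# values (each column one replicate). Returns a list of named vectors.
column_gof_stats <- function(u_sorted, stats) {
  n <- nrow(u_sorted)
  i <- seq_len(n)
  out <- list()
  if ("ks" %in% stats) {
    d_plus <- i / n - u_sorted
    d_minus <- u_sorted - (i - 1) / n
    out$ks <- apply(pmax(d_plus, d_minus), 2L, max)
  }
  if ("ad" %in% stats) {
    uc <- pmin(pmax(u_sorted, 0), 1)
    bad <- apply(uc == 0 | uc == 1, 2L, any)
    w <- 2 * i - 1
    a2 <- -n - (colSums(w * log(uc)) + colSums(w * log(1 - uc[n:1, , drop = FALSE]))) / n
    a2[bad] <- Inf
    out$ad <- a2
  }
  out
}
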