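#' Product moments of a sample (plug-in estimators)
#'
#' Computes mean, standard deviation, coefficient of variation, skewness and
#' kurtosis using plug-in (1/n) estimators: central moments
#' \eqn{m_r = n^{-1}\sum (x_i - \bar x)^r}, \eqn{S = m_3/m_2^{3/2}},
#' \eqn{K = m_4/m_2^2} (raw kurtosis; the normal reference value is 3, not
#' 0). With these estimators every sample satisfies the distributional
#' bound \eqn{K \ge S^2 + 1} exactly, so the theoretical boundary can be
#' overlaid on sample scatter.
#'
#' @param values Numeric vector with at least 4 values.
#' @return A one-row tibble: `n`, `mean`, `sd`, `cv`, `skewness`,
#'   `kurtosis`, `degenerate` (TRUE for constant data, in which case the
#'   standardized moments are `NA`).
#' @examples
#' product_moments(c(-1, 1, -1, 1))  # S = 0, K = 1: the bound's equality case
#' @export
product_moments <- function(values) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 4L) abort("Need at least 4 values for product moments through order 4.")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    return(tibble(n = n, mean = m, sd = 0, cv = if (m != 0) 0 else NA_real_,
                  skewness = NA_real_, kurtosis = NA_real_, degenerate = TRUE))
  }
  tibble(
    n = n, mean = m, sd = sqrt(m2),
    cv = if (m != 0) sqrt(m2) / m else NA_real_,
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2,
    degenerate = FALSE
  )
}

#' Sample L-moments via probability-weighted moments
#'
#' Unbiased sample L-moments (Hosking). With order statistics
#' \eqn{x_{(1)} \le \dots \le x_{(n)}} and probability-weighted moments
#' \eqn{b_r = n^{-1}\sum_i \frac{(i-1)\cdots(i-r)}{(n-1)\cdots(n-r)} x_{(i)}},
#' the first four L-moments are \eqn{\ell_1 = b_0},
#' \eqn{\ell_2 = 2b_1 - b_0}, \eqn{\ell_3 = 6b_2 - 6b_1 + b_0},
#' \eqn{\ell_4 = 20b_3 - 30b_2 + 12b_1 - b_0}; the L-moment ratios are
#' \eqn{\tau_3 = \ell_3/\ell_2} (L-skewness) and
#' \eqn{\tau_4 = \ell_4/\ell_2} (L-kurtosis).
#'
#' @param values Numeric vector with at least 4 values.
#' @return A one-row tibble: `l1`, `l2`, `tau3`, `tau4`, `degenerate`
#'   (constant data has `l2 = 0` and undefined ratios).
#' @examples
#' sample_lmoments(1:4)  # l1 = 2.5, l2 = 5/6
#' @export
sample_lmoments <- function(values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 4L) abort("Need at least 4 values for L-moments through order 4.")
  i <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((i - 1) * x) / (n * (n - 1))
  b2 <- sum((i - 1) * (i - 2) * x) / (n * (n - 1) * (n - 2))
  b3 <- sum((i - 1) * (i - 2) * (i - 3) * x) / (n * (n - 1) * (n - 2) * (n - 3))
  l1 <- b0
  l2 <- 2 * b1 - b0
  l3 <- 6 * b2 - 6 * b1 + b0
  l4 <- 20 * b3 - 30 * b2 + 12 * b1 - b0
  if (l2 == 0) {
    return(tibble(l1 = l1, l2 = 0, tau3 = NA_real_, tau4 = NA_real_,
                  degenerate = TRUE))
  }
  tibble(l1 = l1, l2 = l2, tau3 = l3 / l2, tau4 = l4 / l2, degenerate = FALSE)
}

#' Lower bound on kurtosis given skewness
#'
#' Any probability distribution with skewness `S` has raw kurtosis at least
#' `S^2 + 1`; plug-in sample moments satisfy the same bound sample-wise.
#'
#' @param S Skewness value(s).
#' @return `S^2 + 1`.
#' @export
kurtosis_lower_bound <- function(S) S^2 + 1

#' Per-gene moment summary of an expression matrix
#'
#' Applies [product_moments()] and [sample_lmoments()] to every gene (row)
#' of an expression matrix.
#'
#' @param x An `expr_mat`.
#' @return A tibble with one row per gene: `gene_id`, `n`, `mean`, `sd`,
#'   `cv`, `skewness`, `kurtosis`, `l1`, `l2`, `tau3`, `tau4`, `degenerate`.
#' @export
moment_summary <- function(x) {
  stopifnot(is_expr_mat(x))
  v <- expr_values(x)
  n <- ncol(v)
  if (n < 4L) abort("Need at least 4 samples per gene.")
  m <- rowMeans(v)
  d <- v - m
  m2 <- rowMeans(d^2)
  m3 <- rowMeans(d^3)
  m4 <- rowMeans(d^4)
  degenerate <- m2 == 0
  sdv <- sqrt(m2)
  skew <- ifelse(degenerate, NA_real_, m3 / m2^1.5)
  kurt <- ifelse(degenerate, NA_real_, m4 / m2^2)
  cv <- ifelse(m == 0, NA_real_, sdv / m)

  # row-wise sorted values for the probability-weighted moments
  vs <- t(apply(v, 1L, sort))
  i <- seq_len(n)
  b0 <- rowMeans(vs)
  b1 <- as.numeric(vs %*% (i - 1)) / (n * (n - 1))
  b2 <- as.numeric(vs %*% ((i - 1) * (i - 2))) / (n * (n - 1) * (n - 2))
  b3 <- as.numeric(vs %*% ((i - 1) * (i - 2) * (i - 3))) /
    (n * (n - 1) * (n - 2) * (n - 3))
  l1 <- b0
  l2 <- 2 * b1 - b0
  l3 <- 6 * b2 - 6 * b1 + b0
  l4 <- 20 * b3 - 30 * b2 + 12 * b1 - b0
  tau3 <- ifelse(l2 == 0, NA_real_, l3 / l2)
  tau4 <- ifelse(l2 == 0, NA_real_, l4 / l2)

  tibble(
    gene_id = expr_genes(x), n = n, mean = unname(m), sd = unname(sdv),
    cv = unname(cv), skewness = unname(skew), kurtosis = unname(kurt),
    l1 = unname(l1), l2 = unname(l2), tau3 = unname(tau3),
    tau4 = unname(tau4), degenerate = unname(degenerate)
  )
}
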