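test_that("KS statistic matches hand evaluation and a brute-force oracle", {
  expect_equal(ks_statistic(c(0.1, 0.5, 0.9), identity), 7 / 30, tolerance = 1e-15)
  # symmetric grid attains the minimum possible D at n = 3
  expect_equal(ks_statistic(c(1 / 6, 1 / 2, 5 / 6), identity), 1 / 6, tolerance = 1e-15)
  # brute force: sup over a dense grid augmented with the jump points,
  # with the left limit of the empirical cdf approximated at t - 1e-12
  set.seed(31)
  x <- rbeta(40, 2, 5)
  d <- ks_statistic(x, identity)
  grid <- sort(c(seq(0, 1, length.out = 1e6), x))
  Fe <- stats::ecdf(x)
  oracle <- max(pmax(Fe(grid) - grid, grid - Fe(grid - 1e-12)))
  expect_lt(abs(d - oracle), 1e-9)
  expect_error(ks_statistic(c(0.2, 0.1), function(u) rev(u)), "non-monotonically")
})

test_that("AD statistic matches hand evaluation, symmetry and ad.test", {
  # hand evaluation: A^2 = -3 - (1/3)[1*(2 ln .1) + 3*(2 ln .5) + 5*(2 ln .9)]
  a <- ad_statistic(c(0.1, 0.5, 0.9), identity)
  expect_equal(a, -3 - (2 * log(0.1) + 6 * log(0.5) + 10 * log(0.9)) / 3,
               tolerance = 1e-12)
  expect_equal(a, 0.2725528, tolerance = 1e-6)
  # u and 1 - u give identical statistics
  set.seed(32)
  u <- runif(25)
  expect_equal(ad_statistic(u, identity), ad_statistic(1 - u, identity),
               tolerance = 1e-12)
  # numeric-integration oracle: A^2 = n * int (Fn - F)^2 / (F(1-F)) dF
  x <- sort(runif(15))
  Fe <- stats::ecdf(x)
  integrand <- function(t) (Fe(t) - t)^2 / (t * (1 - t))
  oracle <- 15 * stats::integrate(integrand, 0, 1, subdivisions = 2000L,
                                  rel.tol = 1e-12)$value
  expect_equal(ad_statistic(x, identity), oracle, tolerance = 1e-6)
  # matches nortest's composite-normal statistic when given the same cdf
  y <- rnorm(80, 3, 2)
  expect_equal(ad_statistic(y, function(q) pnorm(q, mean(y), sd(y))),
               unname(nortest::ad.test(y)$statistic), tolerance = 1e-10)
  expect_equal(ad_statistic(c(0, 0.5), identity), Inf)
})

test_that("the null mean of the AD statistic is about 1", {
  set.seed(33)
  a2 <- replicate(3000, ad_statistic(runif(100), identity))
  expect_lt(abs(mean(a2) - 1), 3 * sd(a2) / sqrt(3000))
})

test_that("bootstrap GOF p-values are valid and flags are coherent", {
  set.seed(34)
  res <- bootstrap_gof(rnorm(60), "normal", stats = c("ad", "ks"), B = 200, seed = 5)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$p_value >= 1 / 201 & res$p_value <= 1))
  expect_true(all(res$reject_95 <= res$reject_90))  # reject_95 implies reject_90
  expect_error(bootstrap_gof(rnorm(60), "normal", B = 50), "at least 100")
  expect_error(bootstrap_gof(rep(1, 60), "normal", B = 200), "identical")
  # identical results for identical seeds, regardless of outer RNG state
  y <- rlogis(50)
  r1 <- bootstrap_gof(y, "logistic", stats = "ks", B = 100, seed = 11)
  set.seed(999)
  r2 <- bootstrap_gof(y, "logistic", stats = "ks", B = 100, seed = 11)
  expect_equal(r1, r2)
})

test_that("bootstrap p-values are uniform under a true null", {
  set.seed(35)
  ps <- vapply(1:150, function(i) {
    bootstrap_gof(rnorm(50), "normal", stats = "ad", B = 199, seed = 1000 + i)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
  expect_lt(abs(mean(ps <= 0.1) - 0.1), 2.576 * sqrt(0.1 * 0.9 / 150) + 0.01)
})

test_that("non-normal families run through the generic bootstrap path", {
  set.seed(36)
  x <- rweibull(50, 2, 5)
  r <- bootstrap_gof(x, "weibull", stats = "ad", B = 100, seed = 3)
  expect_gt(r$p_value, 0.05)  # true family should not be rejected here
  g <- bootstrap_gof(rgamma(50, 3, 1), "gamma", stats = "ks", B = 100, seed = 4)
  expect_true(g$p_value >= 1 / 101 && g$p_value <= 1)
})

test_that("chi-square GOF matches hand computations", {
  # a sample laid out exactly uniformly has a perfect fit
  x <- (1:40 - 0.5) / 40
  r0 <- chisq_gof(x, quantile_fun = identity, n_params = 0, bins = 4)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # observed (10, 0, 5, 5) against uniform expected (5, 5, 5, 5)
  y <- c(runif(10, 0, 0.25), runif(5, 0.5, 0.75), runif(5, 0.75, 1))
  r1 <- chisq_gof(y, quantile_fun = identity, n_params = 0, bins = 4)
  expect_equal(r1$statistic, 10)
  expect_equal(r1$df, 3L)
  expect_equal(r1$p_value, pchisq(10, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(r1$p_value, 4), 0.0186)
  expect_error(chisq_gof(runif(10), quantile_fun = identity, n_params = 0),
               "expected counts|bins")
})

test_that("chi-square GOF handles fitted single and mixture models", {
  set.seed(37)
  x <- rnorm(300, 2, 1.5)
  r1 <- chisq_gof(x, fit_mle(x, "normal"))
  expect_false(r1$reject_95)
  mf <- fit_mixture_em(x, 3, seed = 8)
  r3 <- chisq_gof(x, mf)
  expect_equal(r3$df, r3$bins - 1L - 8L)
  expect_true(is.finite(r3$statistic))
})

test_that("batch testing summarizes rejections and handles log-ratio NA families", {
  sim <- null_sim(n_genes = 25, n_per_group = 25, n_groups = 2, seed = 17)
  out <- batch_gof(sim$expression, families = c("normal", "weibull"),
                   stats = "ad", B = 100, seed = 2)
  expect_s3_class(out$results, "tbl_df")
  expect_equal(nrow(out$results), 50L)
  expect_true(all(out$results$reject_95 <= out$results$reject_90, na.rm = TRUE))
  expect_true(all(c("frac_rejected_95", "frac_rejected_90") %in% names(out$summary)))
  expect_true("frac_any_not_rejected_95" %in% names(out$any_not_rejected))

  # log-ratio mode: positive-support families are recorded as NA, no crash
  vr <- matrix(rnorm(25 * 20, 0, 0.3), 25, 20)
  mr <- make_mat(vr, mode = "log_ratio")
  outr <- batch_gof(mr, families = c("normal", "weibull", "lognormal"),
                    stats = "ad", B = 100, seed = 2)
  na_rows <- dplyr::filter(outr$results, family != "normal")
  expect_true(all(is.na(na_rows$p_value)))
  expect_true(all(!is.na(dplyr::filter(outr$results, family == "normal")$p_value)))
  expect_error(batch_gof(sim$expression, genes = character(0)), "Empty gene set")
})

test_that("batch results are reproducible for a fixed master seed", {
  sim <- null_sim(n_genes = 10, n_per_group = 20, n_groups = 2, seed = 18)
  a <- batch_gof(sim$expression, families = "normal", stats = "ad", B = 100, seed = 5)
  b <- batch_gof(sim$expression, families = "normal", stats = "ad", B = 100, seed = 5)
  expect_equal(a$results, b$results)
})
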