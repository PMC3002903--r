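test_that("product moments match direct summation and known exact cases", {
  # symmetric two-point sample: the K = S^2 + 1 equality case
  pm <- product_moments(c(-1, 1, -1, 1))
  expect_equal(pm$skewness, 0)
  expect_equal(pm$kurtosis, 1)
  # brute-force summation oracle
  x <- c(1, 2, 3, 4, 10)
  pm2 <- product_moments(x)
  n <- length(x); m <- sum(x) / n
  m2 <- sum((x - m)^2) / n; m3 <- sum((x - m)^3) / n; m4 <- sum((x - m)^4) / n
  expect_equal(pm2$mean, m, tolerance = 1e-12)
  expect_equal(pm2$sd, sqrt(m2), tolerance = 1e-12)
  expect_equal(pm2$cv, sqrt(m2) / m, tolerance = 1e-12)
  expect_equal(pm2$skewness, m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(pm2$kurtosis, m4 / m2^2, tolerance = 1e-12)
  # constant data flagged degenerate
  pmc <- product_moments(rep(2, 6))
  expect_true(pmc$degenerate)
  expect_true(is.na(pmc$skewness))
  expect_error(product_moments(1:3), "at least 4")
})

test_that("sample L-moments match hand probability-weighted moments", {
  lm1 <- sample_lmoments(1:4)
  expect_equal(lm1$l1, 2.5)
  expect_equal(lm1$l2, 5 / 6, tolerance = 1e-12)
  # hand PWM oracle on an arbitrary sample
  x <- sort(c(0.3, 1.2, 2.2, 5.0, 9.1, 9.2))
  n <- 6; i <- 1:6
  b0 <- mean(x)
  b1 <- sum((i - 1) / (n - 1) * x) / n
  b2 <- sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * x) / n
  b3 <- sum((i - 1) * (i - 2) * (i - 3) / ((n - 1) * (n - 2) * (n - 3)) * x) / n
  lmx <- sample_lmoments(x)
  expect_equal(lmx$l2, 2 * b1 - b0, tolerance = 1e-12)
  expect_equal(lmx$tau3, (6 * b2 - 6 * b1 + b0) / (2 * b1 - b0), tolerance = 1e-12)
  expect_equal(lmx$tau4, (20 * b3 - 30 * b2 + 12 * b1 - b0) / (2 * b1 - b0),
               tolerance = 1e-12)
  # any exactly symmetric sample has zero L-skewness
  s <- c(-3, -1, 0, 1, 3)
  expect_equal(sample_lmoments(s)$tau3, 0, tolerance = 1e-14)
  # constant data: l2 = 0, ratios undefined
  lc <- sample_lmoments(rep(1, 5))
  expect_true(lc$degenerate)
  expect_equal(lc$l2, 0)
})

test_that("the plug-in kurtosis bound holds for every sample, even discrete ones", {
  set.seed(41)
  for (r in 1:300) {
    n <- sample(4:60, 1)
    x <- switch(sample(4, 1),
                rnorm(n), rgamma(n, shape = runif(1, 0.2, 5)),
                rcauchy(n), sample(c(-1, 0, 1, 5), n, replace = TRUE))
    if (max(x) == min(x)) next
    pm <- product_moments(x)
    expect_gte(pm$kurtosis, kurtosis_lower_bound(pm$skewness) - 1e-10)
    lmx <- sample_lmoments(x)
    expect_lt(abs(lmx$tau3), 1 + 1e-12)
    expect_gte(lmx$l2, 0)
    # negation symmetry: tau3 flips sign, tau4 invariant
    lmn <- sample_lmoments(-x)
    expect_equal(lmn$tau3, -lmx$tau3, tolerance = 1e-9)
    expect_equal(lmn$tau4, lmx$tau4, tolerance = 1e-9)
  }
})

test_that("the L-moment attainability bound holds for continuous data but is a population property", {
  set.seed(42)
  # continuous expression-like samples respect tau4 >= (5 tau3^2 - 1)/4
  for (r in 1:300) {
    n <- sample(10:60, 1)
    x <- switch(sample(4, 1),
                rnorm(n), rgamma(n, shape = runif(1, 0.3, 5)),
                rlogis(n), rlnorm(n, 0, runif(1, 0.2, 1)))
    lmx <- sample_lmoments(x)
    expect_gte(lmx$tau4, (5 * lmx$tau3^2 - 1) / 4 - 1e-10)
  }
  # ...but unbiased sample ratios of tied/extreme samples can violate it:
  # a documented counterexample, not a bug
  cx <- c(-0.3047415, -0.2097803, 1.4035438, 1.4705822)
  lc <- sample_lmoments(cx)
  expect_lt(lc$tau4, (5 * lc$tau3^2 - 1) / 4)
})

test_that("kurtosis_lower_bound is S^2 + 1, even in S", {
  expect_equal(kurtosis_lower_bound(0), 1)
  expect_equal(kurtosis_lower_bound(2), 5)
  expect_equal(kurtosis_lower_bound(-2), 5)
})

test_that("moment_summary equals the per-gene scalar computations", {
  sim <- null_sim(n_genes = 12, n_per_group = 8, n_groups = 2, seed = 55)
  ms <- moment_summary(sim$expression)
  v <- expr_values(sim$expression)
  for (i in c(1, 5, 12)) {
    pm <- product_moments(v[i, ])
    lmx <- sample_lmoments(v[i, ])
    expect_equal(ms$mean[i], pm$mean, tolerance = 1e-12)
    expect_equal(ms$skewness[i], pm$skewness, tolerance = 1e-9)
    expect_equal(ms$kurtosis[i], pm$kurtosis, tolerance = 1e-9)
    expect_equal(ms$l2[i], lmx$l2, tolerance = 1e-9)
    expect_equal(ms$tau4[i], lmx$tau4, tolerance = 1e-9)
  }
})

test_that("theoretical L-moment points are correct", {
  expect_equal(lmoment_curve("UNI")$tau4, 0, tolerance = 1e-9)
  expect_equal(lmoment_curve("UNI")$tau3, 0, tolerance = 1e-9)
  expect_equal(lmoment_curve("EXP")$tau3, 1 / 3)
  expect_equal(lmoment_curve("EXP")$tau4, 1 / 6)
  # normal point: tau3 = 0, tau4 = 30/pi * atan(sqrt(2)) - 9
  nor <- lmoment_curve("NOR")
  expect_equal(nor$tau3, 0, tolerance = 1e-9)
  expect_equal(nor$tau4, 30 / pi * atan(sqrt(2)) - 9, tolerance = 1e-7)
  # Gumbel point: tau3 = ln(9/8)/ln 2
  gum <- lmoment_curve("GUM")
  expect_equal(gum$tau3, log(9 / 8) / log(2), tolerance = 1e-6)
  expect_equal(gum$tau4, (16 * log(2) - 10 * log(3)) / log(2), tolerance = 1e-6)
})

test_that("GPA and GLO closed-form curves pass through known points", {
  # GPA at tau3 = 1/3 coincides with the exponential point
  expect_equal(lmoment_curve("GPA", 1 / 3)$tau4, 1 / 6, tolerance = 1e-12)
  # GLO at tau3 = 0 is the logistic point tau4 = 1/6
  expect_equal(lmoment_curve("GLO", 0)$tau4, 1 / 6)
  expect_error(lmoment_curve("GLO", 1.2), "inside")
})

test_that("theoretical curves agree with large-sample simulated L-moment ratios", {
  set.seed(43)
  n <- 1e6
  u <- runif(n)
  # generalized logistic via its quantile function, three shapes
  for (k in c(-0.2, 0.1, 0.3)) {
    x <- (1 - ((1 - u) / u)^k) / k
    sl <- sample_lmoments(x)
    expect_lt(abs(lmoment_curve("GLO", sl$tau3)$tau4 - sl$tau4), 0.002)
  }
  # generalized Pareto, shape 0.25: tau3 = (1-k)/(3+k)
  k <- 0.25
  x <- (1 - (1 - u)^k) / k
  sl <- sample_lmoments(x)
  expect_lt(abs(sl$tau3 - (1 - k) / (3 + k)), 0.002)
  expect_lt(abs(lmoment_curve("GPA", sl$tau3)$tau4 - sl$tau4), 0.002)
  # GEV, shape 0.15
  x <- (1 - (-log(u))^0.15) / 0.15
  sl <- sample_lmoments(x)
  expect_lt(abs(lmoment_curve("GEV", sl$tau3)$tau4 - sl$tau4), 0.002)
  # Pearson III (gamma shape 4) and generalized normal (k = 0.5)
  x <- qgamma(u, shape = 4)
  sl <- sample_lmoments(x)
  expect_lt(abs(lmoment_curve("PE3", sl$tau3)$tau4 - sl$tau4), 0.002)
  x <- (1 - exp(-0.5 * qnorm(u))) / 0.5
  sl <- sample_lmoments(x)
  expect_lt(abs(lmoment_curve("GNO", sl$tau3)$tau4 - sl$tau4), 0.002)
})

test_that("diagram data stacks curves and points", {
  dd <- lmoment_diagram_data(tau3 = seq(-0.4, 0.6, length.out = 21))
  expect_setequal(unique(dd$family),
                  c("GEV", "GLO", "GNO", "GPA", "PE3", "EXP", "NOR", "GUM", "RAY", "UNI"))
  expect_true(all(dd$geometry[dd$family == "NOR"] == "point"))
  expect_equal(sum(dd$family == "GLO"), 21L)
})
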