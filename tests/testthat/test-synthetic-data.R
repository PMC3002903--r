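test_that("spec validation rejects inconsistent configurations", {
  expect_error(synthetic_spec(noise_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_spec(family_weights = c(normal = 0.5)), "sum to 1")
  expect_error(synthetic_spec(family_weights = c(banana = 1)), "named with families")
  expect_error(synthetic_spec(conditions = character(0)), "2 samples")
  expect_error(synthetic_spec(mode = "log_ratio",
                              family_weights = c(lognormal = 1)),
               "log_expression")
  expect_error(synthetic_spec(sampling = "stratified", shape = "family"),
               "polynomial")
  spec <- synthetic_spec(conditions = c(A = 3, B = 4))
  expect_equal(spec$n_samples, 7L)
})

test_that("generation is deterministic for a fixed spec and seed", {
  spec <- synthetic_spec(n_genes = 40, conditions = c(A = 6, B = 6),
                         noise_fraction = 0.2, mixture_fraction = 0.1, seed = 5)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(expr_values(a$expression), expr_values(b$expression))
  expect_identical(a$truth, b$truth)
  c <- simulate_expression(synthetic_spec(n_genes = 40, conditions = c(A = 6, B = 6),
                                          noise_fraction = 0.2,
                                          mixture_fraction = 0.1, seed = 6))
  expect_false(identical(expr_values(a$expression), expr_values(c$expression)))
})

test_that("flags and dimensions are consistent with the spec proportions", {
  spec <- synthetic_spec(n_genes = 200, conditions = c(A = 10, B = 10),
                         noise_fraction = 0.15, affected_fraction = 0.2,
                         mixture_fraction = 0.1, seed = 8)
  sim <- simulate_expression(spec)
  expect_equal(dim(expr_values(sim$expression)), c(200L, 20L))
  expect_equal(sum(sim$truth$noise), 30L)
  expect_equal(sum(sim$truth$affected), 40L)
  expect_equal(sum(sim$truth$mixture), 20L)
  expect_equal(nrow(sim$truth), 200L)
  # noise genes sit below the floor, signal genes above it
  expect_true(all(sim$truth$true_mean[sim$truth$noise] < 6))
  expect_true(all(sim$truth$true_mean[!sim$truth$noise] > 6))
})

test_that("a zero-variance gene yields a constant row flagged degenerate", {
  sim <- simulate_expression(synthetic_spec(
    n_genes = 1, conditions = c(A = 3, B = 2), cv_trend = c(-Inf, 0),
    noise_fraction = 0, seed = 2
  ))
  v <- as.numeric(expr_values(sim$expression))
  expect_equal(length(unique(v)), 1L)
  expect_true(sim$truth$degenerate)
})

test_that("per-gene sample means and SDs are unbiased for the generating values", {
  sim <- null_sim(n_genes = 600, n_per_group = 25, n_groups = 2, seed = 23)
  ms <- moment_summary(sim$expression)
  n <- 50
  # standardized mean errors are t-like; test mean zero across genes
  z_mean <- (ms$mean - sim$truth$true_mean) / (sim$truth$true_sd / sqrt(n))
  expect_gt(t.test(z_mean)$p.value, 0.01)
  # plug-in SD has known bias ~ sd*(1 - 3/(4n)); correct and test
  z_sd <- ms$sd / (sim$truth$true_sd * sqrt((n - 1) / n) * (1 - 1 / (4 * (n - 1)))) - 1
  expect_gt(t.test(z_sd)$p.value, 0.01)
})

test_that("the CV trend is recovered from generated data within 3 SE", {
  sim <- simulate_expression(synthetic_spec(
    n_genes = 2500, conditions = c(A = 35, B = 35, C = 35),
    cv_trend = c(-2.10, -0.22), noise_fraction = 0.15,
    affected_fraction = 0, seed = 29
  ))
  mom <- noise_floor_filter(moment_summary(sim$expression), "log_expression")
  fit <- fit_log_cv_vs_mean(mom)
  co <- tidy(fit)
  expect_lt(abs(co$estimate[1] - (-2.10)) / co$std_error[1], 3)
  expect_lt(abs(co$estimate[2] - (-0.22)) / co$std_error[2], 3)
})

test_that("condition shifts give Kruskal-Wallis power matching a Monte-Carlo oracle", {
  # fixed mean and CV so every affected gene shares one generating setup:
  # sd = 0.4, shift range 2 SD across 3 conditions of 10 samples
  sd_true <- 0.4
  spec <- synthetic_spec(
    n_genes = 500, conditions = c(A = 10, B = 10, C = 10),
    mean_range = c(8, 8), cv_trend = c(log10(sd_true / 8), 0), cv_jitter_sd = 0,
    noise_fraction = 0, affected_fraction = 0.5, affected_effect = 2 * sd_true,
    seed = 31
  )
  sim <- simulate_expression(spec)
  sc <- suppressMessages(screen_unaffected(sim$expression, sim$conditions, alpha = 0.1))
  power_obs <- mean(!sc$retained[sim$truth$affected])

  # independent oracle: simulate the same design directly
  set.seed(77)
  shifts <- rep(2 * sd_true * ((1:3 - 1) / 2 - 0.5), each = 10)
  power_mc <- mean(replicate(2000, {
    y <- rnorm(30, 8, sd_true) + shifts
    kruskal.test(y, g = factor(rep(1:3, each = 10)))$p.value <= 0.1
  }))
  se <- sqrt(power_mc * (1 - power_mc) * (1 / 250 + 1 / 2000))
  expect_lt(abs(power_obs - power_mc), 3 * se)
  # unaffected genes are retained at about the nominal rate
  expect_gt(mean(sc$retained[!sim$truth$affected]), 0.8)
})

test_that("generated single-family genes pass their own GOF test at the nominal rate", {
  sim <- null_sim(n_genes = 120, n_per_group = 30, n_groups = 2, seed = 37)
  out <- batch_gof(sim$expression, families = "normal", stats = "ad",
                   B = 200, seed = 3)
  frac <- out$summary$frac_rejected_95
  expect_lt(abs(frac - 0.05), 2.576 * sqrt(0.05 * 0.95 / 120) + 0.01)
})

test_that("polynomial shape mode hits its moment targets", {
  spec <- synthetic_spec(n_genes = 150, conditions = c(A = 1000, B = 1000),
                         shape = "polynomial", sampling = "stratified",
                         noise_fraction = 0, seed = 41)
  sim <- simulate_expression(spec)
  ms <- moment_summary(sim$expression)
  expect_equal(ms$mean, sim$truth$true_mean, tolerance = 0.01)
  expect_equal(ms$skewness, sim$truth$true_skewness, tolerance = 0.2)
  # kurtosis targets respect the quadratic trend region
  expect_true(all(sim$truth$true_kurtosis >=
                    sim$truth$true_skewness^2 + 1))
})

test_that("mixture genes are flagged and excluded from single-family truth", {
  spec <- synthetic_spec(n_genes = 60, conditions = c(A = 100, B = 100),
                         mixture_fraction = 0.5, noise_fraction = 0, seed = 43)
  sim <- simulate_expression(spec)
  ms <- moment_summary(sim$expression)
  expect_equal(sum(sim$truth$mixture), 30L)
  expect_true(all(is.na(sim$truth$true_skewness[sim$truth$mixture])))
  expect_true(all(sim$truth$family[sim$truth$mixture] == "normal_mixture"))
})

test_that("log-ratio mode produces signed means with a noise stratum near zero", {
  spec <- synthetic_spec(n_genes = 300, conditions = c(A = 20, B = 20),
                         mode = "log_ratio", mean_range = c(0.05, 1),
                         cv_trend = c(0.57, -1.67), noise_fraction = 0.3, seed = 47)
  sim <- simulate_expression(spec)
  expect_equal(expr_mode(sim$expression), "log_ratio")
  tr <- sim$truth
  expect_true(all(abs(tr$true_mean[tr$noise]) < 0.05))
  expect_true(all(abs(tr$true_mean[!tr$noise]) > 0.05))
  expect_gt(sum(tr$true_mean < 0), 50)  # both signs occur
})

test_that("synthetic studies round-trip to disk", {
  sim <- null_sim(n_genes = 20, n_per_group = 4, n_groups = 2, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_synthetic(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_expression(paths[["expression"]])
  expect_equal(expr_values(back), signif(expr_values(sim$expression), 6),
               tolerance = 1e-12)
  cfg <- jsonlite::fromJSON(paths[["spec"]])
  expect_equal(cfg$n_genes, 20L)
  expect_equal(cfg$seed, 3L)
})
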