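#' Specification of a synthetic expression study
#'
#' Describes the statistical structure of a synthetic gene-by-sample matrix
#' of log-scale expression: a linear trend between the mean and the log10
#' coefficient of variation, a quadratic kurtosis-skewness relation, a
#' low-expression noise stratum with inflated dispersion, condition-affected
#' genes with location shifts, and optional normal-mixture genes.
#'
#' Two shape-control modes are available. `shape = "family"` draws each
#' gene from a single parametric family (moment-matched to the gene's
#' target mean and SD), so higher moments follow each family's own
#' one-parameter curve. `shape = "polynomial"` uses a Fleishman
#' cubic-polynomial-of-normal transform giving exact population control of
#' (mean, SD, skewness, kurtosis), and places genes on the
#' `kurt_skew_trend` quadratic with Gaussian scatter `kurt_noise_sd`.
#'
#' @param n_genes Number of genes.
#' @param conditions Either a character vector of per-sample condition
#'   labels, or a named integer vector of per-condition sample counts
#'   (default three conditions of 35 samples, a tissue-scale design).
#' @param mode `"log_expression"` (single-color, strictly positive means)
#'   or `"log_ratio"` (two-color, means near zero, possibly negative).
#' @param family_weights Named proportions over the generating families
#'   (`normal`, `logistic`, `extreme_value`, `lognormal`, `gamma`,
#'   `weibull`); must sum to 1. Positive-support families require
#'   log-expression mode.
#' @param cv_trend `c(intercept, slope)` of
#'   `log10(CV) = intercept + slope * mean` (log-ratio mode uses
#'   `|mean|` as predictor). Default `c(-2.10, -0.22)`, a whole-brain
#'   tissue panel scale.
#' @param kurt_skew_trend `c(c0, c1, c2)` of `K = c0 + c1 S + c2 S^2`
#'   (polynomial mode only). Default `c(2.96, -0.31, 1.40)`, a
#'   craniofacial-development panel scale.
#' @param skew_mean,skew_sd,skew_limits Distribution of per-gene target
#'   skewness in polynomial mode: normal, truncated to `skew_limits`.
#' @param kurt_noise_sd SD of the Gaussian scatter of kurtosis around the
#'   quadratic trend (polynomial mode).
#' @param noise_fraction Proportion of genes placed below the noise floor.
#' @param noise_floor Mean cutoff separating signal from noise; defaults to
#'   6 (log-expression) or 0.05 (absolute log-ratio).
#' @param noise_cv_factor Multiplier inflating the CV (hence all higher
#'   dispersion) of noise-stratum genes.
#' @param affected_fraction Proportion of genes given condition-dependent
#'   location shifts.
#' @param affected_effect Total shift range in log units: condition `j` of
#'   `k` receives `affected_effect * ((j - 1)/(k - 1) - 1/2)`, so the two
#'   extreme conditions differ by exactly `affected_effect`.
#' @param mixture_fraction Proportion of genes drawn from a 2-3 component
#'   normal mixture.
#' @param mean_range Range of signal-stratum means (log-expression mode).
#' @param cv_jitter_sd SD (log10 units) of the lognormal scatter of CV
#'   around the trend line.
#' @param shape Higher-moment control: `"family"` draws each gene from one
#'   parametric family; `"polynomial"` uses the cubic-polynomial-of-normal
#'   transform to hit the `kurt_skew_trend` targets exactly (see Details).
#' @param sampling `"iid"` draws each gene's samples independently;
#'   `"stratified"` (polynomial mode only) draws one value per probability
#'   stratum of the gene's distribution, randomly placed within the stratum
#'   and permuted across samples — unbiased for the population moments but
#'   with much smaller estimation noise, the preferred design for studying
#'   moment relationships.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000L,
                           conditions = c(A = 35L, B = 35L, C = 35L),
                           mode = c("log_expression", "log_ratio"),
                           family_weights = c(normal = 1),
                           cv_trend = c(-2.10, -0.22),
                           kurt_skew_trend = c(2.96, -0.31, 1.40),
                           skew_mean = -0.39, skew_sd = 0.6,
                           skew_limits = c(-1.5, 1.2),
                           kurt_noise_sd = 0.3,
                           noise_fraction = 0.2,
                           noise_floor = NULL,
                           noise_cv_factor = 3,
                           affected_fraction = 0,
                           affected_effect = 1,
                           mixture_fraction = 0,
                           mean_range = c(6, 14),
                           cv_jitter_sd = 0.1,
                           shape = c("family", "polynomial"),
                           sampling = c("iid", "stratified"),
                           seed = 1L) {
  mode <- match.arg(mode)
  shape <- match.arg(shape)
  sampling <- match.arg(sampling)
  if (sampling == "stratified" && shape != "polynomial") {
    abort("Stratified sampling is implemented for the polynomial shape mode.")
  }
  if (n_genes < 1L) abort("n_genes must be >= 1.")

  if (is.numeric(conditions)) {
    if (is.null(names(conditions)) || any(conditions < 1)) {
      abort("Numeric conditions must be a named vector of positive counts.")
    }
    conditions <- rep(names(conditions), times = conditions)
  }
  conditions <- as.character(conditions)
  if (length(conditions) < 2L) abort("Need at least 2 samples.")

  props <- c(noise_fraction = noise_fraction,
             affected_fraction = affected_fraction,
             mixture_fraction = mixture_fraction)
  if (any(props < 0 | props > 1)) {
    abort("noise_fraction, affected_fraction and mixture_fraction must lie in [0, 1].")
  }
  fams <- c("normal", "logistic", "extreme_value", "lognormal", "gamma", "weibull")
  if (is.null(names(family_weights)) || !all(names(family_weights) %in% fams)) {
    abort(paste0("family_weights must be named with families among: ",
                 paste(fams, collapse = ", ")))
  }
  if (any(family_weights < 0) || abs(sum(family_weights) - 1) > 1e-8) {
    abort("family_weights must be nonnegative and sum to 1.")
  }
  positive_fams <- c("lognormal", "gamma", "weibull")
  if (mode == "log_ratio" &&
      any(family_weights[names(family_weights) %in% positive_fams] > 0)) {
    abort("Positive-support generating families need log_expression mode.")
  }
  noise_floor <- noise_floor %||% if (mode == "log_expression") 6 else 0.05

  structure(
    list(n_genes = as.integer(n_genes), conditions = conditions,
         n_samples = length(conditions), mode = mode,
         family_weights = family_weights, cv_trend = cv_trend,
         kurt_skew_trend = kurt_skew_trend, skew_mean = skew_mean,
         skew_sd = skew_sd, skew_limits = skew_limits,
         kurt_noise_sd = kurt_noise_sd,
         noise_fraction = noise_fraction, noise_floor = noise_floor,
         noise_cv_factor = noise_cv_factor,
         affected_fraction = affected_fraction,
         affected_effect = affected_effect,
         mixture_fraction = mixture_fraction, mean_range = mean_range,
         cv_jitter_sd = cv_jitter_sd, shape = shape, sampling = sampling,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# population skewness/kurtosis of the moment-matched generating families
family_shape_moments <- function(family, cv) {
  switch(
    family,
    normal = c(0, 3),
    logistic = c(0, 4.2),
    extreme_value = c(-12 * sqrt(6) * 1.2020569031595943 / pi^3, 5.4),
    lognormal = {
      w <- 1 + cv^2
      c((w + 2) * sqrt(w - 1), w^4 + 2 * w^3 + 3 * w^2 - 3)
    },
    gamma = {
      k <- 1 / cv^2
      c(2 / sqrt(k), 3 + 6 / k)
    },
    weibull = {
      k <- weibull_shape_from_cv(cv)
      if (k > 50) {
        # large-shape Weibull converges to the minimum-type Gumbel shape
        c(-12 * sqrt(6) * 1.2020569031595943 / pi^3, 5.4)
      } else {
        g <- gamma(1 + (1:4) / k)
        v <- g[2L] - g[1L]^2
        s <- (g[3L] - 3 * g[1L] * g[2L] + 2 * g[1L]^3) / v^1.5
        kk <- (g[4L] - 4 * g[1L] * g[3L] + 6 * g[1L]^2 * g[2L] - 3 * g[1L]^4) / v^2
        c(s, kk)
      }
    }
  )
}

weibull_shape_from_cv <- function(cv) {
  # cv^2(k) = exp(lgamma(1 + 2/k) - 2 lgamma(1 + 1/k)) - 1, decreasing in k
  g <- function(k) expm1(lgamma(1 + 2 / k) - 2 * lgamma(1 + 1 / k)) - cv^2
  lo <- 0.08
  hi <- 500
  while (g(hi) > 0 && hi < 1e8) hi <- hi * 8
  uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Generate a synthetic expression matrix with ground truth
#'
#' Realizes a [synthetic_spec()]: draws per-gene means and SDs from the CV
#' trend, applies the requested shape control, inserts noise-stratum,
#' condition-affected and mixture genes, and returns the matrix together
#' with a per-gene truth table. Deterministic for a fixed spec (the seed is
#' part of the spec).
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_expression`: `expression` (an
#'   [as_expr_mat()] tibble), `truth` (per-gene tibble with the generating
#'   family, true moments and the noise/affected/mixture/degenerate flags),
#'   `conditions` (a [condition_map()]), and `spec`.
#' @examples
#' sim <- simulate_expression(synthetic_spec(n_genes = 50, seed = 7))
#' sim$truth
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::local_seed(spec$seed)
  ng <- spec$n_genes
  ns <- spec$n_samples
  log_ratio <- spec$mode == "log_ratio"

  gene_id <- sprintf("g%0*d", max(5L, nchar(ng)), seq_len(ng))
  sample_id <- sprintf("s%0*d", max(3L, nchar(ns)), seq_len(ns))

  # ---- flags: noise first, then mixture and affected among the rest ------
  n_noise <- round(spec$noise_fraction * ng)
  n_mix <- round(spec$mixture_fraction * ng)
  n_aff <- round(spec$affected_fraction * ng)
  ord <- sample.int(ng)
  noise <- logical(ng); noise[ord[seq_len(n_noise)]] <- TRUE
  rest <- ord[setdiff(seq_len(ng), seq_len(n_noise))]
  mixture <- logical(ng)
  mixture[head(rest, min(n_mix, length(rest)))] <- TRUE
  # affected genes are drawn uniformly over non-mixture genes (an
  # independent permutation, so noise and affected flags are not confounded)
  affected <- logical(ng)
  affected[head(setdiff(sample.int(ng), which(mixture)), n_aff)] <- TRUE

  # ---- means ------------------------------------------------------------
  mu <- numeric(ng)
  if (log_ratio) {
    mag <- runif(ng, spec$noise_floor, max(abs(spec$mean_range)))
    mu <- mag * sample(c(-1, 1), ng, replace = TRUE)
    mu[noise] <- runif(sum(noise), -spec$noise_floor, spec$noise_floor)
  } else {
    mu <- runif(ng, spec$mean_range[1L], spec$mean_range[2L])
    mu[noise] <- runif(sum(noise), max(spec$mean_range[1L] - 4, 1),
                       spec$noise_floor)
  }

  # ---- CV from the trend, SD from CV -------------------------------------
  pred <- if (log_ratio) abs(mu) else mu
  cv <- 10^(spec$cv_trend[1L] + spec$cv_trend[2L] * pred +
              rnorm(ng, 0, spec$cv_jitter_sd))
  cv[noise] <- cv[noise] * spec$noise_cv_factor
  s <- cv * pmax(abs(mu), if (log_ratio) 0.02 else abs(mu))

  # ---- shape targets -----------------------------------------------------
  if (spec$shape == "polynomial") {
    S <- pmin(pmax(rnorm(ng, spec$skew_mean, spec$skew_sd),
                   spec$skew_limits[1L]), spec$skew_limits[2L])
    K <- spec$kurt_skew_trend[1L] + spec$kurt_skew_trend[2L] * S +
      spec$kurt_skew_trend[3L] * S^2 + rnorm(ng, 0, spec$kurt_noise_sd)
    # keep targets inside the attainable region of the cubic transform
    # (empirical feasibility boundary ~ 1.85 + 1.58 S^2, plus margin)
    K <- pmax(K, 1.92 + 1.60 * S^2)
    K[noise] <- K[noise] + 2 * (spec$noise_cv_factor - 1)  # inflated tails
    fam <- rep("polynomial", ng)
  } else {
    fam <- sample(names(spec$family_weights), ng, replace = TRUE,
                  prob = spec$family_weights)
    S <- K <- numeric(ng)
  }
  fam[mixture] <- "normal_mixture"

  # ---- draw the matrix ---------------------------------------------------
  values <- matrix(NA_real_, ng, ns, dimnames = list(gene_id, sample_id))
  degenerate <- s == 0

  if (spec$shape == "polynomial") {
    idx <- which(!mixture)
    if (length(idx) > 0L) {
      cf <- fleishman_coef_matrix(S[idx], K[idx])
      if (spec$sampling == "stratified") {
        # one draw per probability stratum (randomly placed within it, then
        # permuted across samples): unbiased for the population moments with
        # far smaller estimation noise than iid sampling
        for (j in seq_along(idx)) {
          u <- (seq_len(ns) - runif(ns)) / ns
          z <- qnorm(u)[sample.int(ns)]
          g <- idx[j]
          values[g, ] <- mu[g] + s[g] *
            (cf[j, "a"] + z * (cf[j, "b"] + z * (cf[j, "c"] + z * cf[j, "d"])))
        }
      } else {
        z <- matrix(rnorm(length(idx) * ns), length(idx), ns)
        core <- cf[, "a"] + z * (cf[, "b"] + z * (cf[, "c"] + z * cf[, "d"]))
        values[idx, ] <- mu[idx] + s[idx] * core
      }
    }
  } else {
    for (f in unique(fam[!mixture])) {
      idx <- which(fam == f & !mixture)
      nf <- length(idx)
      if (nf == 0L) next
      if (f %in% c("lognormal", "gamma", "weibull") && any(mu[idx] <= 0)) {
        abort("Positive-support families need positive target means.")
      }
      draw <- switch(
        f,
        normal = matrix(rnorm(nf * ns, mean = mu[idx], sd = s[idx]), nf, ns),
        logistic = matrix(rlogis(nf * ns, location = mu[idx],
                                 scale = s[idx] * sqrt(3) / pi), nf, ns),
        extreme_value = {
          beta <- s[idx] * sqrt(6) / pi
          loc <- mu[idx] + 0.5772156649015329 * beta
          matrix(qgumbel_min(runif(nf * ns), rep(loc, length.out = nf * ns),
                             rep(beta, length.out = nf * ns)), nf, ns)
        },
        lognormal = {
          sdl <- sqrt(log(1 + (s[idx] / mu[idx])^2))
          ml <- log(mu[idx]) - sdl^2 / 2
          matrix(stats::rlnorm(nf * ns, meanlog = ml, sdlog = sdl), nf, ns)
        },
        gamma = {
          k <- (mu[idx] / s[idx])^2
          matrix(rgamma(nf * ns, shape = k, scale = mu[idx] / k), nf, ns)
        },
        weibull = {
          k <- vapply(s[idx] / mu[idx], weibull_shape_from_cv, numeric(1L))
          matrix(rweibull(nf * ns, shape = k,
                          scale = mu[idx] / gamma(1 + 1 / k)), nf, ns)
        }
      )
      values[idx, ] <- draw
      sk <- t(mapply(function(ff, cc) family_shape_moments(ff, cc), f,
                     pmax(s[idx] / abs(mu[idx]), 1e-12)))
      S[idx] <- sk[, 1L]; K[idx] <- sk[, 2L]
    }
  }

  # constant rows for zero-SD genes
  if (any(degenerate)) values[degenerate, ] <- mu[degenerate]

  # ---- mixture genes -----------------------------------------------------
  mix_idx <- which(mixture)
  for (i in mix_idx) {
    k <- sample(2:3, 1L)
    w <- runif(k, 0.2, 1); w <- w / sum(w)
    cm <- rnorm(k, 0, 1.5) * s[i]
    cm <- cm - sum(w * cm)          # center so the overall mean is mu
    cs <- s[i] * runif(k, 0.3, 0.7)
    comp <- sample.int(k, ns, replace = TRUE, prob = w)
    values[i, ] <- mu[i] + rnorm(ns, cm[comp], cs[comp])
    S[i] <- NA_real_; K[i] <- NA_real_
  }

  # ---- condition-dependent location shifts -------------------------------
  cond <- factor(spec$conditions, levels = unique(spec$conditions))
  k <- nlevels(cond)
  if (any(affected) && k >= 2L) {
    shifts <- spec$affected_effect * ((seq_len(k) - 1) / (k - 1) - 0.5)
    shift_by_sample <- shifts[as.integer(cond)]
    values[affected, ] <- values[affected, , drop = FALSE] +
      rep(shift_by_sample, each = sum(affected))
  }

  truth <- tibble(
    gene_id = gene_id, family = fam,
    true_mean = mu, true_sd = s, true_cv = cv,
    true_skewness = S, true_kurtosis = K,
    noise = noise, affected = affected, mixture = mixture,
    degenerate = degenerate
  )

  structure(
    list(
      expression = new_expr_mat_from_values(values, mode = spec$mode),
      truth = truth,
      conditions = condition_map(sample_id, as.character(cond)),
      spec = spec
    ),
    class = "synthetic_expression"
  )
}

#' @export
print.synthetic_expression <- function(x, ...) {
  cat("<synthetic_expression>", x$spec$n_genes, "genes x",
      x$spec$n_samples, "samples, mode:", x$spec$mode,
      ", shape:", x$spec$shape, "\n")
  cat("flags: ", sum(x$truth$noise), " noise, ", sum(x$truth$affected),
      " affected, ", sum(x$truth$mixture), " mixture\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the expression matrix, condition map and truth table as TSV and
#' the generating spec as JSON.
#'
#' @param sim A `synthetic_expression` from [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_expression"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    conditions = file.path(dir, "conditions.tsv"),
    truth = file.path(dir, "truth.tsv"),
    spec = file.path(dir, "spec.json")
  )
  write_expression(sim$expression, paths[["expression"]])
  write_condition_map(sim$conditions, paths[["conditions"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  spec_list <- unclass(sim$spec)
  spec_list$family_weights <- as.list(spec_list$family_weights)
  writeLines(jsonlite::toJSON(spec_list, auto_unbox = TRUE, digits = NA),
             paths[["spec"]])
  invisible(paths)
}
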