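# Theoretical (tau3, tau4) relationships for the L-moment ratio diagram.
#
# Three-parameter families trace curves; one/two-parameter families reduce
# to single points. GEV, GLO, GPA use closed-form expressions in the shape
# parameter; GNO and PE3 are computed by adaptive numeric quadrature of the
# quantile function against shifted Legendre polynomials (L-moment ratios
# are location/scale free, so standardized forms are integrated).

# shifted Legendre polynomials P*_0..P*_3 on (0, 1)
shifted_legendre <- list(
  function(u) rep(1, length(u)),
  function(u) 2 * u - 1,
  function(u) 6 * u^2 - 6 * u + 1,
  function(u) 20 * u^3 - 30 * u^2 + 12 * u - 1
)

# First four L-moments of a distribution given its quantile function,
# lambda_r = int_0^1 Q(u) P*_{r-1}(u) du.
lmoments_from_quantile <- function(qfun, lower = 0, upper = 1) {
  vapply(1:4, function(r) {
    integrate(function(u) qfun(u) * shifted_legendre[[r]](u),
              lower, upper, rel.tol = 1e-10, subdivisions = 500L)$value
  }, numeric(1L))
}

lmr_from_quantile <- function(qfun) {
  l <- lmoments_from_quantile(qfun)
  c(tau3 = l[3] / l[2], tau4 = l[4] / l[2])
}

# GEV with shape k (Hosking parametrization): closed forms.
gev_tau3 <- function(k) {
  ifelse(abs(k) < 1e-9,
         log(9 / 8) / log(2),
         2 * (1 - 3^(-k)) / (1 - 2^(-k)) - 3)
}
gev_tau4 <- function(k) {
  ifelse(abs(k) < 1e-9,
         (16 * log(2) - 10 * log(3)) / log(2),
         (5 * (1 - 4^(-k)) - 10 * (1 - 3^(-k)) + 6 * (1 - 2^(-k))) / (1 - 2^(-k)))
}

# GNO (generalized normal / three-parameter lognormal), standardized
# quantile Q(u) = (1 - exp(-k z)) / k with z = qnorm(u).
gno_lmr <- function(k) {
  if (abs(k) < 1e-8) return(c(tau3 = 0, tau4 = nor_point()[["tau4"]]))
  f <- function(r) {
    integrate(function(z) {
      (1 - exp(-k * z)) / k * shifted_legendre[[r]](pnorm(z)) * dnorm(z)
    }, -9, 9, rel.tol = 1e-10, subdivisions = 500L)$value
  }
  l2 <- f(2); l3 <- f(3); l4 <- f(4)
  c(tau3 = l3 / l2, tau4 = l4 / l2)
}

# PE3 (Pearson type III) with gamma shape a; negative skew by mirroring.
# Integrated over the central quantile range so the mass is never missed
# for large shapes (where the density is a narrow spike far from 0).
pe3_lmr <- function(a) {
  lo <- qgamma(1e-14, shape = a)
  hi <- qgamma(1e-14, shape = a, lower.tail = FALSE)
  f <- function(r) {
    integrate(function(x) {
      x * shifted_legendre[[r]](pgamma(x, shape = a)) * stats::dgamma(x, shape = a)
    }, lo, hi, rel.tol = 1e-10, subdivisions = 500L)$value
  }
  l2 <- f(2); l3 <- f(3); l4 <- f(4)
  c(tau3 = l3 / l2, tau4 = l4 / l2)
}

nor_point <- function() lmr_from_quantile(qnorm_trunc)
qnorm_trunc <- function(u) qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15))

.lmr_cache <- new.env(parent = emptyenv())

lmr_point <- function(family) {
  key <- paste0("pt_", family)
  if (!is.null(.lmr_cache[[key]])) return(.lmr_cache[[key]])
  val <- switch(
    EXPR = family,
    NOR = nor_point(),
    UNI = c(tau3 = 0, tau4 = 0),
    EXP = c(tau3 = 1 / 3, tau4 = 1 / 6),
    GUM = lmr_from_quantile(function(u) -log(-log(pmin(pmax(u, 1e-15), 1 - 1e-15)))),
    RAY = lmr_from_quantile(function(u) sqrt(-2 * log(pmax(1 - u, 1e-300))))
  )
  .lmr_cache[[key]] <- val
  val
}

# Tabulated (tau3, tau4) curve over a shape grid, for interpolation.
lmr_curve_table <- function(family) {
  key <- paste0("curve_", family)
  if (!is.null(.lmr_cache[[key]])) return(.lmr_cache[[key]])
  tab <- switch(
    family,
    GEV = {
      k <- c(seq(-0.95, -0.05, by = 0.05), seq(-0.04, 0.04, by = 0.01),
             seq(0.05, 1, by = 0.05), seq(1.1, 12, by = 0.1))
      tibble(tau3 = gev_tau3(k), tau4 = gev_tau4(k))
    },
    GNO = {
      k <- seq(-4.5, 4.5, by = 0.1)
      res <- t(vapply(k, gno_lmr, numeric(2L)))
      tibble(tau3 = res[, 1], tau4 = res[, 2])
    },
    PE3 = {
      a <- exp(seq(log(0.02), log(10000), length.out = 90L))
      res <- t(vapply(a, pe3_lmr, numeric(2L)))
      pos <- tibble(tau3 = res[, 1], tau4 = res[, 2])
      dplyr::bind_rows(
        tibble(tau3 = -rev(pos$tau3), tau4 = rev(pos$tau4)),
        tibble(tau3 = 0, tau4 = nor_point()[["tau4"]]),
        pos
      )
    }
  )
  tab <- dplyr::arrange(dplyr::distinct(tab, .data$tau3, .keep_all = TRUE), .data$tau3)
  .lmr_cache[[key]] <- tab
  tab
}

#' Theoretical L-moment ratio curve of a family
#'
#' Returns the (L-skewness, L-kurtosis) relationship traced by a family on
#' the L-moment ratio diagram. Three-parameter families (GEV, GLO, GNO,
#' GPA, PE3) trace curves parametrized by their shape; one- and
#' two-parameter families (EXP, NOR, GUM, RAY, UNI) reduce to single
#' points because L-moment ratios are invariant to location and scale.
#'
#' Closed forms: GLO \eqn{\tau_4 = (1 + 5\tau_3^2)/6}; GPA
#' \eqn{\tau_4 = \tau_3(1 + 5\tau_3)/(5 + \tau_3)}; GEV in the shape
#' parameter. GNO and PE3 are evaluated by numeric quadrature of the
#' quantile function and interpolated.
#'
#' @param family One of `"GEV"`, `"GLO"`, `"GNO"`, `"GPA"`, `"PE3"`,
#'   `"EXP"`, `"NOR"`, `"GUM"`, `"RAY"`, `"UNI"`.
#' @param tau3 Grid of L-skewness values for curve families (ignored for
#'   point families). Default: an even grid over `c(-0.9, 0.9)`.
#' @return A tibble with columns `family`, `tau3`, `tau4`.
#' @examples
#' lmoment_curve("GPA", tau3 = 1 / 3)  # tau4 = 1/6, the exponential point
#' lmoment_curve("NOR")
#' @export
lmoment_curve <- function(family, tau3 = NULL) {
  family <- match.arg(family, c("GEV", "GLO", "GNO", "GPA", "PE3",
                                "EXP", "NOR", "GUM", "RAY", "UNI"))
  if (family %in% c("EXP", "NOR", "GUM", "RAY", "UNI")) {
    p <- lmr_point(family)
    return(tibble(family = family, tau3 = unname(p[["tau3"]]),
                  tau4 = unname(p[["tau4"]])))
  }
  if (is.null(tau3)) tau3 <- seq(-0.9, 0.9, length.out = 61L)
  if (any(abs(tau3) >= 1)) abort("tau3 must lie strictly inside (-1, 1).")
  tau4 <- switch(
    family,
    GLO = (1 + 5 * tau3^2) / 6,
    GPA = tau3 * (1 + 5 * tau3) / (5 + tau3),
    GEV = {
      vapply(tau3, function(t3) {
        k <- uniroot(function(k) gev_tau3(k) - t3, c(-0.99, 30),
                     tol = 1e-12)$root
        gev_tau4(k)
      }, numeric(1L))
    },
    GNO = ,
    PE3 = {
      tab <- lmr_curve_table(family)
      if (any(tau3 < min(tab$tau3) | tau3 > max(tab$tau3))) {
        abort(paste0("tau3 outside the tabulated range for ", family, "."))
      }
      stats::spline(tab$tau3, tab$tau4, xout = tau3, method = "natural")$y
    }
  )
  tibble(family = family, tau3 = tau3, tau4 = tau4)
}

#' All theoretical curves and points for an L-moment ratio diagram
#'
#' @param tau3 Grid passed to [lmoment_curve()] for the curve families.
#' @return A tibble stacking every family's curve or point, with a
#'   `geometry` column (`"curve"` or `"point"`).
#' @export
lmoment_diagram_data <- function(tau3 = seq(-0.6, 0.9, length.out = 61L)) {
  curves <- purrr::map(c("GEV", "GLO", "GNO", "GPA", "PE3"), function(f) {
    dplyr::mutate(lmoment_curve(f, tau3), geometry = "curve")
  })
  points <- purrr::map(c("EXP", "NOR", "GUM", "RAY", "UNI"), function(f) {
    dplyr::mutate(lmoment_curve(f), geometry = "point")
  })
  dplyr::bind_rows(c(curves, points))
}
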