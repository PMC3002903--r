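Package: exprdist
Title: Distributional Characterization of Gene Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize the empirical distribution of gene
    expression measured on microarray-style platforms. Screens probe sets
    unaffected by experimental conditions with the Kruskal-Wallis test,
    fits candidate univariate distributions (normal, lognormal, logistic,
    log-logistic, Weibull, extreme value, gamma, Pareto) by maximum
    likelihood, calibrates Kolmogorov-Smirnov and Anderson-Darling
    goodness-of-fit tests under composite nulls by parametric bootstrap,
    fits normal mixtures by EM with chi-square comparison, computes
    product moments and sample L-moments with L-moment ratio diagrams,
    and quantifies the linear mean versus log coefficient-of-variation
    and quadratic kurtosis versus skewness moment relationships. Includes
    a synthetic expression-matrix generator emulating these structures so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    mclust,
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
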