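# exprdist

Distributional characterization of gene-expression matrices.

Statistical analyses of microarray (and other) expression data routinely
assume a parametric form for each gene's expression distribution — normal
for classical linear-model inference, gamma or lognormal in error models,
normal priors in empirical-Bayes moderation. `exprdist` provides a tested
pipeline for asking whether such assumptions hold in a gene × sample matrix
of log-scale expression, and for characterizing what the data look like
instead:

* **Screening.** Kruskal–Wallis tests per gene across experimental
  conditions identify *unaffected* genes (`p > 0.1` by default), so that
  distribution fitting is not confounded by condition-induced shifts; a
  mean-expression noise floor (6 on the log scale for single-color data,
  0.05 absolute log-ratio for two-color data) separates genes measured as
  signal from optical/ratio noise. For two-color data an active-gene set
  can be expanded by Pearson correlation (`p < 1e-5`).
* **Distribution fitting and testing.** Maximum-likelihood fits of eight
  candidate families (normal, lognormal, logistic, log-logistic, Weibull,
  minimum-type extreme value, gamma, Pareto), with Kolmogorov–Smirnov and
  Anderson–Darling statistics calibrated for the composite null (parameters
  estimated from the tested data) by a Lilliefors-style parametric
  bootstrap, reporting rejections at the 90% and 95% levels. Normal
  mixtures are fitted by EM and compared by a chi-square test with
  equal-probability bins.
* **Moment structure.** Per-gene product moments with plug-in (1/n)
  estimators — so every sample respects the distributional bound
  `K ≥ S² + 1` relating kurtosis and skewness — and unbiased sample
  L-moments (ℓ₁, ℓ₂, τ₃, τ₄) via probability-weighted moments, plus the
  theoretical (τ₃, τ₄) curves of GEV, GLO, GNO, GPA, PE3 and the EXP, NOR,
  GUM, RAY, UNI points for L-moment-ratio diagrams.
* **Moment relationships.** OLS fits of the linear trend
  `log10(CV) = a + b·mean` and the quadratic trend `K = c0 + c1·S + c2·S²`
  over the signal stratum, loess-style smooths of the noise stratum,
  residual heteroscedasticity diagnostics, and the Spearman rank
  correlation between per-gene mean and SD.
* **Synthetic studies.** A generator that emulates this structure —
  CV trend, kurtosis–skewness trend, noise stratum, condition-affected
  genes, mixture genes — with a per-gene ground-truth table, so the whole
  pipeline is testable end to end without downloading anything.

Functions take data frames first and return tibbles; fitted objects have
`tidy()`/`glance()` methods and ggplot2 helpers (`autoplot()`,
`plot_lmoment_diagram()`, `plot_moment_scatter()`).

## Worked example

Simulate a three-condition developmental time-course (105 arrays, 2000
genes, 20% noise-floor genes, 30% condition-affected genes) and
characterize it:

```r
library(exprdist)

spec <- synthetic_spec(
  n_genes = 2000, conditions = c(E10.5 = 35, E11.5 = 35, E12.5 = 35),
  noise_fraction = 0.2, affected_fraction = 0.3, seed = 42
)
sim <- simulate_expression(spec)

ch <- characterize_expression(sim$expression, sim$conditions)
#> screen_unaffected: 1263/2000 genes retained at alpha = 0.1.
ch
#> <expr_characterization>
#> screened: 1263 of 2000 genes retained
#> strata: 1001 signal / 262 noise genes
#> log10(CV) trend: intercept -2.130, slope -0.218 (R^2 0.96)
#> K(S) trend: 2.827 -0.038 S +1.764 S^2 (R^2 0.12)
#> Spearman rho(mean, sd): -0.982
```

The screen keeps the ~90% of unaffected genes a liberal 0.1 cutoff should
keep (affected genes are removed with high power at this effect size); the
fitted log10(CV)-vs-mean line recovers the generator's trend
(intercept −2.10, slope −0.22) up to sampling noise, and the strong
negative Spearman correlation restates it nonparametrically.

Test one gene's distributional fit with a bootstrap-calibrated
Anderson–Darling and Kolmogorov–Smirnov test:

```r
x <- expr_values(sim$expression)["g00017", ]
bootstrap_gof(x, "normal", stats = c("ad", "ks"), B = 1000, seed = 1)
#>   family statistic      value   p_value reject_90 reject_95    B   n seed
#> 1 normal        ad 0.43600976 0.3176823     FALSE     FALSE 1000 105    1
#> 2 normal        ks 0.06662237 0.3206793     FALSE     FALSE 1000 105    1
```

This gene was generated normal, and neither statistic rejects. Batch
versions (`batch_gof()`) summarize rejection fractions per family together
with the fraction of genes for which at least one family survives.

L-moment-ratio diagram data for family identification:

```r
lmoment_curve("GPA", c(0.1, 1/3, 0.5))
#>   family      tau3       tau4
#> 1    GPA 0.1000000 0.02941176
#> 2    GPA 0.3333333 0.16666667
#> 3    GPA 0.5000000 0.31818182
mom <- moment_summary(sim$expression)
plot_lmoment_diagram(mom)   # genes over the theoretical curves
```

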