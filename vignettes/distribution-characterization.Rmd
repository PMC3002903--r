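---
title: "Characterizing expression distributions: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing expression distributions: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprdist)
```

# The problem

Expression measured on single-color microarray platforms is summarized as a
log2-scale value per gene (probe set) per array; two-color platforms yield
log ratios against a reference pool, which can be negative. Most downstream
statistics lean on a distributional assumption for the per-gene values
across samples. `exprdist` implements the machinery to interrogate that
assumption on a gene × sample matrix: screen out genes that the
experimental conditions actually shifted, fit candidate families by
maximum likelihood, calibrate goodness-of-fit tests under the composite
null, and — since no single family tends to survive — describe the
*relationships between moments* that the data do exhibit.

The pipeline consumes already-normalized matrices. Probe-level
preprocessing (background correction, summarization) is out of scope;
cross-batch quantile normalization is provided (`quantile_normalize()`,
delegating to limma's implementation with mean reference quantiles and
tie-sharing) because large compendia must be normalized batch-wise.

# Screening and stratification

**Unaffected genes.** A per-gene Kruskal–Wallis test across condition
groups (tie-corrected mid-ranks, chi-square approximation with $k-1$
degrees of freedom) flags genes whose location any condition shifted.
Genes with $p > \alpha$ are retained; the default $\alpha = 0.1$ is
deliberately liberal — the cost of keeping a slightly affected gene is a
mild distortion of one gene's distribution, while the cost of testing an
affected gene is a spurious rejection of every candidate family. Under the
null the screen loses exactly $\alpha$ of the genes, a property the tests
verify. The chi-square approximation is adequate for the group sizes in
scope (three or more replicates per condition); no exact small-sample
enumeration is attempted.

**Noise floor.** Low-intensity measurements behave as optical noise
(single-color) or unstable ratios (two-color): their CV, skewness and
kurtosis are inflated and carry no biological signal. Genes enter the
signal stratum only if their mean *strictly exceeds* the floor — 6 log2
units for log-expression, 0.05 absolute mean log-ratio for two-color data.
The boundary is exclusive on both scales so that a gene sitting exactly on
the floor is treated as noise. In the noise stratum no parametric trend is
assumed; `loess_smooth()` describes it with tricube-weighted local linear
regression (span 0.75, no robustness iterations), implemented directly so
that its window rule — the span fraction of nearest neighbors, widened
with a warning if a window degenerates — is exactly the documented one.

**Active-set expansion (two-color).** Given a seed set of transcriptionally
active genes, `expand_active()` adds every gene whose Pearson correlation
with at least one seed gene is significant at $p < 10^{-5}$ (two-sided
t transformation; sidedness is a package choice, as conventions differ).

# Distribution fitting

`fit_mle()` covers eight families. Closed forms are used where they exist:
normal (mean and the $1/n$-normalized SD), lognormal (normal fit of the
logs), Pareto ($\hat x_m = \min x$, $\hat\alpha = n / \sum \ln(x_i/\hat
x_m)$; the minimum convention for $\hat x_m$ is the standard ML choice).
The gamma shape solves $\ln k - \psi(k) = \ln \bar x - \overline{\ln x}$
by Newton iteration from a Minka-style starting value; Weibull uses the
profile equation in the shape with powers taken of $x/\max(x)$ so large
shapes cannot overflow; the extreme-value (Gumbel) family solves its
profile scale equation by bracketed root finding; the logistic is the one
family fitted by direct numerical likelihood maximization. The
extreme-value family is minimum-type by default (left-skewed, matching the
left tails typical of log expression), with the maximum-type behind
`gumbel = "max"`.

Positive-support families (lognormal, log-logistic, Weibull, gamma,
Pareto) refuse nonpositive data; for log-ratio matrices only the normal,
logistic and extreme-value families are applicable, and `batch_gof()`
records the others as `NA` rather than failing. All families are fitted
directly to the supplied log-scale values (no second log, no
re-exponentiation): normalized single-color output is strictly positive,
which is what the log-family fits require.

**Normal mixtures.** `fit_mixture_em()` is a standard univariate EM with
k-means initialization plus random restarts, a component-SD floor of
$10^{-6}$ times the data SD against variance collapse, relative
log-likelihood tolerance $10^{-8}$, and a 1000-iteration cap. The cap
matters: for weakly separated (or unimodal) data the mixture likelihood is
nearly flat and EM can need several hundred iterations; stopping early
leaves the fit short of the ML and visibly biases the chi-square model
comparison below. With $k=1$ the fit reduces exactly to the closed-form
normal MLE, and the per-iteration log-likelihood trace is retained so the
monotonicity of EM is a tested invariant.

# Goodness of fit under a composite null

With parameters estimated from the same data, the textbook critical values
of the Kolmogorov–Smirnov statistic
$D = \max_i \max\{i/n - F(x_{(i)}),\ F(x_{(i)}) - (i-1)/n\}$ and the
Anderson–Darling statistic
$A^2 = -n - \tfrac1n \sum_i (2i-1)[\ln F(x_{(i)}) + \ln(1-F(x_{(n+1-i)}))]$
are invalid. `bootstrap_gof()` calibrates both by the Lilliefors-style
parametric bootstrap: fit $\hat\theta$, simulate $B$ samples from
$F(\hat\theta)$, refit each, recompute the statistic, and take
$p = (1 + \#\{A^2_b \ge A^2_{\rm obs}\})/(B+1)$ — a convention that can
never produce a literal zero. One mechanism serves all eight families
(published critical-value tables exist for six of them, but the bootstrap
converges to those tables and removes the table-lookup special case); for
the normal and lognormal families the location-scale structure makes the
null distribution parameter-free, and the $B$ replicates are computed in
closed form as a vectorized batch. $B = 1000$ by default; per-gene seeds
derive from a master seed plus the gene index, so batch runs are
reproducible and order-independent. Rejection flags are reported at both
the 90% and 95% levels, and `reject_95 ⇒ reject_90` is an invariant.

The chi-square test (`chisq_gof()`) uses equal-probability bins under the
fitted model — by default $\min(25, \max(4, \lfloor n/10\rfloor))$ bins,
constrained to expected counts of at least 5 — with
$\mathrm{df} = \text{bins} - 1 - p$ where $p$ counts estimated parameters
($3k - 1$ for a $k$-component mixture). This df convention is the
conventional correction, not an exact one: when parameters are estimated
from the raw data rather than the binned counts, the statistic is
stochastically larger than $\chi^2_{\mathrm{df}}$ (Chernoff–Lehmann), and
the discrepancy grows with the number of *barely identifiable* parameters.
Fitting a 3-normal mixture to unimodal data is the extreme case: the extra
six parameters move the binned fit by much less than six degrees of
freedom, so the $k=3$ test over-rejects relative to $k=1$ even on exactly
normal data. The package therefore phrases the mixture comparison
directionally — the mixture shows *no improvement* over the single normal
— which is also the scientifically meaningful statement; expecting the two
rejection fractions to be equal would build the df approximation's failure
into the acceptance of the package.

# Moments and L-moments

`product_moments()` uses plug-in ($1/n$) estimators throughout:
$S = m_3/m_2^{3/2}$ and $K = m_4/m_2^2$ with $m_r = n^{-1}\sum(x_i-\bar
x)^r$, kurtosis on the raw scale (normal = 3). The plug-in choice is
deliberate: these are the population moments *of the empirical
distribution*, so the distributional inequality $K \ge S^2 + 1$ holds for
every sample exactly, and the theoretical boundary can be drawn under
sample scatter without apologies. Bias-adjusted estimators would break
this sample-wise guarantee.

`sample_lmoments()` implements Hosking's unbiased estimators via
probability-weighted moments of the order statistics, with
$\tau_3 = \ell_3/\ell_2$ and $\tau_4 = \ell_4/\ell_2$. One subtlety the
test suite documents explicitly: the attainability bound
$\tau_4 \ge (5\tau_3^2-1)/4$ is a *population* property. The unbiased
sample ratios satisfy it empirically for continuous data at the sample
sizes in scope (verified over $10^5$-sample sweeps of normal, gamma,
logistic, lognormal and Weibull draws), but heavily tied discrete samples
— and tiny samples — can violate it, and a concrete counterexample is kept
in the tests. Unbiasedness itself is asserted only for $\ell_1$ and
$\ell_2$; ratios of unbiased estimators are not unbiased.

The theoretical curves for the L-moment-ratio diagram use closed forms
where available (GLO: $\tau_4 = (1+5\tau_3^2)/6$; GPA:
$\tau_4 = \tau_3(1+5\tau_3)/(5+\tau_3)$; GEV in its shape parameter,
inverted by root finding) and adaptive numeric quadrature of the quantile
function against shifted Legendre polynomials for GNO and PE3 (tabulated
over a shape grid, interpolated by natural splines; published polynomial
approximations would be an alternative, but quadrature keeps one mechanism
and is accurate to far better than the 0.002 the oracle tests demand).
Point families (EXP, NOR, GUM, RAY, UNI) are evaluated the same way —
numerically, not from typed-in constants — and checked against their known
closed forms in the tests.

# Trend models

`fit_log_cv_vs_mean()` regresses $\log_{10}(\mathrm{CV})$ on the mean over
the signal stratum; `fit_kurt_vs_skew()` regresses $K$ on $(1, S, S^2)$.
Both report OLS coefficients with standard errors, $R^2$ and the overall
F-test p-value (to machine precision — a printed "0" means below print
precision, never literal zero), and the quadratic fit counts
bound violations ($K < S^2+1$), expected to be zero on any input produced
by the package's own moment estimators. The base-10 convention for the CV
trend is a package-wide choice; coefficients under a natural-log
convention differ only by the factor $\ln 10$, and generator and fit share
one convention so recovery studies are base-invariant. OLS standard errors
are reported even though the residuals of both models are heteroscedastic
on real-looking data; rather than attempting a weighted or robust variant
(deliberately out of scope), `residual_diagnostics()` quantifies the
violation — Pearson correlation of $|e_i|$ with each covariate, plus a
bootstrap-calibrated normality p-value on the residuals.

# The synthetic-data generator

`synthetic_spec()`/`simulate_expression()` define the study conditions the
tests run under. Per gene: a mean drawn uniformly (default 6–14 for
log-expression, the post-cutoff signal range; noise genes 2–6), a CV from
$\log_{10}\mathrm{CV} = a + b\cdot\mathrm{mean}$ with lognormal jitter
(default $\sigma = 0.1$ in $\log_{10}$ units) and default trend
$(-2.10, -0.22)$, a tissue-panel scale; noise genes get their CV inflated
threefold, a stand-in for the "unusually high" low-intensity scatter that
no published generative model constrains. Condition-affected genes receive
location-only shifts, evenly spaced across conditions so the extreme
conditions differ by exactly `affected_effect` (real condition effects
also change shape; that is intentionally not modeled). Mixture genes draw
from 2–3 normal components with randomized weights and separations.
Affected genes are drawn independently of the noise stratum, so the two
labels are not confounded.

**Controlling skewness and kurtosis.** Two modes:

* `shape = "family"` draws each gene from one parametric family
  (normal, logistic, extreme value, lognormal, gamma, Weibull),
  moment-matched to the gene's mean and SD. This is the right mode for
  GOF-calibration studies — the data really do come from the tested
  family — but each family traces a fixed one-parameter curve in the
  $(S, K)$ plane (gamma: $K = 3 + 1.5S^2$; nothing reaches $K < 3$ at
  $S = 0$), so no family mix can follow an arbitrary quadratic whose
  constant is below 3.
* `shape = "polynomial"` uses a Fleishman cubic polynomial of a standard
  normal, $X = a + bZ + cZ^2 + dZ^3$, with coefficients solved by damped
  Newton iteration to hit each gene's $(\mu, \sigma, S, K)$ exactly. Genes
  draw a target skewness (normal, mean $-0.39$, SD $0.6$, truncated to
  $[-1.5, 1.2]$ — matching the left-skewed averages seen on single-color
  platforms) and a kurtosis on the quadratic trend (default
  $(2.96, -0.31, 1.40)$) plus Gaussian scatter with SD 0.3, which
  reproduces a trend $R^2$ near 0.9. Targets are clamped to the
  polynomial's attainable region ($K \gtrsim 1.85 + 1.58 S^2$, mapped
  empirically, with a small margin); the clamp binds for well under 1% of
  genes at the default settings.

**Sampling designs.** `sampling = "iid"` draws each gene's samples
independently. `sampling = "stratified"` (polynomial mode) places one draw
in each probability stratum of the gene's distribution — $u_i = (i -
U_i)/n$, transformed through the quantile function and permuted across
samples. Stratification is unbiased for every population moment but
shrinks the estimation noise of the plug-in third and fourth moments
several-fold. That matters for moment-*relationship* studies: with iid
sampling the estimation errors of $\hat S$ and $\hat K$ are strongly
correlated (correlation near $\pm 0.9$, sign following the skewness), and
regressing $\hat K$ on $\hat S$ then inflates the fitted curvature by an
$O(1/n_{\rm samples})$ term that, at $10^4$ genes, exceeds the OLS
standard errors for any affordable sample count. The recovery study
therefore runs the quadratic-trend configuration at 5000 stratified
samples per gene (between the ~100-array tissue panels and the
several-thousand-array compendium scale), where recovery sits comfortably
within 3 standard errors; the CV-trend configuration uses a realistic
105-array iid design, where second-moment estimation is benign.

**What the generator does not emulate.** Probe-level artifacts, spatial
effects, cross-gene correlation, condition-dependent shape changes, and
the specific tail behavior of real normalization pipelines. Passing tests
on synthetic data therefore validate the *estimators and their
relationships under the stated model*, not the claim that real platforms
follow that model — on real data the same machinery is the instrument for
finding out.

# Numerical choices and degenerate inputs

Constant genes are flagged degenerate: MLE refuses them, product moments
return `NA` standardized moments with a zero-variance flag, L-moments
return $\ell_2 = 0$ with undefined ratios. AD statistics become `Inf`
when any fitted CDF value touches 0 or 1 (counted against the null in
bootstrap comparisons). The bootstrap p-value floor is $1/(B+1)$.
Quantile normalization resolves within-sample ties by sharing the mean of
the tied reference quantiles. Mixture quantiles invert the CDF by
bracketed root finding. The Fleishman solver retries from several starting
points and reports genuinely infeasible targets as errors rather than
returning an approximate transform. Problem sizes in the shipped tests and
acceptance script ($10^4$ genes, up to 5000 samples, $B = 1000$, $10^5$
bound-sweep samples) were chosen so the statistical assertions have the
power they need while a full run stays in the minutes range on one CPU.

# Known limitations

* Bootstrap GOF for families without closed-form refits (logistic,
  Weibull, gamma, extreme value, log-logistic, Pareto) loops over
  replicates and is orders of magnitude slower than the vectorized
  normal/lognormal path; batch studies at $B = 1000$ are practical mainly
  for the location-scale-in-log families.
* The chi-square df convention over-rejects for overparameterized models
  (see above); treat mixture-vs-single comparisons directionally.
* The L-moment attainability bound is not a sample-wise guarantee for
  unbiased estimators; diagrams of very small or heavily tied samples can
  show points below the theoretical boundary.
* OLS standard errors for the trend fits inherit the heteroscedasticity
  they diagnose; confidence statements based on them are approximate by
  construction.
* The heteroscedastic-ANOVA residual-bootstrap alternative to the
  Kruskal–Wallis screen is not implemented (its published description is
  not specific enough to reproduce faithfully).
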