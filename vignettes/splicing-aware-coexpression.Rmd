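---
title: "Splicing-aware testing of gene–gene co-expression: model, methods, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing-aware testing of gene-gene co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecor)
```

## The problem

Bulk RNA-seq measures each gene's *total expression* (TE): the sum over
all of the gene's isoforms in a sample. When different isoforms of a
regulator gene have different effects on a target gene, the TE–TE
correlation between the two genes is not one number — it varies across
samples with the regulator's isoform composition. A sample enriched for
the active isoform shows a strong correlation; a sample dominated by an
inert isoform shows none. Standard correlation tests average over this
heterogeneity and can miss such pairs entirely.

`splicecor` models this directly. Isoform composition is summarized by
LeafCutter-style *intron excision ratios* (IERs): within an intron
cluster, the per-sample excision ratios sum to one and act as a
surrogate for relative isoform usage.

## The model

For mean-centered expression vectors $y$ (response gene) and $x$
(predictor/regulator gene) over $n$ samples, with covariate design $Z$
(intercept included):

$$y = x\beta_1 + \mathrm{diag}(x)\,\beta_2 + Z\gamma + u + \varepsilon,$$

where $\beta_1$ is the usual fixed TE–TE slope, $\beta_2 \in
\mathbb{R}^n$ is a per-sample *random slope* with $\beta_2 \sim N(0,
\sigma^2_{Int}\Sigma)$, $u \sim N(0, \sigma^2_u \Sigma)$ is a random
intercept, and $\varepsilon \sim N(0, \sigma^2_e I)$. The matrix
$\Sigma$ is the *splicing kernel*: the sample–sample covariance of the
predictor gene's IER profile. Samples with similar isoform composition
are assumed to share similar slopes. Mean-centering $y$ and $x$ is
recommended (and done by `center_and_align()`); the test remains valid
without it but implicitly reweights genes by their means.

### The splicing kernel

The data never specify $\Sigma$ — only the IER block. `build_kernel()`
standardizes each intron across samples (mean 0, variance 1; constant
introns are dropped), forms the Gram matrix
$\Sigma = \tilde W \tilde W^\top / k$ over the $k$ surviving introns,
and rescales so $\mathrm{trace}(\Sigma) = n$. Standardize-then-Gram is
the convention used throughout kernel-based interaction testing; the
trace normalization puts $\sigma^2_u, \sigma^2_{Int}$ on a scale
comparable across genes with different intron counts. A raw-covariance
mode (`standardize = FALSE`) is kept for sensitivity analysis.
Within-cluster IERs sum to one and are therefore collinear; we do *not*
drop one intron per cluster — the Gram construction is basis-invariant
and rank deficiency is handled everywhere downstream. The same
construction accepts any covariate block (`kernel_from_covariates()`),
including many more covariates than samples.

Only the nonzero eigenpairs of $\Sigma$ (rank $\le k$) are computed,
via the thin SVD of $\tilde W$; eigenvalues below $10^{-8}$ of the
largest are truncated to exactly zero so that every downstream mixture
weight agrees on the null directions.

## Fitting the null model

Under $H_0: \sigma^2_{Int} = 0$ the covariance is $V = \sigma_u^2\Sigma
+ \sigma_e^2 I$. `fit_null()` profiles the single ratio $\delta =
\sigma^2_u/\sigma^2_e$ by 1-D optimization of the ML log-likelihood on
the log scale over $[10^{-6}, 10^6]$ (tolerance $10^{-8}$), with the
exact boundary $\delta = 0$ also evaluated, so data without a random
intercept reduce to OLS exactly. Fixed effects are GLS at each
$\delta$; $\sigma_e^2$ is closed-form. All algebra runs through the
kernel's nonzero eigenpairs (rank-$k$ Woodbury identities), so a fit
costs $O(nk^2)$, not $O(n^3)$, and the eigen-work is done once per
predictor gene and shared across every response gene — the decisive
cost saving in an all-pairs scan. ML (not REML) is the default because
the score-test covariance $V$ is defined through the ML estimates;
REML is available behind a flag for sensitivity checks. Boundary
estimates $\hat\sigma^2_u = 0$ are accepted silently — no
likelihood-ratio machinery is used, so no boundary correction is
needed.

## The interaction test

The score statistic for $H_0: \sigma^2_{Int} = 0$ is

$$Q = (y-\hat y)^\top V^{-1}\mathrm{diag}(x)\,\Sigma\,\mathrm{diag}(x)
V^{-1}(y-\hat y),$$

a quadratic form whose null distribution is a weighted sum of 1-df
chi-squares. The weights matter. The *projected* form — eigenvalues of
$B^\top P B$ with $\mathrm{diag}(x)\Sigma\,\mathrm{diag}(x) = BB^\top$
and $P = V^{-1} - V^{-1}M(M^\top V^{-1}M)^{-1}M^\top V^{-1}$,
$M = [x, Z]$ — accounts for both the $x$-modulation and fixed-effect
estimation, and is the form that calibrates: at $n = 300$, $k = 5$,
2,000 null replicates, the empirical size at $\alpha = 0.05$ is 0.048
with p-values passing Kolmogorov–Smirnov uniformity. The naive
alternative (using the eigenvalues of $\Sigma$ itself as weights)
ignores $\mathrm{diag}(x)$ and the projection and does not calibrate;
it is retained behind `weights = "kernel_only"` for comparison only.

### Mixture-of-chi-square p-values

Two routes are provided:

* `liu_pvalue()` — Liu–Tang–Zhang four-cumulant moment matching (the
  modified kurtosis variant used across the SKAT family). Fast and
  adequate in the rejection region.
* `davies_pvalue()` — the exact tail, primarily via Ruben's expansion
  of the mixture as an infinite series of central chi-square tails on a
  common scale (truncated at $10^{-14}$ relative, with the term budget
  scaled to $Q/\beta$), falling back to numerical inversion of the
  characteristic function, and to Liu (flagged) only if both fail.
  Weights carrying less than $10^{-7}$ of the total scale are dropped
  first; they perturb the tail by less than the integration tolerance.

A caution worth stating plainly: moment matching is *not* accurate to
$10^{-3}$ across the body of the distribution. For heterogeneous weight
sets the absolute error of Liu's method reaches a few $10^{-2}$ around
$p \approx 0.7$ and a few $10^{-3}$ inside $[10^{-4}, 0.05]$ (we
verified this against the Ruben series, itself validated against
closed forms and Monte Carlo). The interaction test therefore uses Liu
with an automatic switch to the exact method below $p = 10^{-4}$,
which reproduces the conventional choice; the joint test (below) needs
more.

## The joint association test

To test the predictor's fixed and random slope together, the model is
rewritten so both live in one variance component with kernel

$$K(\rho) = (1-\rho)\,\mathbf{1}\mathbf{1}^\top + \rho\,\Sigma,
\qquad
\rho = \frac{\sigma^2_{Int}}{\sigma^2_{Int} + \sigma^2_X},$$

where $\sigma^2_X$ carries the overall slope and $\rho$ is the
proportion of the predictor's contribution attributable to
splicing-induced variation. The null model for this test excludes $x$
entirely (covariates and random intercept only). Since $\rho$ is
unknown, $Q(\rho)$ is evaluated on the grid $\{0, 0.1, \ldots, 1\}$
and the grid p-values are aggregated by the Cauchy combination, which
is valid under arbitrary dependence. A point-estimate plug-in mode
(`fixed_rho`) is exposed; scanning-plus-combination is the default
because it is the established practice in this test family and keeps
the null tractable.

Two deliberate choices here:

* **Exact per-leg p-values.** At intermediate $\rho$ one mixture
  weight dominates and Liu's body error is at its worst; feeding such
  legs into the Cauchy combination visibly inflates it (measured
  $\approx 0.07$ at $\alpha = 0.05$). With exact legs the combination
  sits at 0.060 over 2,000 null replicates — acceptable, though still
  mildly anti-conservative, a known property of the combination at
  non-tail thresholds under strong dependence.
* **$\rho = 0$ reduction.** At $\rho = 0$ the statistic collapses to
  the GLS score/Wald test of the slope given $V$ from the
  covariate-only null — i.e. the standard correlation test adjusting
  for covariates *and* splicing. `correlation_test(mode =
  "gls_kernel")` implements exactly that statistic (chi-square
  reference), so the equivalence holds to machine precision. The
  `"ols"` mode is the classical t-test; the two coincide under a
  boundary random-intercept estimate only when both use the same
  reference and residual-scale convention, which the `reference`
  argument makes explicit.

### Estimating the variance partition

$\hat\rho$ as reported (`estimate_rho()`) comes from the full
four-component ML fit, with covariance
$\sigma^2_X xx^\top + \sigma^2_{Int}\,\mathrm{diag}(x)\Sigma\,
\mathrm{diag}(x) + \sigma^2_u\Sigma + \sigma^2_e I$ — not from the
grid argmin (`rho_star`), which is also reported but is a test-side
quantity. All four kernels are low-rank, so each likelihood evaluation
works on a $(2k{+}1)$-dimensional core; optimization is L-BFGS-B on
log variance ratios, bounds $[-18, 8]$, from three fixed starts.
Ratios ending at the lower bound are reported as exact zeros.
Non-convergence is flagged, never thrown, so a genome scan continues
past pathological pairs.

Two honest caveats, both visible in our tests: ML variance components
built on a rank-$k$ kernel have heavy small-sample skew — with $k = 5$
the median of $\hat\sigma^2_{Int}$ under-shoots truth by roughly 17%,
shrinking to under 10% at the more typical $k = 8$; and under a true
zero the estimate sits exactly at the boundary only ~60% of the time,
the remainder being small positive values (all below 0.05 in our
$n = 500$ runs). $\hat\rho$ itself is recovered with median error
within 0.1 across truths $\{0, 0.5, 0.75, 1\}$ at $n = 1000$.

## Multiple testing and networks

Pooled Benjamini–Hochberg (via `stats::p.adjust`), response-stratified
FDR (BH within each response gene's tests — matching the
many-predictors-per-response geometry of a scan; the stratum key is
configurable), Bonferroni thresholds, and Storey's $\pi_0$ using the
deterministic $\lambda$-average estimator (grid $0.05, \ldots, 0.95$)
rather than the spline smoother.

Networks are directed: an edge predictor $\to$ response for every pair
passing the stratified FDR on the chosen test. Hubs are genes with
outdegree $\ge 5$, ties broken lexicographically for deterministic
output. Pathway comparisons use the size-adjusted mean outdegree (total
outdegree divided by pathway size). Multi-tissue scans are summarized
by per-pair tissue-sharing counts and per-gene, per-tissue outdegree
matrices; sharing is computed both at the pair level and at the hub
level, since the two answer different questions. Differential
correlation between two sample groups (e.g. tumor versus adjacent
normal) is a Wald test on the $x \times \mathrm{group}$ coefficient in
the stacked covariate-adjusted linear model — preferred over Fisher's z
on residual correlations because it respects covariate adjustment
exactly; the Fisher-z contrast is available as an alternative mode.

## The synthetic-data generator

`simulate_pair()` and `simulate_cohort()` draw data *exactly* under the
model above: per-sample isoform compositions from a symmetric Dirichlet
(one intron cluster per gene, so ratios sum to one by construction),
the kernel built by the same `build_kernel()` code, and
$\beta_2, u, \varepsilon$ from their stated distributions through the
kernel's matrix square root. Defaults — $n = 300$ samples, $k = 5$
introns, Dirichlet concentration 1, three standard-normal covariates
with effects 0.5, $\sigma^2_u = 0.3$, $\sigma^2_e = 1$, slope
$\beta_1 = 0.3$ and $\sigma^2_{Int} = 0.5$ where the scenario activates
them — describe a moderately heterogeneous bulk-tissue cohort of
realistic size; concentration 1 gives strong inter-sample composition
variability, the regime in which splicing-induced slope variation is
a first-order phenomenon. Scenario presets (`null`, `fixed_only`,
`interaction_only`, `mixed`) set the signal parameters consistently.

In cohorts, signal pairs are drawn among forward-ordered gene pairs so
the effects form a DAG and accumulate through the *observed* predictor
expression. A consequence: indirect effects (A affects B, B affects C)
are genuinely present, so end-to-end error rates are assessed on
recovery of designated pairs, not on the false-discovery proportion,
which counts real indirect paths as errors. A `confounded` mode
correlates the predictor's expression with its own composition to
exercise confounding-reduction analyses.

What the generator does **not** emulate: read-level sampling noise and
LeafCutter quantification error (IERs are exact compositions),
cell-type mixing, realistic covariate structure (PEER-factor-like
surrogates), library-size or normalization artifacts, and missing-data
patterns beyond what `load_ier()`'s `0/0` convention produces. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to the full messiness of real
bulk RNA-seq.

## Numerical conventions, in one place

* Eigenvalue/weight truncation: $10^{-8}$ of the largest, shared by
  kernel and both tests.
* $\delta$ profiling: log-scale, $[10^{-6}, 10^6]$, tolerance
  $10^{-8}$, boundary $\delta = 0$ evaluated explicitly.
* Full-model ML: 3 fixed starts, L-BFGS-B on log ratios in
  $[-18, 8]$; lower-bound ratios reported as 0.
* Collinearity guard: predictor rejected when its residual sum of
  squares on $Z$ falls below $10^{-10}$ of its total.
* IER cluster sums must be within $10^{-6}$ of 1 on complete
  cluster-sample sets; offending clusters are rejected (dropped with a
  warning), never renormalized — a bad sum signals an upstream
  quantification bug. Missing IERs are mean-imputed per intron (the
  neutral choice after per-intron standardization) and counted in the
  log; sample alignment uses the sorted intersection across tables.
* Degenerate predictors ($x \equiv 0$, or all weights truncated) yield
  $Q = 0$, $p = 1$, flagged — never an exception mid-scan.

## Problem sizes used by the test suite

Calibration is measured at $n = 300$, $k = 5$, 2,000 replicates;
power at $n = 300$, 300 replicates; variance-partition recovery at
$n = 1000$, 100 replicates per truth; oracle (dense-matrix)
equivalence on 20–40-sample instances. These sizes make the full suite
a coffee-break run on one core while keeping Monte-Carlo bands tight
enough to be meaningful.

## Known limitations

* The joint test's Cauchy combination is mildly anti-conservative at
  conventional thresholds (empirically $\approx 0.06$ at
  $\alpha = 0.05$); in the deep tail — where genome-scan discoveries
  live — the combination is at its most accurate.
* Liu's method is used only where its accuracy is adequate; see the
  p-value section. Reported p-values below $10^{-4}$ always come from
  the exact method.
* The variance-partition estimate inherits the small-rank skew of ML
  variance components; for genes with very few introns, treat
  $\hat\rho$ as a ranking device rather than an unbiased estimate.
* Inference conditions on the estimated $V$; no uncertainty in
  $\hat\sigma^2_u, \hat\sigma^2_e$ is propagated (standard for this
  family of score tests, and supported by the calibration results).
* Confidence intervals for $\hat\rho$ and likelihood-ratio-based
  alternatives are out of scope.
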