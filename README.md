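# splicecor

Splicing-aware analysis of gene–gene co-expression from bulk RNA-seq.

## The problem

Most genes are alternatively spliced, and a bulk sample's measured
*total expression* (TE) of a gene sums over its isoforms. When isoforms
of a regulator gene differ in their effect on a target gene, the TE–TE
correlation between the two genes varies from sample to sample with the
regulator's isoform composition — and a standard correlation test,
which assumes one slope for all samples, can miss the pair entirely.
`splicecor` is for analysts of co-expression and regulatory networks
who want to detect, test, and quantify this splicing-induced
inter-sample variation using ordinary bulk data plus LeafCutter-style
intron-excision ratios (IERs) as a surrogate for isoform composition.

## The model

For mean-centered expression vectors `y` (response) and `x` (predictor)
over n samples, covariates `Z`:

    y = x b1 + diag(x) b2 + Z g + u + e
    b2 ~ N(0, s2_Int * Sigma),  u ~ N(0, s2_u * Sigma),  e ~ N(0, s2_e * I)

`Sigma` is the **splicing kernel**: the trace-normalized Gram matrix of
the predictor gene's standardized IER profile, so samples with similar
isoform composition share similar slopes. The package provides

* an **interaction test** — a variance-component score test of
  `H0: s2_Int = 0` with statistic
  `Q = (y - yhat)' V^-1 diag(x) Sigma diag(x) V^-1 (y - yhat)`,
  `V = s2_u*Sigma + s2_e*I` estimated by ML; null distribution a
  weighted sum of chi-squares (Liu moment matching, exact
  Ruben/characteristic-function inversion in the tail);
* a **joint association test** for fixed and random slope together,
  scanning the variance-partition parameter `rho` over a grid with a
  Cauchy combination;
* **rho estimation** (`s2_Int / (s2_Int + s2_X)`) from a
  four-component ML fit — the share of the predictor's contribution
  attributable to splicing;
* multiple-testing control (BH, response-stratified FDR, Storey pi0),
  directed network construction with hub/outdegree summaries,
  tissue-sharing profiles, and tumor-vs-normal differential
  correlation;
* a generative simulator emitting expression/IER/covariate files in
  exactly the formats the loaders read.

## Worked example

The `analysis/` directory is a numbered workflow. Step 1 simulates a
20-gene, 300-sample cohort in which 10% of directed pairs carry a fixed
slope (0.3) plus a splicing-interaction variance (0.5); step 2 reloads
the files and scans all 380 directed pairs with all three tests:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_scan.R
Rscript analysis/03_multiple_testing.R
Rscript analysis/04_networks.R
Rscript analysis/05_calibration_power.R
```

Step 3 prints, for this cohort (seed 20260927):

    interaction: 69/380 significant at stratified 5% FDR, 40 at Bonferroni, 1-pi0 = 0.385
    joint      : 112/380 significant at stratified 5% FDR, 69 at Bonferroni, 1-pi0 = 0.528
    correlation: 79/380 significant at stratified 5% FDR, 43 at Bonferroni, 1-pi0 = 0.467
    median rho: all pairs 0.276 | joint-significant 0.539 | joint+interaction 0.851

The ordering is the point: the joint test (which accounts for
splicing-induced slope variation) finds more co-expressed pairs than
the correlation test on the same data, and pairs significant in *both*
the joint and interaction tests have a much larger estimated splicing
share (median rho 0.85) than joint-significant pairs overall (0.54).
Step 4 builds the three networks (112, 79 and 69 edges; the joint
network is the densest, with 12 hub genes of outdegree >= 5) and shows
that interaction effects in a 3-tissue simulation are mostly
tissue-specific (33 of 39 significant pairs in one tissue only) while
shared effects are recovered in all three. Step 5 reports the tests'
operating characteristics; under interaction-only signal the
interaction and joint tests reach power ~1.0 while the correlation
test stays near its size (0.07).

In code, one pair at a time:

```r
library(splicecor)
sp <- simulate_pair(sim_config(seed = 7, scenario = "interaction_only"))
nf <- fit_null(sp$y, sp$x, sp$Z, sp$kernel)
interaction_score(sp$y, sp$x, nf, sp$kernel)
#> splice_test: Q = 5546, p = 6.13e-28
nf0 <- fit_null(sp$y, NULL, sp$Z, sp$kernel)
joint_score(sp$y, sp$x, nf0, sp$kernel)
#> joint_test: p_combined = 2.67e-27, rho_star = 1.00
estimate_rho(sp$y, sp$x, sp$Z, sp$kernel)$rho_hat
#> [1] 1
```

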