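---
title: "Combining dependent partial tests with z-scores: methods and design"
author: "zcombine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining dependent partial tests with z-scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zcombine)
```

## The testing problem

A common toxicogenomics design measures expression for thousands of genes in
one vehicle-control arm and several compound arms, with the *same* control
shared by every compound.  For gene $g$ the scientific null hypothesis is the
intersection ("complex") hypothesis

$$H_{0g}:\ \text{gene } g \text{ is equally expressed under every compound},$$

built from $n$ *partial* hypotheses, one per compound-versus-control
comparison.  Each partial test yields a t-statistic $T_{gi}$, and because all
of them use the same control samples, the $T_{g1},\dots,T_{gn}$ are
positively dependent: for equal arm sizes,
$\mathrm{cor}(T_{gi}, T_{gj}) \approx 1/2$.

Classical combining functions for $n$ partial p-values $p_{g1..gn}$ are
Tippett's minimum $T^T_g = \min_i p_{gi}$ and Fisher's omnibus
$T^F_g = -2\sum_i \log p_{gi}$.  Both have known null laws only under
independence; under shared-control dependence their null distributions must
be approximated numerically, in practice by label permutation, which is
expensive at genome scale and grainy at the small thresholds used for
discovery.

## The z-score route

`zcombine` centres on the Stouffer (Liptak) combination of *signed* z-scores.
Each partial statistic is mapped through its exact null CDF,

$$z_{gi} = \Phi^{-1}\!\big(F_\nu(T_{gi})\big),$$

where $F_\nu$ is the central t CDF of the pooled two-sample statistic with
$\nu = 2k - 2$ degrees of freedom ($k$ replicates per arm).  Under the
partial null $z_{gi}$ is exactly standard normal; the combined statistic

$$T^S_g = \frac{1}{\sqrt n}\sum_{i=1}^n z_{gi}$$

is therefore normal with mean 0 *regardless of the dependence*, with the
single unknown

$$\sigma^2 = \mathrm{Var}(T^S_g)
           = \frac{1}{n}\sum_{i,j}\sigma_{ij}
           = 1 + \frac{2}{n}\sum_{i<j}\rho_{ij},$$

where $\sigma_{ij} = \mathrm{Cov}(z_{gi}, z_{gj})$ is assumed common across
the equally expressed genes.  Because a screen carries thousands of genes,
$\Sigma = (\sigma_{ij})$ can be estimated by the sample covariance of the
z-score columns *over genes*, and the final test is simply
$p_g = 2\{1 - \Phi(|T^S_g| / \hat\sigma)\}$.  No resampling is involved
anywhere in the pipeline, which is the practical advantage over the
permutation-calibrated combiners.

The pipeline (`run_stouffer_pipeline()`) is:

1. partial pooled-t tests and z-scores (S1);
2. per-gene Stouffer statistic (S2);
3. selection of a putative-null gene set (S3);
4. covariance and combined-variance estimation over that set (S4);
5. the standard-normal test with the estimated scale, plus Storey q-values (S5).

### Which genes estimate the null covariance?

Step S3 exists because genes that are truly differential contaminate the
covariance.  The "zero assumption" view selects genes with
$|T^S_g| \le x_0$ — central genes are almost surely null — and estimates
$\Sigma$ from them.  Two facts shaped our defaults:

* **Raw covariance over a central window is badly biased.**  Conditioning on
  $|T^S| \le x_0$ shrinks the variance along the sum direction: a window of
  $\pm a$ null standard deviations retains only
  $1 - 2a\phi(a)/(2\Phi(a) - 1)$ of it, and the *observable* truncated
  variance of $T^S$ can never exceed $x_0^2/3$.  With $x_0$ near one null SD,
  the raw plug-in estimate of $\sigma^2$ comes out several-fold too small and
  the final test becomes wildly anti-conservative.  When a finite window is
  used, `fit_dependence()` therefore de-truncates: under a normal working
  model the conditional covariance differs from the unconditional one by a
  rank-one term along the sum direction, so a one-dimensional fixed point
  recovers the unconditional variance and a rank-one update restores
  $\Sigma$.  If the observed variance sits too close to the $x_0^2/3$ ceiling
  the inversion is ill-posed and the fit refuses with a request for a larger
  window, rather than returning a noise-amplified estimate.

* **With a high null proportion, no window is needed.**  When most genes are
  null, the selection step can be skipped and $\Sigma$ estimated from *all*
  genes.  Contamination by true DEGs then only *inflates* $\hat\sigma^2$
  (every DEG contributes its squared effect to variances and covariances
  alike), which errs on the conservative side: fewer false discoveries, at
  the price of reduced nominal power near the threshold.  Ranking of genes is
  unaffected, because a scalar scale change is monotone in $|T^S|$.

The default is therefore `x0 = Inf` (all genes), the estimator of choice for
screens where a few percent of genes are differential.  A finite `x0`, a
quantile rule (`x0_quantile`), and the de-truncation switch are exposed for
data where the differential fraction is large; these are interpretations of
an underdetermined selection rule, and we flag them as such.

The covariance uses mean subtraction over the selected genes and denominator
(count − 1); with thousands of genes the count/count − 1 distinction is
immaterial, and the unbiased form is the conventional one.

### Numerical details

* The z-transform is computed on the log-probability scale in the relevant
  tail (`pt(..., log.p = TRUE)` into `qnorm(..., log.p = TRUE)`), mirrored
  for exact odd symmetry, so it is accurate far beyond the naive
  `qnorm(pt(t, df))` breakdown point.  Non-finite statistics (zero pooled
  variance with a nonzero mean difference) map to the double-precision-safe
  sentinel $|z| = 8.2$.
* A gene with zero pooled variance *and* zero mean difference gets $t = 0$
  with a warning; both degeneracies are surfaced, never silently dropped.
* If $\hat\sigma^2 < 1$ (possible with raw sample covariances and negative
  dependence) it is kept as estimated, with a warning — the variance formula
  permits it — and a negative total is an error, never silently clipped.

## Comparator methods

**Permutation-calibrated Tippett and Fisher.**  `permutation_tests()`
permutes the sample-to-arm labels *jointly across all samples* (whole-column
permutation, one permutation per iteration applied to every gene), recomputes
the partial pooled-t p-values with the same machinery as the observed data,
and uses the add-one estimator $(1 + \#\text{extreme})/(B + 1)$.  Whole-column
permutation preserves any inter-gene structure, costs one recomputation per
permutation (vectorized across genes through BLAS on membership matrices),
and is the conservative reading of a label-permutation null.  Per-gene nulls
are the default; `pool_genes = TRUE` pools the $G \times B$ permutation
statistics into one null for p-value resolution $1/(GB + 1)$, useful when the
decision threshold is below $1/(B+1)$.  The permutation count matters for
calibration, not just resolution: with per-gene nulls the realized FDR of a
Storey-thresholded permutation test is biased downward when $1/(B+1)$ is not
small against the rejection threshold, which is why the evaluation harness
uses $B = 5{,}000$.

**Dunnett's many-to-one test.**  Per gene, $\max_i |t_i|$ with the variance
pooled over all arms (degrees of freedom $(n+1)(k-1)$).  Under the gene-level
null the $t_i$ follow the equicorrelated multivariate t with
$\rho = 1/2$, and the two-sided simultaneous p-value is evaluated from a
seeded Monte Carlo sample of the joint representation
$T_i = (Z_i - Z_0)/(\sqrt{2}\,W)$, $W^2 \sim \chi^2_\nu/\nu$, shared across
genes ($10^5$ draws by default; the test suite checks it against an
independent multivariate-t quadrature oracle to within 0.005).  Because this
p-value is exactly uniform under the null, Storey-q thresholding controls the
realized FDR near the target — a property the evaluation harness verifies
directly.

**Storey q-values.**  `storey_qvalue()` uses the canonical fixed-$\lambda$
form: $\hat\pi_0 = \min\{1, \#(p > \lambda)/(m(1-\lambda))\}$ with
$\lambda = 0.5$, and the step-up envelope
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$.  No smoother: the
fixed-$\lambda$ estimator is the transparent default and is what the rest of
the package's calibration statements assume.

## The synthetic-data generator

`simulate_experiment()` emulates the design the methods target: $G = 4{,}000$
genes, $200$ DEGs, one control plus $n = 3$ compound arms, $k$ replicates per
arm ($5$ or $20$), control entries pure IID error, compound entries error
plus $\delta = 1.5$ for every DEG in *every* compound arm.  Error families:
standard normal, $t_5$, and Gamma(shape 3, rate 1).  Choices worth noting:

* The gamma errors are used uncentered (mean 3): a location shift common to
  all arms cancels from every two-sample comparison, so centering would not
  change any statistic in the package.
* $\delta$ is added with a single positive sign in all compound arms; there
  are no mixed-sign or per-compound effects.  This is the least-favourable
  simple alternative for the signed Stouffer sum to exploit, and the natural
  reading of a single-$\delta$ compound-group model.
* Genes are simulated independently.  Real expression data carry inter-gene
  correlation, which widens the spread of the empirical null beyond what the
  theoretical one predicts; the generator deliberately does not emulate
  that, so passing calibration tests here demonstrates correctness of the
  method's own assumptions, not robustness to correlated genes (an
  empirical-null estimate would be the remedy, and is out of scope).
* Probe-level artefacts and normalization are not simulated: inputs are
  assumed already normalized, log-scale intensities.
* Dataset $d$ of a replicated run uses seed $\texttt{seed} + d$, so the whole
  harness is reproducible bit for bit and no two datasets share a stream.

## What the harness computes

`run_full_benchmark()` simulates 20 datasets per condition, applies the
requested methods, and reports (i) rank statistics of the true DEGs
(quartiles, mean, max — averaged over datasets with their SDs), (ii) realized
false discovery proportions when q-values are thresholded at targets 0.1 and
0.2, and (iii) rank-based ROC curves averaged on a common 512-point FPR grid,
with per-dataset ranking AUCs.  Under the default conditions the qualitative
picture is: the Stouffer pipeline ranks DEGs best (mean DEG rank near the
ideal $100.5$ at $k = 20$) and is deliberately conservative in FDR (realized
FDR well under the target, by the contamination-inflation mechanism above);
the permutation combiners are near-calibrated; the calibrated Dunnett test
sits near the target by construction.  Every number quoted in the package
README is produced by running this code.

Problem sizes used by the shipped test suite and acceptance script — 20
datasets per condition, $B = 5{,}000$ permutations at $k \in \{5, 20\}$,
$10^5$ Monte Carlo draws for the Dunnett null, $10^5$-gene single-arm
simulations for distributional checks — were chosen so the full suite
completes in minutes on a single core while keeping Monte Carlo error an
order of magnitude below every asserted tolerance.

## Known limitations

* The theoretical-null Stouffer pipeline is conservative whenever the
  covariance is estimated with DEG contamination (the default), and can be
  anti-conservative if a narrow selection window is used without
  de-truncation; the package refuses the clearly ill-posed cases but cannot
  verify the zero assumption itself.
* Permutation p-values inherit the granularity $1/(B+1)$ (or $1/(GB+1)$
  pooled); decisions at thresholds near that floor are dominated by the
  add-one correction.
* Equal replicate counts per arm are assumed by the permutation and Dunnett
  comparators; the Stouffer pipeline itself only needs two samples per arm.
* Inter-gene dependence and empirical-null estimation are out of scope, as
  is any preprocessing (normalization, background correction).
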