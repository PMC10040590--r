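---
title: "Single- and multi-environment Bayesian genomic prediction with megp"
author: "megp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single- and multi-environment Bayesian genomic prediction with megp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breeding programs phenotype a panel of lines in replicated field trials over
several environments (years, locations) and genotype the same lines at
thousands of SNP markers. Genomic prediction regresses the phenotypes on all
markers jointly and predicts the genetic values of lines that were not
phenotyped — new candidates, or lines observed only in some environments.
`megp` implements this pipeline for the two-stage design common in plant
breeding: plot-level data are first condensed into per-environment best
linear unbiased estimates (BLUEs) of line means, and the whole-genome
regressions are then fitted to those BLUEs.

## Stage 1: line means from the RCBD

Per environment and trait the plot model is

$$y_{io} = \mu + g_i + b_o + \epsilon_{io}$$

with genotype fixed, block random, fitted by REML (`rcbd_blues()`, backed by
`lme4`). Returning the estimated genotype means makes the result invariant
to the fixed-effect coding. With balanced complete blocks these BLUEs equal
arithmetic line means for any estimated block variance; with missing plots
the mixed-model equations weight information correctly. Environments with a
single block cannot separate block from residual variance; the function
falls back to raw line means and flags the fact rather than failing.

## Stage 2: whole-genome regression

`wgr()` fits, by Gibbs sampling, the single-environment models

* **GBLUP** — $y = 1\mu + u + \epsilon$, $u \sim N(0, G\sigma^2_u)$ with
  $G = WW'/m$ the genomic relationship matrix of centred and standardized
  gene contents $W$ (additive gene action);
* **RKHS** — the same model with a Gaussian kernel
  $GK(i,i') = \exp(-\theta\, d^2_{ii'})$ of the standardized marker rows,
  which captures epistatic similarity; *kernel averaging* fits several
  bandwidths (defaults $\theta = 0.2$ and $1.2$, one global and one local
  kernel) as separate random effects whose variances are learned, a
  practical substitute for bandwidth selection;
* **BayesB / BayesC** — marker regression on 0/1/2 gene contents (centred)
  with a spike-and-slab prior: each effect is zero with probability
  $\pi = 0.99$, otherwise Gaussian with a per-marker (BayesB) or shared
  (BayesC) slab variance;
* **RR-BLUP** — ridge regression on standardized markers, the marker-effect
  twin of GBLUP (the two give the same predictions, which the test suite
  exploits as a cross-check).

Variance components carry scaled inverse-$\chi^2$ priors with $\nu = 5$
degrees of freedom. Scales follow the standard default rule: the model is
assumed a priori to explain $r^2 = 0.5$ of the phenotypic variance, giving
$S_u = V_y r^2 (\nu + 2) / \overline{\mathrm{diag}(K)}$ for kernel models and
$S_\alpha = V_y r^2 (\nu + 2) / \mathrm{MSx}$ for marker models, where MSx is
the summed sample variance of the marker covariates; spike-and-slab models
divide by $(1 - \pi)$ because only that fraction of markers carries the
slab. The mixture proportion $\pi$ is fixed, not sampled.

Kernel models are sampled in the eigenbasis of each kernel. After one
eigendecomposition per kernel, every Gibbs update is a sequence of
independent scalar draws, so a 50,000-iteration chain at a few hundred
lines takes seconds. Missing phenotypes are handled by data augmentation,
which keeps the eigenbasis orthonormal and yields predictions for
unphenotyped lines directly. The marker-effect samplers (single-site Gibbs
in fixed marker order over a running residual) are compiled code but draw
through R's RNG, so `set.seed()` gives bit-identical chains.

## The marker-by-environment interaction model

With $L \ge 2$ environments, `mxe()` decomposes each marker effect into a
main component shared across environments plus environment-specific
deviations:

$$y_{il} = \mu_l + \sum_k w_{ilk}\,(\alpha_{0k} + \alpha_{lk}) + \epsilon_{il}$$

with heterogeneous residual variances $\sigma^2_{\epsilon l}$. The shared
$\alpha_0$ is what lets one environment borrow information from another;
the ratio of main to specific variance measures how much marker-by-
environment interaction the trait shows. Marker covariates are centred and
standardized per environment over the lines observed there (so MSx $= m$
per block and marker variances convert to genetic-value-scale variances by
multiplying with $m$). Prior scales are set so the prior means of the
genetic variance components sum to half the phenotypic variance, divided
equally between the main and specific parts — the model states a target
prior mean, hence the mean convention $S = \mathrm{target}\,(\nu - 2)$ here,
against the mode convention used by the single-environment default rule.

Derived parameters (`genomic_heritability()`, `variance_proportions()`,
`variance_derived_phenotypic_correlation()`) plug in posterior-mean variance
components on the genetic-value scale. A two-environment trial reports one
heritability per environment; the single-number summary is their mean —
a labelled convention, since a pooled ratio would be equally defensible.

`bivariate_gblup()` treats the same trait in two environments as two
correlated traits, $(u, \epsilon) \sim N(0, \Sigma_u \otimes G,
\Sigma_\epsilon \otimes I)$, with inverse-Wishart priors on both 2×2
covariance matrices (identity scale matrices; $\nu_u = \nu_\epsilon = 4$,
weakly informative for a 2×2 matrix — the degrees of freedom are a package
choice, any value above dimension + 1 is proper). The genomic correlation
$r_g = \sigma_{u12}/\sqrt{\sigma^2_{u1}\sigma^2_{u2}}$ is computed per
posterior draw and averaged; draws with numerically zero genetic variance
are skipped and counted. Non-positive-definite scale matrices during
sampling are jittered and the occurrences reported.

## Cross-validation designs

Four evaluation designs (`cv_partitions()` plus one driver each):

* **single** — repeated random subsampling within one environment, 2/3
  training (floor), 1/3 testing, 50 replicates by default;
* **CV0** — all lines of one environment predict the same lines in the
  other; since no target-environment intercept is estimable, the
  (scale-free) Pearson correlation compares predicted genetic values with
  target phenotypes directly;
* **CV1** — new lines: test lines are masked in *every* environment; the
  M×E model cannot borrow within line here and is expected to match, not
  beat, single-environment GBLUP;
* **CV2** — sparse trials: per replicate the lines are split into thirds,
  one third masked in each environment and one third observed in both, so
  every masked cell's line is observed elsewhere. The masking ratio is a
  package choice (the design is described qualitatively in the field);
  masking both environments symmetrically keeps the two arms comparable.

Both arms of a comparison share partitions and seeds, so accuracy
differences are paired. Undefined correlations (constant vectors) are
recorded as missing, counted, and excluded from replicate means.

Because subsampling replicates share training lines, the naive paired
t-test on accuracy differences is anticonservative. The corrected
resampled t-test divides by
$\sqrt{(1/K + n_{\mathrm{test}}/n_{\mathrm{train}})\, s^2_d}$ instead of
$\sqrt{s^2_d/K}$. Its calibration is checked in the test suite with two
equal-performance deterministic predictors (G-kernel vs Gaussian-kernel
BLUP) on pure-noise phenotypes: with two literally identical arms the
differences are exactly zero and no test can reject, and with differences
driven only by Monte-Carlo noise the correction makes the test arbitrarily
conservative — the calibrated regime, and the one the correction was
derived for, is precisely when differences are driven by the random
subsampling itself.

## The synthetic-data generator

`simulate_panel()` produces a study with known truth: allele frequencies
uniform in [0.05, 0.5], genotypes Binomial(2, p) per line (Hardy-Weinberg,
linkage equilibrium), marker effects drawn as main + specific components so
that the main-effect share equals the target genetic correlation, residuals
orthogonalized against the genetic values and rescaled so the realized
heritability matches its target exactly, and a complete RCBD layout with 7
and 5 blocks in the two environments. Defaults (182 lines, two
environments, 7/5 blocks, $h^2 = 0.5$, $r_g = 0.8$) mirror a two-season
oilseed diversity panel; the marker count defaults to 1,000 because, under
linkage equilibrium, additional markers add no new statistical structure —
only computation. A `pi_null` option gives sparse architectures for
variable-selection tests, and `ld_block_size` gives blocks of near-copied
markers for LD-pruning tests.

What the generator does **not** emulate: population structure and
relatedness (G is near-identity, so absolute prediction accuracies are
lower than in a real diversity panel, where structure and LD inflate them),
linkage disequilibrium beyond the optional copy-blocks, selfing
(simulated genotypes are outbred, so the heterozygosity QC filter for
selfing panels must be relaxed to `het_max = 1` on simulated data), and
environmental covariates. Passing tests therefore validate the estimators
and the relative ordering of scenarios, not absolute accuracy levels of any
particular crop.

## Numerical choices

* Standardization uses the sample mean and sample standard deviation
  (denominator $n-1$) of the observed codes; a Hardy-Weinberg variant
  (centre $2p$, scale $\sqrt{2p(1-p)}$) is available via
  `standardize_markers(method = "hwe")`. The two agree closely under
  Hardy-Weinberg sampling (tested at $m = 2000$).
* Missing genotypes are mean-imputed per marker before standardization.
* LD pruning is a greedy left-to-right scan in marker order within a
  1,000-marker window; the earlier marker of a linked pair is kept.
* Kernel eigenvalues below $-10^{-8}\lambda_{\max}$ raise an error; small
  negative values inside that tolerance are treated as zero (the
  eigendecomposition drops components below $10^{-10}\lambda_{\max}$).
* Gaussian-kernel distances are computed on standardized markers without
  rescaling by the mean distance (a `scale_dist` flag enables it for
  interoperability with implementations that do).
* Variance full conditionals are $(S + \mathrm{SS})/\chi^2_{\nu + k}$ with
  the degrees of freedom accumulating the number of effects $k$; chains are
  thinned post hoc and only post-burn-in draws are summarized. Effective
  sample sizes and Geweke z-scores are reported as diagnostics, never used
  as gates.
* Monomorphic markers are an error at standardization (they carry no
  information and would divide by zero); markers monomorphic only within
  one environment's observed subset of the M×E model are centred and left
  at zero.

## Problem sizes

The test suite and the acceptance script run desk-scale versions of every
experiment: parameter-recovery checks use 300 lines × 1,000 markers with
the short chain profile (2,000 iterations, 500 burn-in, thinning 2);
scenario comparisons use the default 182-line panel with 10–20 replicates;
the t-test calibration uses 200 datasets of 80 lines with closed-form BLUP
arms. The full-length profile (50,000 / 20,000 / 5) remains the default of
`mcmc_settings()` for final inference; with the eigenbasis sampler it is
entirely practical at panel sizes of a few hundred lines.

## Known limitations

* No pedigree kernels, no phasing, no imputation beyond marker means.
* The M×E model is additive; epistatic multi-environment kernels are out
  of scope.
* The bivariate model handles exactly two environments (the M×E model
  itself accepts any $L \ge 2$).
* $\pi$ is fixed; BayesA and the Bayesian LASSO are not provided.
* CV0 reports genetic-value correlations; absolute calibration of
  predictions in a new environment (intercept, scale) is not attempted.

## A worked example

```{r example}
library(megp)
cfg <- sim_config(seed = 1)
panel <- simulate_panel(cfg)
blues <- rcbd_blues(panel$fieldbook)
Y <- phenotype_matrix(blues, "y")
qc <- marker_qc(panel$geno, het_max = 1)
fit <- mxe(Y, qc$genotypes, mcmc = mcmc_quick())
summary(fit)
G <- genomic_relationship(standardize_markers(qc$genotypes))
rg <- genomic_correlation(bivariate_gblup(Y, G, mcmc = mcmc_quick()))
p2 <- cv_partitions(rownames(Y), "cv2", n_reps = 10, seed = 2)
summary(cv2(Y, qc$genotypes, p2))
```
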