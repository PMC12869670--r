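---
title: "Estimating average and modifier-dependent causal effects from GWAS and GWIS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating average and modifier-dependent causal effects from GWAS and GWIS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(merlinmr)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure X on an outcome Y from per-SNP association summary statistics,
using genetic variants as instruments. Classical estimators summarize that
effect by a single number. When the causal effect is modified by an
environmental variable E — sex, age, or any measured covariate — the
population-average effect can hide, or even be manufactured by, effect
heterogeneity: with opposite effects in the two sexes, a sex-combined
analysis can report a confidently nonzero "average" effect whose sign and
size describe neither sex.

`merlinmr` jointly estimates the **average causal effect** `beta_A` and the
**causal interaction** `beta_I` — the change in the causal effect per unit
of the standardized modifier — from four summary-statistics inputs:

* exposure GWAS (`gamma_G`): per-SNP additive effects on X,
* exposure GWIS (`gamma_GI`): per-SNP SNP-by-E interaction effects on X,
* outcome GWAS (`Gamma_G`): per-SNP additive effects on Y,
* outcome GWIS (`Gamma_GI`): per-SNP SNP-by-E interaction effects on Y,

each with standard errors. The individual-level structural model behind
these quantities is linear with multiplicative effect modification:

```
X = sum_j G_j gamma_G_j + E gamma_E + sum_j (G_j E) gamma_GI_j + e_X
Y = X beta_A + sum_j G_j beta_G_j + E beta_E + (X E) beta_I + e_Y
```

with centered genotypes `G_j`, a standardized modifier E independent of the
instruments, horizontal pleiotropy `beta_G_j` (direct SNP effects on Y),
and residuals `e_X`, `e_Y` that absorb confounding and noise. The
outcome-scale true effects satisfy

```
Gamma_G  = beta_A gamma_G  + beta_G
Gamma_GI = beta_A gamma_GI + beta_I gamma_G .
```

The second relation is the key identifying equation: the outcome GWIS
effect of a SNP combines its exposure-interaction path (`beta_A gamma_GI`)
with the interaction-driven re-scaling of its additive path
(`beta_I gamma_G`).

## The summary-statistics likelihood

Observed effect-size vectors are modelled as Gaussian with covariance
`S_k R S_k`, where `S_k` is the diagonal matrix of the block's standard
errors and `R` the LD correlation matrix among instruments. Marginal
(per-SNP) association estimates mix the true joint effects through LD, so
every block mean is a marginal-projection operator `S_k R S_k^-1` applied
to a true-effect combination:

| block | mean | covariance |
|---|---|---|
| exposure GWAS | `S1 R S1^-1 gamma_G` | `S1 R S1` |
| exposure GWIS | `S2 R S2^-1 gamma_GI` | `S2 R S2` |
| outcome GWAS | `S3 R S3^-1 (Gamma_G + beta_I gamma_GI)` | `S3 R S3` |
| outcome GWIS | `S4 R S4^-1 (Gamma_GI + mu3 beta_I gamma_GI)` | `S4 R S4` |

The two cross terms are moment effects of the modifier. Because
`E[E^2] = 1` for any standardized E, the interaction-mediated outcome
signal `beta_I gamma_GI` leaks into the *additive* outcome association.
For a standardized two-point (binary) modifier with stratum-1 proportion
p, the identity `E^2 = 1 + mu3 E` with skewness
`mu3 = (1 - 2p) / sqrt(p(1 - p))` additionally leaks
`mu3 beta_I gamma_GI` into the outcome *interaction* association; `mu3`
vanishes for balanced strata (p = 0.5) and for a symmetric continuous
modifier. We verified these mean structures — including the placement of
the cross terms inside the block's own projection operator, a point on
which plausible alternative forms exist — against per-SNP regressions on
large simulated cohorts (the "moment oracle" tests): for every modifier
preset the observed coefficients match within Monte-Carlo error, while
variants that scale the cross terms by SE-ratio factors are rejected at
several standard errors. For a skewed *continuous* modifier the `mu3 = 0`
form is retained for estimation; interaction testing is robust to moderate
skew, and the moment tests cover the modifier kinds above.

The four blocks are treated as mutually independent. This matches a design
with non-overlapping exposure and outcome cohorts; GWAS and GWIS of the
same trait may share all individuals because, for a standardized modifier
independent of genotype, `G_j` and `G_j E` are asymptotically uncorrelated
regressors, making the additive and interaction estimates approximately
independent. Exposure–outcome sample overlap correlates the blocks'
errors; see "Known limitations".

## Bayesian hierarchical model and Gibbs sampler

True per-SNP effects get exchangeable normal priors,
`gamma_G ~ N(0, sigma1^2 I)`, `beta_G ~ N(0, sigma2^2 I)` (pleiotropy),
`gamma_GI ~ N(0, sigma3^2 I)`, with `InvGamma(a_k, b_k)` hyperpriors on
the variance components and improper flat priors on `(beta_A, beta_I)`.
Every full conditional is conjugate: given the other blocks, each of
`gamma_G`, `gamma_GI`, `beta_G` has a Gaussian conditional (the likelihood
is linear in each), `(beta_A, beta_I)` has a bivariate Gaussian
conditional (a 2-parameter GLS given the latent effects), and the variance
components are inverse-gamma. The sampler therefore needs no tuning. With
independent instruments (`R = I`, the recommended use after LD clumping)
all matrix conditionals factorize over SNPs and the update cost is linear
in the panel size; this path is implemented in compiled code. A dense-R
sampler handles a supplied LD matrix at cubic per-iteration cost, suitable
for panels of modest size.

Defaults: 5,000 iterations, 2,000 burn-in, 2 chains, `a_k = b_k = 0.01`.
These are desk-scale stability choices: the conditionals mix quickly
because the latent effects are strongly informed by their own data blocks.
Convergence is monitored with split-Rhat on `beta_A` and `beta_I`
(warning above 1.1; the fit is returned either way, flagged). Posterior
summaries pool post-burn-in draws across chains; P values are two-sided
normal ("Wald-style") on the posterior mean and sd — the simplest
construction consistent with reporting frequentist-style P values from a
Bayesian fit. Reported sex-specific effects
(`beta_M = beta_A + beta_I`, `beta_F = beta_A - beta_I`, with the
convention Male = +1, Female = −1) take their standard errors from the
joint posterior covariance of `(beta_A, beta_I)`, not from
independence-based addition.

A reduced estimator (`fit_merlin_no_outcome_gwis()`) drops the outcome
GWIS block; `beta_I` is then identified solely through the
`beta_I gamma_GI` leakage in the outcome GWAS mean, which requires real
exposure GWIS signal. The fit is flagged experimental and warns when the
interaction is weakly identified (95% CI half-width above 0.5 on the
standardized scale).

## Instrument selection

Candidates pass either the exposure-GWAS threshold (`t_gwas`, default
5e-8) or the exposure-GWIS threshold (`t_gwis`, default 5e-6) — the GWIS
channel admits instruments whose effect on the exposure is
context-dependent. Each candidate is prioritized by the smaller of its two
P values; greedy LD clumping keeps the best-priority SNP and removes
candidates with `r^2 > r2_max` (default 0.3) within a distance window
(default 1 Mb), ties broken lexicographically by SNP id so the output is
independent of row order. The clumping window is distance-based; supplied
LD matrices are shrunk toward the identity (`lambda = 0.05`) so the
likelihood's `R` is always invertible. With no LD panel supplied,
instruments are treated as independent, which is the design point of the
simulation studies (independent SNPs).

## The synthetic-data generator

`sim_scenario()` / `simulate_scenario()` emulate a two-cohort
summary-statistics study: one population is drawn (independent
`Binomial(2, maf)` SNPs, `maf ~ U(0.05, 0.5)`, columns centered), the
exposure cohort and outcome cohort are index ranges over it (sharing
`n_overlap` individuals — genotypes, modifier and residual draws), both
phenotypes follow the structural model above, and the four per-SNP
analyses are ordinary least squares (GWAS: `trait ~ 1 + G_j`; GWIS:
`trait ~ 1 + G_j + E + G_j:E`, reporting the interaction term).

Calibration of the generator:

* Effect vectors `(gamma_G_j, gamma_GI_j)` are bivariate normal with
  correlation `rho_AI` ("polygenic gene–environment interaction"), then
  rescaled so realized variance shares are exact: `h2_gamma_G` (default
  0.3), `h2_gamma_GI` (default 0.15, half the additive share),
  `h2_beta_G` pleiotropy (default 0).
* Modifier main effects `gamma_E = beta_E = 0.1` are folded into composite
  residuals whose correlation is `resid_corr = 0.6` (shared-environment
  plus confounding) and whose scales are solved — using realized sample
  moments — so both phenotypes have unit variance.
* Default cohort sizes are 20,000 with M = 200 candidate SNPs and 100–500
  replicates: a desk-scale design that keeps a full replicate under half a
  second. Per-SNP instrument strength (non-centrality ≈ 30) is a quarter
  of what cohorts of 80,000 would give; consequences below.

What the generator does **not** emulate: LD structure among SNPs (SNPs are
independent by design, matching the analysis assumption after clumping),
assortative mating or population stratification, binary phenotypes,
genetically influenced modifiers, and winner's-curse-free external
instrument discovery. Passing tests therefore certify the estimator under
its own assumptions plus the listed perturbations (unbalanced and
continuous modifiers, pleiotropy, cohort overlap), not robustness to
structured confounding in real data.

## Numerical choices

* Quadratic forms use Cholesky factors of `R`; no explicit inverse of
  `S R S` is formed. Zero-variance reference-panel SNPs are excluded;
  shrinkage guarantees positive-definiteness.
* Per-SNP OLS scans run on accumulated cross-moments with 4x4 Cholesky
  solves; a deterministic fit (zero residual) floors the SE at a tiny
  positive value rather than emitting an invalid record.
* Strand-ambiguous (A/T, C/G) SNPs are dropped in harmonization by
  default — their orientation cannot be resolved from alleles alone;
  override with `drop_palindromic = FALSE`. Duplicate SNP ids keep the
  first occurrence, logged. Missing P values are recomputed from
  `beta/se`.
* Replicate benchmarks (`merlin_replicates()`) use 1 chain of 2,000
  iterations (500 burn-in): across-replicate averaging makes the
  per-fit Monte-Carlo error negligible relative to between-replicate
  spread. Single fits keep the 5,000/2,000/2-chain default.
* Variance-component draws are floored at 1e-12; the inverse-gamma
  hyperprior (0.01, 0.01) keeps conditionals proper when a block carries
  no signal.

## Known limitations

* **Attenuation under correlated effect vectors at desk scale.** The model
  places independent priors on `gamma_G` and `gamma_GI`. When the
  generating effects are strongly correlated (`rho_AI = 0.8`) and
  instruments have finite strength, the posterior mean of `beta_I` is
  attenuated by roughly the inverse per-SNP non-centrality: about 5% at
  n = 20,000 (mean estimate ≈ 0.285–0.29 for a true 0.3), about 1% at
  n = 80,000. This is a property of the estimator itself — it reproduces
  on data drawn exactly from the model's own likelihood with correlated
  true effects and is absent at `rho_AI = 0` — so the package's
  interaction-recovery tests at nonzero `rho_AI` document the deviation
  rather than masking it. Per-replicate instrument selection adds a
  smaller winner's-curse attenuation of the same order (visible even at
  `rho_AI = 0`); both shrink with cohort size.
* **Sample overlap.** The likelihood treats the four blocks as
  independent. Shared exposure/outcome individuals correlate the blocks'
  errors and shift `beta_A` upward by a few parts per thousand per unit of
  confounded residual correlation (≈ +0.007 at half-cohort overlap,
  n = 20,000, residual correlation 0.6); interaction inference stays
  calibrated in the tested conditions. An overlap-aware block covariance
  is the natural extension.
* The interaction enters as a single linear multiplicative term; nonlinear
  modification is out of scope. The modifier must be independent of the
  instruments (no genetically influenced modifiers). Binary outcomes are
  not specially transformed; effects are on the linear scale of the
  supplied summary statistics.
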