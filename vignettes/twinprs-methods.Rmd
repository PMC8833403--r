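---
title: "Methods: polygenic risk scores inside biometric twin models"
author: "twinprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk scores inside biometric twin models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Twin studies estimate the heritability of late-onset Alzheimer's disease at
roughly 0.6--0.8 on the liability scale, while genome-wide methods applied
to measured common variants recover far less. `twinprs` implements the
machinery needed to confront the two estimates inside a *single* twin
cohort: a clumping-and-thresholding polygenic risk score (PRS) is built
from GWAS summary statistics, its contribution is tested in a mixed-effects
probit regression that respects the twin pairing, and it is then embedded
as a *measured* genetic component inside an extended ACE liability-threshold
model, so that the variance a PRS captures can be read directly as a share
of total additive genetic variance.

Because registry twin data cannot be redistributed, the package ships a
synthetic cohort generator with the exact statistical structure the models
assume. Every stage is therefore testable end-to-end without any download.

## The liability-threshold ACE model with a measured PRS

Each twin's liability is standard normal around its covariate mean and
decomposes as

$$ 1 \;=\; \sigma^2_{A_P} \;(+\; \sigma^2_{A_{\varepsilon 4}}) \;+\;
   \sigma^2_{A_B} \;+\; \sigma^2_C \;+\; 2\,\sigma_{AC} \;+\; \sigma^2_E , $$

where $A_P$ is the latent polygenic factor perfectly indexed by the
observed standardized PRS (its observed variance scaled by $p$, so
$\mathrm{var}(\mathrm{PRS}) = p^2\sigma^2_{A_P}$), $A_{\varepsilon4}$ is an
analogous factor for the measured APOE $\varepsilon4$ allele count (scaling
$q$), $A_B$ is background additive genetic variance, $C$ shared and $E$
unique environment, and $\sigma_{AC} = \sigma_{A_PC} + \sigma_{A_BC}$ is an
optional A--C covariance. Genetic components correlate 1 across MZ and 1/2
across DZ co-twins; $C$ correlates 1 in both; hence the model-implied twin
correlations

$$ r_{MZ} = \sigma^2_{A_B} + \sigma^2_{A_P} + \sigma^2_C + 2\sigma_{AC},
   \qquad
   r_{DZ} = \tfrac12\sigma^2_{A_B} + \tfrac12\sigma^2_{A_P} + \sigma^2_C +
   2\sigma_{AC}. $$

The disease indicator is `liability > 0` with the threshold fixed at 0 and
the liability mean estimated (intercept plus sex, centered age, centered
age squared) — statistically equivalent to fixing the mean and estimating
the threshold, but simpler when measured-variable means are already free.

**Estimation.** The pair likelihood multiplies the Gaussian density of the
measured block (PRS and/or $\varepsilon4$ scores) by the conditional
bivariate-normal rectangle probability of the two binary outcomes; all
conditioning is exact (Schur complements of the implied pair covariance).
Key numerical choices:

* **Unbounded components.** $\sigma^2_{A_B}$, $\sigma^2_C$ and
  $\sigma_{AC}$ are estimated without sign constraints, which keeps
  likelihood-ratio statistics for dropping them honestly
  $\chi^2$-distributed; a 200-replicate null calibration of the C-drop
  test is part of the test suite. $\sigma^2_E$ is *eliminated* through the
  unit-variance identity rather than constrained, which is equivalent and
  keeps the parameter space a plain Euclidean box. The measured blocks are
  parameterized as (log observed variance, liability loading, mean) — a
  bijection of $(p, \sigma^2_{A_P}, \mu)$ under which
  $\sigma^2_{A_P} = \lambda^2 v_P$ is structurally nonnegative, as a
  variance of a measured quantity must be.
* **Singular MZ blocks.** The model implies cross-twin PRS correlation 1
  for MZ pairs (and many cohorts copy-impute one MZ twin's score outright),
  so the 2x2 MZ measured block is singular. The likelihood collapses it to
  one pair-level value (the mean of the two observations) with a univariate
  density; a configurable measurement-error `ridge` added to the observed
  scores is available as the alternative strategy. Neither claims to match
  any particular SEM package's internal handling; with clean data the two
  agree closely (tested).
* **Rectangle probabilities** come from a vectorized implementation of the
  standard Gauss--Legendre scheme for the bivariate normal (arcsine-
  substituted integral for $|\rho|\le0.925$, complementary expansion
  beyond), accurate to ~1e-10 or better across the whole correlation range
  — verified against a base-R numerical-integration oracle. Stable profile
  confidence intervals need this accuracy.
* **Optimization** is multi-start (deterministic moment-based start plus an
  alternative and optional seeded jitters), `nlminb` refined by BFGS;
  infeasible implied covariances receive a large smooth penalty instead of
  hard bounds. Standard errors come from the numerical observed
  information with a delta-method map to the standardized shares.
* **Profile CIs** re-optimize all nuisance parameters at fixed component
  values and bisect the profiled deviance against the $\chi^2_1$ 95%
  critical value 3.841; for derived components the constraint is imposed
  by substitution (e.g. fixing $\sigma^2_{A_P}$ pins the loading at
  $\pm\sqrt{c/v_P}$ while $v_P$ stays free). A quadratic-likelihood case in
  the tests confirms the interval collapses to estimate $\pm 1.96\,$SE.
* **Information criteria** follow the SEM reporting convention
  AIC $= -2LL + 2k$, BIC $= -2LL + k\log(\text{pairs})$. `k` counts the
  derived E alongside the free structural parameters, the liability mean
  coefficients, and *one mean plus one scaling per measured variable*.
  That last convention is the one consistent with the recoverable
  arithmetic of published model tables (baseline ACE k = 7, AE k = 6,
  full ACE+PRS k = 11, AE+PRS k = 9, AE+PRS+$\varepsilon4$ k = 12); a
  per-twin-position PRS mean would break it, so it is not the default.
* **$\varepsilon4$ as a continuous indicator.** The standardized allele
  count enters the measured block under a normal working density. Its
  first two moments (variance 1, cross-twin correlation 1 for MZ and 1/2
  for DZ under the additive single-locus model) are exactly those the
  model assumes, so the Gaussian quasi-likelihood leaves the covariance
  parameters consistent even though a count of 0/1/2 is not normal; the
  conditional liability distribution given the count *is* exactly normal.
  By default $A_{\varepsilon4}$ is uncorrelated with $A_P$, appropriate
  when the PRS excludes the APOE region.
* **covAC split.** Only total $\sigma_{AC}$ is freed by default (assigned
  to the $A_B$ path); freeing the $A_P$--$C$ split as well is supported but
  rests on weak identification from cross-twin PRS--liability covariances
  and is flagged as fragile.

Monte-Carlo power (`power_sim`) replaces any closed-form power formula:
replicate cohorts are simulated at the generating values and the rejection
rate of the component's likelihood-ratio test is reported with its binomial
error.

## The mixed-effects probit regression

The regression model is a pair-level random-intercept probit (or logit)

$$ \Phi^{-1}\!\big(P(\mathrm{AD}_{ij}=1 \mid u_j)\big) =
   b_0 + b_1\,\mathrm{MZ} + b_2\,\mathrm{Sex} + b_3\,\mathrm{Age} +
   b_4\,\mathrm{Age}^2 + b_5\,\mathrm{Array} + b_6\,z\mathrm{PRS} + u_j, $$

with $u_j \sim N(0, v_{MZ})$ or $N(0, v_{DZ})$ by zygosity. The marginal
likelihood integrates $u_j$ per pair by *adaptive* Gauss--Hermite
quadrature (Laplace-recentred nodes, 21 by default); binary clusters of
size two are exactly the situation where non-adaptive rules fail, and the
suite checks that 21 vs 41 nodes moves the log-likelihood by less than
1e-4. Singletons from incomplete pairs contribute one-member clusters.
Residual intra-pair correlations are reported as $v/(1+v)$ (probit) or
$v/(v+\pi^2/3)$ (logit); information criteria use the clustered-regression
convention AIC $= \log L - k$, SBC $= \log L - (k/2)\log(\text{pairs})$
with $k$ = fixed effects + free random variances. Nagelkerke $R^2$ is
computed against a configurable reference — covariates-only by default,
reproducing the incremental convention for a PRS column, with the
intercept-only alternative exposed. AUC uses marginal (fixed-effects-only)
predictions with half-weighted ties, since cluster-level effects are not
identified for singleton controls; whether published AUCs used marginal or
conditional predictions is generally unstated, so the choice is documented
rather than assumed.

## PRS construction

Standard clumping and thresholding: QC removes strand-ambiguous SNPs
(A/T, C/G), SNPs absent from the panel, minor allele frequency < 0.01 and
info score <= 0.8, and harmonizes effect alleles (sign flips on swapped
alleles; irreconcilable pairs dropped and counted). Greedy clumping sorts
by p-value and admits a SNP iff its squared dosage correlation with every
accepted SNP within the window is below r² = 0.01; the tie-break is
deterministic (p, chromosome, position), and the implementation is tested
against an exhaustive-oracle re-implementation. Choices the source
conventions leave open, fixed here and configurable:

* clumping window 250 kb (with a genome-wide-within-chromosome option) —
  published pipelines state only r²;
* APOE region chr19:44.4--46.5 Mb, GRCh37-style, closed interval;
  synthetic panels place their APOE SNPs inside it by construction;
* missing dosages mean-imputed per SNP before scoring, with counts logged;
* r² computed on dosages (allelic correlation), 1-based coordinates,
  uppercase alleles, no strand flipping beyond ambiguity removal;
* ancestry PCs fitted excluding one member of each MZ pair (duplicate
  genomes distort the spectrum), then projected for everyone; PCs are
  computed jointly across arrays, with array as a downstream covariate.

Scores are computed at the eight conventional thresholds (1 ... 5e-8), with
and without the APOE region, residualized on the first four PCs and
z-scored within genotyping array. The APOE $\varepsilon2/\varepsilon4$
counts come from the rs429358/rs7412 diplotype; the double heterozygote is
resolved as $\varepsilon2/\varepsilon4$ ($\varepsilon1$ and reverted
$\varepsilon3$ treated as absent), and impossible combinations under the
three-haplotype system raise an error.

## What the synthetic generator does and does not emulate

The generator states a world and the defaults *are* that world: prevalence
431/1586 ≈ 0.272, 44% male, age at last follow-up N(85.28, 7.02) shared
within a pair, probit covariate effects (0.44, 0.97, −0.55) for sex, age
and age², APOE haplotype frequencies 9.4/74.2/16.4%, two genotyping arrays
in proportion 1451:135, and liability variance shares taken from the
published reduced models when a test needs a named world. LD is a
latent-Gaussian AR(1) within independent blocks — chosen precisely because
its allelic r² is tunable and block independence makes clumping oracles
exact. MZ pairs share a zygote; DZ twins draw one gamete per parent per
block. The liability threshold is solved by root-finding on the covariate-
integrated normal CDF (Gauss--Hermite over age, exact sum over sex), so
prevalence is controlled in expectation rather than forced empirically.
Incomplete pairs and MZ copy-imputation mimic registry missingness. True
latent components are persisted only under an explicit `keep_latent` flag,
so realistic runs cannot accidentally lean on oracle columns.

Deliberately not emulated: ascertainment through screening-based referral
(pairs are sampled at random), realistic human LD maps, genotype
imputation, age-at-onset hazards (the outcome is lifetime status at last
follow-up), and non-additive genetic variance. A green recovery test
therefore establishes that the estimators are correct *under the stated
world*, not that the published point estimates are reproducible — the
real cohort's data-dependent quantities (its AUC near 0.97, its exact
Table estimates) are out of reach by design.

## Known limitations

* The probit mixed model and the biometric model use different integration
  machinery (quadrature vs rectangle probabilities); their variance scales
  differ accordingly (conditional vs marginal), so their random-effect
  summaries are not directly interchangeable.
* Quasi-likelihood treatment of the $\varepsilon4$ count is consistent but
  not fully efficient; with strongly skewed allele frequencies the normal
  working density understates tail information.
* Profile CIs assume a unimodal profiled deviance within the search box;
  bounds that hit the box are flagged `open` rather than extrapolated.
* The A_P--C covariance split is reported but its identification is
  fragile; treat `free_apc = TRUE` fits as sensitivity analyses.
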