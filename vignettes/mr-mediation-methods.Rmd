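---
title: "Methods: Mendelian randomisation mediation of education effects on cardiovascular disease"
author: "mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomisation mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The scientific problem

Longer education is associated with lower cardiovascular risk, but education
itself is hard to intervene on. If a substantial fraction of its protective
effect travels through modifiable risk factors — body mass index (BMI),
systolic blood pressure (SBP) and lifetime smoking — then intervening on
those mediators can reduce the cardiovascular inequality attributable to
education. Quantifying *how much* travels through each mediator is a
mediation problem, and the classical observational answer is biased by two
things genetics can help with: unmeasured confounding, and measurement error
in the mediator, which attenuates the mediator–outcome coefficient and hence
the estimated proportion mediated.

`mrmediate` implements three complementary designs around a common estimand,
the proportion of the total effect of a standardised exposure on a binary
outcome that is transmitted through each mediator:

1. **Two-sample Mendelian randomisation (MR)** on GWAS summary statistics.
2. **One-sample MR** with weighted allele scores in individual-level data.
3. **Observational regression mediation** with bootstrap uncertainty.

All binary-outcome effects are computed and combined on the log-odds scale;
odds ratios appear only when rendering reports. Mediation algebra is linear
on log odds, while products of odds ratios are ill-defined under
non-collapsibility.

## Estimators

With harmonised per-SNP associations $(\hat\beta_{ZX,j}, \hat\beta_{ZY,j})$
and standard errors $(\sigma_{X,j}, \sigma_{Y,j})$:

* **Wald ratio**: $\hat\theta_j = \hat\beta_{ZY,j}/\hat\beta_{ZX,j}$ with
  first-order delta SE $\sigma_{Y,j}/|\hat\beta_{ZX,j}|$, or the
  second-order form adding $\hat\beta_{ZY,j}^2\sigma_{X,j}^2/\hat\beta_{ZX,j}^4$.
* **Fixed-effect IVW**: the inverse-variance weighted mean of the ratios;
  with first-order weights this is exactly weighted least squares of
  $\hat\beta_{ZY}$ on $\hat\beta_{ZX}$ through the origin with weights
  $1/\sigma_Y^2$.
* **MR-Egger**: the same regression with an intercept after orienting all
  SNPs to non-negative exposure effects; the intercept tests directional
  pleiotropy (t, $k-2$ df) and the slope is a pleiotropy-robust estimate.
  SEs carry a multiplicative overdispersion factor
  $\max(1, \sqrt{RSS/(k-2)})$; a strict fixed-effect toggle exists.
* **Weighted median**: ratios sorted, inverse-variance weights normalised,
  and the estimate interpolated at cumulative weight midpoint 0.5;
  consistent when at least half the weight comes from valid instruments.
  Its SE is the SD over parametric resamples of the per-SNP betas, with a
  mandatory seed.
* **Multivariable MR (MVMR)**: weighted least squares of the outcome betas
  on the matrix of exposure betas without intercept, weights $1/\sigma_Y^2$,
  giving each exposure's effect conditional on the others.

Two mediation constructions:

* **Product of coefficients (two-step MR)** per mediator: $a$ = IVW effect
  of exposure on mediator; $b$ = the mediator coefficient from an MVMR of
  the outcome on (exposure, mediator) over the union of both instrument
  panels; indirect $= ab$ with the Sobel SE
  $\sqrt{a^2\sigma_b^2 + b^2\sigma_a^2}$ (no covariance term — two-sample
  pieces come from effectively non-overlapping sources).
* **Difference method** for all mediators jointly:
  $P = (T - D)/T$ with $D$ the exposure coefficient from an MVMR including
  every mediator. The product method is preferred per mediator (least bias
  for binary outcomes); it does not extend to several simultaneous
  mediators in summary-data MR, hence the difference construction for the
  combined estimate.

Proportions mediated are never clipped to $[0,1]$ and their 95% intervals
use the Normal 1.959964 multiplier throughout (delta method), or bootstrap
percentiles where individual-level resampling is available.

## Key tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `palindrome_policy` | `drop_ambiguous` | A/T and G/C SNPs are strand-ambiguous; by default they are dropped when either allele frequency is within 0.08 of 0.5 and otherwise aligned by frequency, never strand-flipped. `infer_by_eaf` flips instead; `keep` trusts the letters. |
| `eaf_ambiguity_window` | 0.08 | Drop palindromic SNPs with min(eaf, 1−eaf) > 0.42. |
| `r2_threshold`, `window_kb` | 0.001, 10000 | Greedy clumping: no retained pair within the window may exceed the r² threshold. The lenient panel regime (pairwise r² < 0.1) is reachable through the same parameters. |
| `se_order` | `first` | Delta order for ratio SEs; first-order matches the standard fixed-effect IVW weighting. |
| `n_boot` | 1000 | Bootstrap resamples (weighted median parametric; observational/one-sample nonparametric percentile). A seed is required wherever a bootstrap runs. |
| Trait SDs | 3.6 y, 4.69, 18.68 mm Hg | Per-SD scaling anchors for education, BMI and SBP used when converting native units. |
| SBP medication offset | +10 mm Hg | Added to measured SBP for treated participants before standardisation. |

Clumping ties on p-value are broken by larger |beta/se| and then by
lexicographic SNP id, so output is invariant to input row order.

## The synthetic study

No individual-level cohort of this kind is redistributable, so the package
ships a generator (`synth_config()`, `simulate_cohort()`) that reproduces
the causal structure the analyses assume, with closed-form truth for every
estimand:

* Independent dosages $G_k \sim \text{Binomial}(2, \text{maf}_k)$,
  maf $\sim U(0.05, 0.45)$; four disjoint panels of 100 SNPs (exposure +
  three mediators), so instruments are valid by construction; a pleiotropy
  knob can add direct SNP→outcome effects for sensitivity-estimator
  studies.
* Education (unit variance) takes 12% of its variance from its panel —
  the variance explained reported for the largest attainment GWAS — plus a
  standard-normal unobserved confounder $U$ (loading 0.3).
* Latent mediators (unit variance) take $\theta_i$ per SD of education
  with $\theta = (-0.22, -0.15, -0.32)$ for BMI, SBP and smoking — the
  two-sample IVW estimates for these pathways — plus 10% of variance from
  their own panels and a 0.2 loading on $U$. The mediator-panel strength is
  a design choice of the synthetic study: it keeps split-sample allele
  scores strong enough for one-sample mediation at a 100 000-person cohort,
  where the published instruments would require millions.
* Observed mediators add classical measurement noise with reliabilities
  (0.95, 0.7, 0.7): BMI is measured well; blood pressure and lifetime
  smoking are not, which is exactly the mechanism that attenuates
  observational mediation.
* The outcome is Bernoulli-logistic on the *latent* mediators, the
  exposure's direct effect, $U$ (loading 0.3) and benign age/sex terms,
  with 5% baseline prevalence. The total log odds ratio is
  $\ln 0.63$ per SD of education and the proportions through BMI/SBP/
  smoking are (0.18, 0.21, 0.34).

Because the mediators are conditionally independent given exposure and
confounder, the log-odds truth is exactly additive:
total $=$ direct $+\sum_i \theta_i\beta_i$, and the combined
(difference-method) proportion equals the sum of the per-mediator
proportions — 0.73 at the defaults. In the real study the combined estimate
(36%) is smaller than the sum of the individual ones because the risk
factors overlap and interact; the generator deliberately omits those
pathways, so its combined truth is the additive one.

The generator also emits realism details the pipeline must undo: education
in years (SD 3.6), measured SBP in mm Hg with 10 mm Hg subtracted for
(blood-pressure-dependent) medication users, which
`standardise_phenotypes()` re-adds via `adjust_sbp_for_medication()` before
standardising.

What the generator does *not* emulate: linkage disequilibrium between
SNPs, assortative mating and dynastic effects, selection into the cohort,
mediator–mediator causal paths, and time-varying exposures. Passing
recovery tests therefore demonstrates correctness of the estimators under
the assumed causal model, not robustness to those real-data violations.

## What the recovery studies show

`end_to_end_truth_check()` runs simulate → GWAS scans → all three arms and
tabulates estimates against truth. At the design scale (n = 100 000, 100
SNPs/panel, 50 replicates) the two-sample and one-sample proportions
mediated are unbiased to within a few hundredths; the acceptance suite
asserts mean absolute deviations of at most 0.04 (two-sample) and 0.06
(one-sample).

Two deliberate imperfections are worth understanding:

* The *total* log odds ratio from per-SNP logistic GWAS is attenuated by a
  few percent relative to the conditional generating value
  (non-collapsibility of the odds ratio: the marginal per-SNP coefficient
  averages over the other risk factors). The attenuation factor is common
  to numerator and denominator of every proportion, so proportions mediated
  are unaffected — which is why the package computes mediation on log odds
  and reports the proportion, exactly as the underlying study does.
* Observational estimates are biased by construction: the unobserved
  confounder pulls the total effect toward the null, and classical
  measurement error multiplies each observational indirect effect by the
  mediator's reliability. With reliability 0.6 the observational proportion
  mediated falls well below the MR proportion on the same cohorts — the
  mechanism the acceptance suite checks over 200 replicates.

## Numerical choices and degenerate inputs

* Per-SNP logistic scans use the sufficient statistics of the 3-valued
  dosage (genotype-class and case counts) with a vectorised two-parameter
  Newton iteration (tolerance 1e-12, 50 iteration cap); it agrees with
  `glm` to ~1e-8 and turns a 400-fit scan into two passes over the
  genotype matrix. Covariate-adjusted binary scans fall back to `glm`.
* Weighted-median interpolation clamps to the extreme ratios when 0.5 lies
  outside the cumulative-midpoint range (fewer than two effective
  instruments on one side).
* `wald_ratio` refuses a zero exposure beta; IVW drops zero-`bx` rows;
  Egger and the weighted median require at least 3 instruments; MVMR
  requires more SNPs than exposures and errors on rank deficiency naming
  the collinear exposure (an all-zero exposure column has no defined
  coefficient).
* The delta SE of a proportion is undefined at a zero indirect effect; the
  point estimate 0 is returned with an `NA` SE unless bootstrap replicates
  are supplied.
* 2SLS uses structural residuals (original regressors) for its error
  variance; the binary one-sample estimator is the reduced-form /
  first-stage ratio, whose multivariable analogue solves the small linear
  system `B c = g` between first-stage and reduced-form coefficients.
* All randomness flows through explicit seeds; package functions restore
  the caller's RNG state.

## Design decisions that were genuinely open

* **Palindromic SNPs**: the source analyses do not state a rule. The
  conservative default never strand-flips; inference by frequency is
  available because it is common practice in two-sample pipelines.
* **IVW weighting order**: first-order weights (the standard fixed-effect
  estimator); the second-order option is retained for single-SNP
  reporting.
* **Overdispersion**: multiplicative `max(1, ·)` scaling for Egger and
  MVMR, with strict fixed-effect toggles, since the underlying study is
  silent.
* **Missing-estimate policy in MVMR**: SNPs lacking an association for any
  exposure or the outcome are dropped and counted, mirroring the fail-safe
  reading of the instrument-union construction.
* **One-sample weighting**: split-sample (weights from one half, analysis
  in the other) for *all* scores, generalising the split design used in
  practice when instrument discovery and analysis would otherwise share a
  cohort; it removes winner's-curse overlap in the synthetic studies.
* **Risk-difference replication**: a linear-probability toggle replicates
  the individual-level mediation on the additive scale, as the original
  sensitivity analysis does.

## Problem sizes used by the shipped studies

The synthetic recovery studies use cohorts of 100 000 with 100 SNPs per
panel (50 replicates) for the headline recovery check, 10 000 with 25 SNPs
per panel (200 replicates) for the attenuation-ordering study, and smaller
instances for unit-level properties. These sizes were chosen so each study
resolves its estimand well inside the Monte-Carlo error budget of the
assertions it feeds.

## Known limitations

* LD-free instruments mean the clumping module is exercised on constructed
  LD matrices, not on the generator's output.
* The one-sample binary estimator is a ratio method, not a full maximum
  likelihood IV; its SE ignores first-stage uncertainty beyond the delta
  approximation (bootstrap CIs are available and preferred).
* Proportions mediated are unstable when the total effect is near zero;
  the package errors rather than reporting an undefined ratio.
* Reproducing the published two-sample numbers requires the per-SNP
  supplementary association tables as inputs
  (`reproduce_published_two_sample()`); they are not redistributable with
  the package.
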