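---
title: "Models and design of the lipmed pipeline"
author: "lipmed authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the lipmed pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipmed)
```

## The scientific question

Variants in lipid-regulating loci such as *MLXIPL* are associated with
triglycerides (TG) and HDL cholesterol, and those lipids are in turn risk
factors for coronary heart disease (CHD) and, more contentiously,
Alzheimer's disease (AD). `lipmed` implements the statistical machinery
needed to dissect such SNP → lipid → disease relationships in
multi-cohort longitudinal data: genotype QC, longitudinal lipid
association models, Cox disease models, conditional-attenuation
comparisons, causal mediation for survival outcomes, and fixed-effect
meta-analysis — together with a synthetic multi-cohort generator so that
every stage can be exercised and validated without access-controlled
cohort data.

## Genotype QC and coding

Dosages count copies of the minor allele (0/1/2). `minor_allele_freq()`
refuses vectors whose counted-allele frequency exceeds 0.5 rather than
silently re-orienting, because a miscoded SNP flips the sign of every
downstream effect. `hwe_exact_test()` is the exact conditional test of
Hardy–Weinberg proportions (two-sided, no mid-p), evaluated through the
standard recurrence over heterozygote counts; the conventional inclusion
filter is p > 0.01, applied as a flag by `snp_qc()`, never as a silent
drop. Linkage disequilibrium is summarised by `ld_r2()`, the squared
Pearson correlation of dosage vectors over pairwise-complete
observations (the composite genotypic r²). Phased/EM haplotype r² would
require either phase information or an EM fit whose result is
essentially identical under Hardy–Weinberg equilibrium; the composite
form is deterministic and transparent, and that trade-off is deliberate.
`select_tag_sets()` partitions SNPs into connected components of the
graph with edges at r² ≥ 0.25, so that SNPs in different sets have
below-threshold LD; which individuals count as "unrelated" for the LD
computation is left to the caller via the `persons` argument of
`ld_matrix()`, since relatedness inference is out of scope.

Carrier coding (`code_genotype(..., "carrier")`) collapses heterozygotes
and minor homozygotes against major homozygotes; it is the exposure
contrast for mediation, where combining the carrier classes preserves
power at low minor-allele frequencies.

## The longitudinal lipid model

Lipids are modelled on all person-exam rows with a Gaussian
estimating-equation regression (`fit_linear_longitudinal()`),

$$Y_{ij} = \beta_0 + \beta_g G_i + \gamma^\top C_{ij} + \epsilon_{ij},$$

with basic adjustments sex, birth year, site and exam age; conditional
models add one co-lipid, and pairwise-SNP models a second dosage term.
Two working correlations are provided: independence (point estimates are
exactly stacked OLS) and exchangeable within person. A general
unstructured working correlation is not identified with ragged exam
counts (1–5 exams at irregular ages), which is why it is not offered;
estimating-equation point estimates are consistent under any working
correlation, and validity of the reported standard errors comes from the
cluster-robust sandwich variance, clustered on the family so that both
repeated exams and family relatedness are absorbed. Persons must nest
within families. With one exam per person the independence and
exchangeable fits coincide exactly — a property the test suite asserts.

## Disease models

`fit_cox()` fits Cox proportional-hazards models with age as the time
axis from birth and no left truncation, Efron tie handling, and
family-clustered robust standard errors. Treating everyone as at risk
from age 0 on the age axis is an analytic convention inherited from the
study design this pipeline mirrors, not a modelling recommendation; it
is faithful to how the reference analyses were run. Disease models use
one row per person; lipid covariates, when requested, follow the
mediator-measurement rule below. Monotone-likelihood notices from small
strata are retained as diagnostics on the result object rather than
surfaced as warnings.

The mediator-measurement rule (`person_level()`): for each person, the
latest exam at which all four lipids are present and which does not
postdate the onset of any modelled disease. Censoring ages do not
constrain the choice; onset ages do.

## Conditional attenuation

`conditional_attenuation()` reports
$100\,(|\beta_{unadj}| - |\beta_{adj}|)/|\beta_{unadj}|$, rounded to the
nearest integer percent (the raw value is also returned). Rounding of
absolute values is what reproduces printed attenuation percentages such
as 52% for a 0.98 → 0.47 change; negative values (magnification) are
possible and reported as such.

## Mediation for a survival outcome

The exposure is carrier status $A$, the mediator $M$ a lipid at the
pre-onset exam, the outcome a disease age with indicator. Two models are
fit: a Gaussian mediator regression
$M = \beta_0 + \beta_1 A + \gamma^\top C + \epsilon$ and a Cox outcome
model $\lambda(t) = \lambda_0(t)\exp(\theta_1 A + \theta_2 M +
\theta_3^\top C)$, with no exposure–mediator interaction.

Two estimators of the natural effects on the log-hazard scale are
provided, and every result carries its estimator label:

* **Product method** (primary): under a rare outcome,
  $\beta_{DE} = \theta_1$, $\beta_{IE} = \theta_2\beta_1$,
  $\beta_{TE} = \beta_{DE} + \beta_{IE}$ exactly. It is transparent,
  exactly additive, and fast enough to bootstrap densely.
* **Weighted natural-effect Cox model** (secondary): each person enters
  twice, once with the auxiliary exposure equal to the observed value
  and once flipped, weighted by the Gaussian mediator density ratio
  $f(M \mid A = a', C)/f(M \mid A = A_{obs}, C)$; a weighted Cox model
  with observed-exposure and auxiliary-exposure terms then returns the
  direct and indirect effects. Weights are truncated at the 99th
  percentile by default, and the fit aborts if more than half the
  weights sit at the truncation bound.

The two estimators agree closely when the outcome is rare (the regime in
which the product decomposition is licensed); with common outcomes
(case fraction above ~20%) they are expected to diverge, which is a
feature: the divergence measures the failure of the rare-outcome
approximation. The marginal-structural-model literature this follows
does not pin down one unique weighting scheme; the implementation here
is one standard realisation, which is why both routes are surfaced.

Inference is a nonparametric bootstrap over persons
(`bootstrap_mediation()`; the reference analysis size is 1000
replicates): standard errors are bootstrap SDs, confidence intervals are
2.5/97.5 percentiles, and $p_{IE}$ is a two-sided normal approximation
from $\beta_{IE}/\widehat{se}_{IE}$ (a percentile-CI p-value is not well
defined). No cluster correction is applied in the bootstrap — the
resampling unit is the person, mirroring the reference design. The
proportion mediated is $100\,\beta_{IE}/\beta_{TE}$ with the
$\beta_{DE}+\beta_{IE}$ sum as the primary total-effect denominator
(exactly additive for the product estimator); results where direct and
indirect effects pull in opposite directions are flagged as inconsistent
mediation, since the percentage is then hard to interpret. The
no-unmeasured-confounding assumption between mediator and outcome is
asserted, not tested; the generator's optional confounder-free design
makes it true by construction in simulations.

**Calibration of the product p-value.** When exactly one of
$\beta_1, \theta_2$ is zero and the other is strongly identified, the
product statistic is asymptotically normal and $p_{IE}$ is uniform — the
test suite measures a 5.0% type-I error rate and a Kolmogorov–Smirnov
uniformity p-value of 0.99 across 500 null simulations in that regime.
Under the complete null ($\beta_1 = \theta_2 = 0$) the product of two
near-zero estimates is well known to concentrate sharply at zero and the
normal-approximation p-value becomes severely conservative (measured
rejection rate ≈ 0); this is a property of every product-based test, not
an implementation artefact, and it is why the calibration suite fixes a
strong exposure→mediator path when probing the null of no mediation.

## Fixed-effect meta-analysis

`fixed_effect_meta()` combines per-cohort estimates with inverse-variance
weights $w_i = 1/se_i^2$ (the effect-based scheme used when betas and
standard errors are combined): $\hat\beta = \sum w_i\beta_i/\sum w_i$,
$se = (\sum w_i)^{-1/2}$. Cochran's Q and $I^2$ are reported as
diagnostics but never switch the model — the pipeline is fixed-effect
throughout. `ci_overlap_compare()` implements the conservative
disjoint-CI criterion for declaring two samples different, alongside the
standard two-sample z-test, because CI overlap alone under-rejects.

## The synthetic multi-cohort generator

The generator (`sim_config()`, `simulate_multicohort()`) emulates the
data structure the models assume; its defaults are the study conditions
the pipeline is designed for and are not tuned per experiment:

* **Genotypes.** Four SNPs with MAFs 0.20/0.19/0.10/0.15, pairwise
  dosage r² of 0.77 for the first pair and 0.03 elsewhere, drawn through
  a Gaussian copula: a latent multivariate normal thresholded at the
  Hardy–Weinberg genotype-probability quantiles, with the latent
  correlation calibrated by monotone root search so the realized dosage
  r² hits its target. The first two MAFs are nearly equal because a
  dosage r² of 0.77 is attainable only for near-equal allele
  frequencies. Pairwise targets are the design goal; higher-order LD
  structure is not modelled.
* **Lipids.** Means 120/52/130/200 mg/dL and SDs 45/15/33/38 mg/dL for
  TG/HDL-C/LDL-C/TC, cross-lipid correlation −0.42 (TG–HDL-C) and 0.95
  (LDL-C–TC); family-shared, person-level and exam-level Gaussian
  components all carry the same correlation matrix so the marginal
  exam-level correlation equals the target. Additive (or carrier) SNP
  effects in mg/dL per allele, sex shifts and exam-age slopes give the
  basic adjustments real signal. Values are floored at 1 mg/dL to keep
  lipids positive; the TG SD of 45 keeps that floor binding for well
  under 1% of draws so injected effects stay recoverable without bias.
  A `friedewald_ldl` switch instead rebuilds TC from the Friedewald
  identity TC = LDL-C + HDL-C + TG/5. Real lipid panels are
  right-skewed; the generator is Gaussian by design, so passing tests
  demonstrate correctness of the estimators under their stated
  assumptions, not robustness to skewness.
* **Exams and families.** 1–5 exams per person at ages 45–60, families
  of size 1–3 sharing a lipid intercept. Events are conditionally
  independent of family given the lipids — enough structure to exercise
  cluster-robust variance, without frailty terms.
* **Events.** Constant baseline hazard beyond age 60 with
  $\lambda(t) = \lambda_0 \exp(\theta_1 A + \theta_2 (M - \bar M))$,
  where $M$ is the person's last-exam mediator value, and independent
  uniform censoring over ages 60–95. Because exams end before 60, the
  pre-onset mediator rule is satisfied by construction. The default
  baseline rates (0.0030/y for AD, 0.0038/y for CHD) give roughly 5% and
  6.6% case fractions under
  $P(\text{event}) = 1 - (1 - e^{-35\lambda_0})/(35\lambda_0)$.
  Mediator–outcome confounding is absent by default, matching the
  estimator's identifying assumption.

Cohorts are independent, share the SNP effects, and differ in small
random lipid mean shifts (5% of each SD), so cross-cohort meta-analysis
has genuine but homogeneous signal. Everything is deterministic given
the seed.

## Numerical choices

* Bivariate-normal rectangle probabilities for copula calibration are
  computed by one-dimensional quadrature to ~1e-10 and the latent
  correlation solved to 1e-8; the exchangeable GEE iterates to 1e-10
  with the within-person correlation clamped to (−0.49, 0.99).
* The HWE recurrence is anchored at the most probable configuration and
  normalised once, with ties in the "as extreme" comparison resolved by
  a 1 + 1e−9 relative guard; it agrees with direct-factorial
  enumeration to 1e-12 up to n = 200 and beyond.
* Cox fits use Efron ties throughout. Bootstrap replicates that fail
  (singular resample designs) are dropped; more than 10% failures abort
  with diagnostics. Monotone-likelihood replicates keep the stopped
  coefficient.
* Tag-set output is deterministic: members sorted within sets, sets
  sorted by first member.

## Problem sizes used in validation

The test suite validates parameter recovery at n = 20,000 persons
(CI coverage of a true indirect effect of 0.015 across 100 replicates at
200 bootstrap draws) and calibration at n = 2,000 (500 null replicates
at 150 bootstrap draws); oracle-equivalence suites use 100 datasets of
up to 30 persons for the Cox grid search and genotype counts up to
n = 200 for the HWE enumeration. These sizes were chosen to make
Monte-Carlo error small relative to the tolerances being asserted while
keeping the full suite comfortably rerunnable on a laptop.

## Known limitations

* One mediator at a time; no exposure–mediator interaction terms, no
  time-varying mediators, and no sensitivity analysis for unmeasured
  confounding.
* The longitudinal model offers independence/exchangeable working
  correlations only; fully unstructured estimation is out of scope.
* The generator's pairwise-LD copula does not reproduce realistic
  haplotype structure, secular trends, or competing risks.
* Attenuation percentages and the proportion mediated are descriptive
  transformations of fitted coefficients; their sampling uncertainty is
  not propagated.
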