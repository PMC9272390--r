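---
title: "Separating direct effects of general and central adiposity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating direct effects of general and central adiposity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Body mass index (BMI, general adiposity) and waist-to-hip ratio (WHR,
central adiposity) are strongly intertwined: higher BMI raises WHR, the
two share genetic and environmental causes, and both influence circulating
lipids and metabolites. Observational regressions of metabolic traits on
either measure are confounded by lifestyle and socioeconomic factors, and
mutual adjustment of two error-prone measured exposures under-corrects.
Mendelian randomization (MR) replaces the measured exposure with its
genetically predicted value: because alleles are allocated at random at
conception, a genetic risk score (GRS) is unconfounded by postnatal
factors, and two-stage least squares (2SLS) against the score estimates a
causal effect under the instrumental-variable assumptions.

Two complications motivate most of this package:

1. **Total versus direct effects.** Because BMI raises WHR, the
   univariable (total) effect of BMI on a trait includes the path through
   WHR. Multivariable MR instruments both exposures jointly — each
   exposure regressed on *both* scores in the first stage, the outcome on
   both predicted exposures in the second — so each coefficient is a
   direct effect holding the other adiposity measure fixed.
2. **Medication as a collider.** Statins lower measured LDL cholesterol,
   and higher adiposity (and higher LDL-C itself) increases the odds of
   statin prescription, more so at older ages. Measured LDL-C therefore
   under-represents the latent, pre-treatment trait among users, and
   *excluding* users conditions on a variable caused by both exposure and
   outcome — a collider — which can bias even an otherwise valid MR
   design. Stratifying on age, which adiposity cannot influence, is the
   safer probe: medication masking should concentrate in older strata.

## The estimators

**Univariable 2SLS.** Stage 1: `x ~ score + covariates`; stage 2:
`y ~ x_hat + covariates`. With one instrument and one exposure this equals
the Wald ratio cov(z, y)/cov(z, x). Standard errors are
heteroskedasticity-robust HC1 sandwich estimates in the IV influence form:
the bread uses the substituted design, the residuals use the *actual*
exposure, which correctly propagates first-stage estimation into the
second-stage variance. The paper-style output row carries beta, SE, the
normal-reference 95% CI and p, the analysed n (complete cases per model),
and instrument-strength statistics.

**Multivariable 2SLS.** As above with both exposures and both scores. The
reported instrument strength per exposure is the Sanderson–Windmeijer
conditional F: residualise exposures and scores on the covariates,
partial the other exposure out of the target exposure by IV using both
scores, regress that residual on the scores, and scale the joint F by
k_Z/(k_Z − k_other) = 2. The conventional adequacy threshold is 10.

**Logistic second stage.** For binary outcomes (statin use) the second
stage is a maximum-likelihood logistic regression on the predicted
exposure — predictor substitution. The naive ML standard errors ignore
first-stage noise; a nonparametric bootstrap of both stages is available
(`n_boot`), and with instrument strength in the thousands the difference
is negligible.

**Interaction tests.** Effect modification by an observed variable (sex,
statin use, age) is tested by adding the modifier and the product of the
genetically predicted exposure with the modifier to the second stage, with
robust SEs on that design. Under a null of no modification the p-values
are uniform (this is verified by simulation in the test suite).

**Summary-level estimators.** From per-SNP association pairs the package
provides four estimators with different pleiotropy assumptions: IVW
(all SNPs valid; equivalent to 2SLS in one-sample data), MR-Egger (free
intercept estimating directional pleiotropy), the weighted median
(majority-valid) and the weighted mode (plurality-valid). IVW and Egger
use multiplicative random-effects scaling, never deflating below the
fixed-effect SE; Egger p-values use a t reference with J − 2 df. Ratio
variances use the first-order delta method. Median and mode SEs come from
a seeded parametric bootstrap (default 1000 draws). The mode uses a
normal-kernel density over the ratio estimates with bandwidth =
`bandwidth_factor` × a weighted Silverman rule
(0.9 · min(weighted SD, 1.4826 · weighted MAD) · J^(−1/5)), evaluated on a
512-point grid spanning the ratios ± 3 bandwidths, ties broken toward the
smallest absolute estimate; the NOME penalty is deliberately omitted.
Harmonisation matches SNPs by ID, flips swapped alleles, and resolves
palindromic (A/T, C/G) SNPs by allele frequency only when both sides are
away from 0.5 (outside [0.42, 0.58]), dropping the rest.

## The synthetic cohort generator

Real individual-level biobank data are managed-access, so the generator
is a first-class module that reproduces the *assumed causal structure* of
the analysis, with every coefficient recorded as an estimand:

- **Genotypes.** Unlinked biallelic SNPs in Hardy–Weinberg equilibrium,
  dosage Binomial(2, f), f uniform on `maf_range`. No LD (real
  instruments are clumped to near-independence), no population structure;
  the "genetic PC" columns are pure noise stand-ins so that model
  interfaces match the field's conventions.
- **Exposures.** BMI = genetic score + confounder + noise with unit
  variance and genetic fraction `h2_bmi`; WHR adds `delta_bmi_to_whr` ×
  BMI. Shared SNPs affect BMI directly and enter the WHR weight table
  with their *marginal* WHR effect delta × b — what an unadjusted WHR
  GWAS would report — so the two scores correlate (expected r is a
  closed form stored in the truth record) while every score remains a
  valid instrument for its exposure.
- **Outcomes.** Each trait is theta_bmi · BMI + theta_whr · WHR + kappa ·
  U + noise, scaled to unit variance. U is a single standard-normal
  confounder loading on exposures and outcomes — the minimal structure
  that makes the observational-versus-MR contrast meaningful. Outcome
  noise is independent across traits; the observed-scale correlation
  structure among real metabolite panels is not modelled.
- **Medication.** Statin use is Bernoulli on a logistic scale in BMI,
  WHR, *latent* LDL-C and centred age; measured LDL-C is the latent value
  minus `tau_statin` for users (a constant SD-scale subtraction — simpler
  than proportional lowering and sufficient for sign and attenuation
  behaviour). Sex is Bernoulli(1/2) with optional per-sex theta
  overrides; allele effects themselves are never sex-specific.
- **Observational covariates.** Education and smoking proxies are drawn
  correlated with U and enter only the conventional models, as in the
  analysis design being emulated.

### The `ukb_like_config()` preset

The preset fixes the study conditions used throughout the tests and the
acceptance script:

| parameter | value | rationale |
|---|---|---|
| SNPs (BMI-specific / shared / WHR-specific) | 16 / 24 / 24 | expected score correlation 0.254, matching the reported 0.25 |
| h2_bmi, h2_whr | 0.05, 0.04 | GRS-scale variance fractions; conditional F in the thousands at n = 10^5 |
| delta_bmi_to_whr | 0.4 | BMI-to-WHR path; gives a 0.24 total BMI effect on triglycerides |
| theta (triglycerides) | BMI 0, WHR 0.6 | central adiposity carries the whole direct effect (reported 0.62/0.63 SD) |
| theta (LDL-C) | BMI 0, WHR 0.15 | small WHR-specific LDL-raising effect |
| theta (HDL-C) | BMI −0.1, WHR −0.3 | inverse control outcome |
| confounder loadings | 0.25/0.20 (exposures), 0.3 (outcomes) | moderate shared confounding |
| statin model | intercept −2.15, slopes 0.4 (BMI), 0.5 (WHR), 0.7 (latent LDL-C), 0.095/yr (age) | calibrated so prevalence rises roughly 5%→17%→29% across age tertiles with a ~16–17% overall rate |
| tau_statin | 1.5 SD | statin-scale LDL-C lowering consistent with trial effects |
| age | uniform 38–73 y | biobank recruitment window |

What passing tests on this generator do **not** show: robustness to LD
between instruments, to population stratification, to genuine horizontal
pleiotropy of the adiposity SNPs, to imputation error (dosages are hard
calls by default), or to the dense correlation structure of real NMR
panels. They do show that every estimator computes what it claims on data
whose truth is known exactly.

## Numerical choices and degenerate inputs

- Sample SD (n − 1) everywhere; standardisation is always among sexes
  combined, before any stratification, so stratum-level SDs are not 1.
- Complete-case deletion per model; each result row reports its own n.
- Singular designs are detected by a condition-number threshold of 1e10
  on the second-stage cross-product; collinear instruments/covariates and
  duplicated exposures error out rather than returning noise.
- Missing dosages: a score is averaged over an individual's observed
  SNPs by default (`na_action = "average"`, matching the average-per-SNP
  semantics of the scoring rule); a strict mode errors instead. Whether
  real scoring pipelines adjust per-individual denominators is ambiguous,
  so both are provided.
- Age tertile boundaries are the empirical 1/3 and 2/3 quantiles;
  boundary ages go to the lower tertile, deterministically.
- The weighted-mode density falls back to the weighted mean when the
  ratio spread is exactly zero; `mr_ivw` drops zero-beta_x SNPs with a
  warning.
- All simulation and bootstrap randomness is seeded; identical
  configurations give byte-identical cohorts and results.

## Problem sizes

Unit tests run on cohorts of 200–50,000 individuals with 4–100 SNPs.
The replicate-based properties use 200 cohorts of n = 20,000 (parameter
recovery and CI coverage), 200 of n = 8,000 per arm (collider probe), 500
null cohorts of n = 1,500 (interaction calibration) and 1,000
summary-level draws (Egger calibration). The acceptance script analyses a
single cohort of n = 100,000. These sizes were chosen so that Monte-Carlo
error is several times smaller than the effects being checked.

## Known limitations

- Two-sample estimators are univariable only; multivariable summary-level
  MR is deliberately out of scope.
- No LIML/Fuller or weak-instrument-robust (Anderson–Rubin) inference;
  instruments here are strong by construction.
- The logistic second stage reports substitution estimates; these are
  consistent under the null and with strong instruments, but their naive
  SEs understate uncertainty when instruments are weak — use the
  bootstrap option there.
- No clumping, GWAS, imputation or ancestry handling: instrument
  selection is upstream of this package.
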