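---
title: "Ethnicity-stratified polygenic risk modeling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ethnicity-stratified polygenic risk modeling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnoprs)
```

# The problem

Polygenic risk scores trained in one ancestry group routinely lose accuracy
when transferred to another: allele frequencies diverge, effect sizes
differ, and the causal architecture itself may only partly overlap between
populations. `ethnoprs` implements a stratified workflow for a dichotomous
disease outcome (a COPD analogue) with a continuous endophenotype (an FEV1
analogue): per-group quality control, SNP-heritability estimation, mixed-
model BLUP screening of variants, partially-penalized logistic risk models
tuned by nested cross-validation, cross-group external validation, and a
deviance-based decomposition of what each variable contributes. Because
real multi-ethnic cohorts of this kind are access-restricted, the package
ships a simulator that generates multi-population cohorts with known
architecture, so every stage of the pipeline is testable end to end.

# Models

## Screening mixed model

For one group, let `y` be the continuous trait, `Z` the fixed-effect
covariates (age, sex, height, pack-years, plus intercept) and `K` the
genetic relationship matrix computed from standardized dosages,
`K = (1/m) * Gs Gs'` with `Gs[,j] = (g_j - 2 p_j) / sqrt(2 p_j (1 - p_j))`.
The model is

    y ~ MVN(Z beta, sigma_g2 * K + sigma_e2 * I)

and `h2 = sigma_g2 / (sigma_g2 + sigma_e2)` is the SNP heritability.
Variance components are estimated by REML. For a single GRM the restricted
likelihood profiles analytically down to one dimension: writing
`V0 = h2 * K + (1 - h2) * I` and rotating by the eigenvectors of `K`, the
total variance has a closed-form optimum, so the fit is an exact dense scan
plus golden-section refinement over `h2` with the `h2 = 0` boundary always
evaluated. This is preferred here over iterative AI-REML for the
single-component case because it cannot diverge, is immune to starting
values, and makes the grid-style optimality check in the test suite cheap
(the same eigendecomposition is reused). The multi-component
(chromosome-partitioned) fit `V = sum_c sigma_c2 K_c + sigma_e2 I` has no
such reduction and uses average-information REML with EM fallback steps
and projection onto the non-negative orthant; it reports each chromosome's
share `sigma_c2 / sum(sigma_c2)` of the genetic variance.

Screening ranks variants either by the absolute per-SNP BLUP score

    score = Gs' K^-1 (y - Z beta_hat) / sigma_g2_hat

or by the two-sided p-value of the single-SNP linear regression with the
same covariates. Two notes on the BLUP formula. First, it divides by
`sigma_g2`, whereas the conventional mixed-model-equation SNP-BLUP
multiplies by it; only the absolute-value *ranking* feeds screening and a
positive rescaling of `sigma_g2` rescales all scores identically, so the
choice is harmless for selection — but the absolute score values should
not be compared with other software. Second, `Gs` is the standardized
matrix used for the GRM (not raw 0/1/2 dosages), keeping the score on the
same scale as `K`. When REML lands on the `sigma_g2 = 0` boundary the BLUP
score is undefined; any consumer (a CV fold, a within-group split) falls
back to the p-value ranking with a logged notice.

Top-`p` selection is a deterministic total order: descending `|score|` or
ascending p-value, ties broken by (chromosome, position, id). Smaller
lists are therefore always prefixes of larger ones.

## Risk model

With screened genotype columns `G` (penalized) and clinical covariates
`Z` (unpenalized, default age, sex, pack-years), the risk model minimizes

    (1/n) sum_i [ -y_i x_i' b + log(1 + exp(x_i' b)) ]
      + lambda * sum_{j in SNPs} [ alpha |b_j| + (1 - alpha)/2 b_j^2 ]

with `alpha = 1` (lasso), `0` (ridge) or `0.5` by default (elastic net).
Only the genetic block is penalized; the intercept and clinical
coefficients are never shrunk. The solver is cyclic coordinate descent on
a quadratic majorizer of the logistic loss with curvature bound
`mu(1 - mu) <= 1/4`: every coordinate update provably cannot increase the
objective, so the objective is monotone non-increasing across sweeps (a
property the test suite asserts directly). All columns are standardized
internally — for penalized columns this defines the penalty scale, for
unpenalized ones it is pure conditioning — and coefficients are returned
on the original scale. Convergence is declared when the largest
coefficient change in a sweep falls below `1e-7` (internal scale); hitting
the sweep cap flags the fit rather than erroring.

The data-driven lambda grid runs log-spaced from `lambda_max` (the
smallest lambda zeroing every penalized coefficient given the unpenalized
block, computed from the standardized data and nudged up by `1e-6`
relatively so the top of the grid really produces an all-zero genetic
block) down to `1e-3 * lambda_max`; the ridge family reuses the lasso-form
`lambda_max` with the mixing floored at 0.001, as is conventional.

## Cross-validation protocol

Performance estimation uses 5 stratified outer folds. Within each outer
training set the screening stack (GRM, REML, BLUP or p-values) is computed
from scratch — held-out samples never touch screening or tuning, and the
suite verifies that permuting a held-out fold's phenotypes leaves the
training-side screening output byte-identical. Tuning of (list size `p`,
penalty family, lambda) is a nested 10-fold stratified CV on the outer
training set, selecting the largest mean inner-validation AUC; ties break
toward smaller `p`, then larger lambda (the sparser, more regularized
model), then the declared family order. Inner folds whose validation part
is single-class are skipped with a warning. AUC is the normalized
Mann-Whitney statistic (ties credited one half), computed exactly from
midranks. Folds are stratified by case status because a 10% case fraction
— the population-cohort regime the simulator reproduces — makes
unstratified 10-fold inner validation sets single-class too often.
Inner-fold AUCs are averaged over folds, not pooled.

External validation applies a fitted model to an independent cohort,
matching variants by id and alleles, flipping dosages (`2 - g`) when the
effect/other labels are interchanged, and leaving genuinely mismatched
labels unmatched. Unmatched model variants contribute nothing to the
linear predictor under either the `drop_reweight` or `zero_impute` policy
(they coincide for additive scores); the matched/modeled counts are
reported.

## Deviance decomposition

Out-of-fold predicted probabilities from shared stratified 5-fold
assignments give the full-model deviance `Delta_F = sum -[y log mu +
(1-y) log(1-mu)]` (the binary cross-entropy form, `0 log 0 := 0`, no
factor 2, probabilities clipped to `[1e-12, 1 - 1e-12]`). The null model
predicts each test fold by its training-fold prevalence, giving
`Delta_0`. Explained variability is McFadden's `(1 - Delta_F/Delta_0) *
100`; the contribution of variable group `i` (each clinical covariate, and
the SNP block as one group) is `(Delta_i - Delta_F)/Delta_0 * 100`, where
the reduced model is refitted without that group under the *same* folds,
screening output and tuning selection, so the difference isolates the
group. Removing the SNP group leaves the covariate-only model; removing a
clinical covariate leaves screening untouched. Contributions are not
constrained to sum to McFadden's value (groups share signal) and negative
contributions are reported as computed. `unexplained + McFadden = 100`
holds exactly by construction. An `in_sample` mode (one refit on all
samples) is available behind a flag; out-of-fold is the default because
overfit in-sample deviances flatter the full model.

# The simulator

`simulate_cohort()` generates, per population: ancestral allele
frequencies uniform on a configurable MAF range (default 0.05–0.5);
population frequencies from the Balding-Nichols model (Beta with mean `p`
and variance `Fst * p(1-p)`; `Fst = 0` short-circuits to identical
frequencies); genotypes binomial(2, freq), i.e. Hardy-Weinberg within
population, coded on the ancestral minor allele; covariates (age normal
55/8, sex Bernoulli(0.5), height normal by sex, pack-years zero-inflated
gamma with 35% structural zeros — reproducing a population cohort's low
smoking exposure — current smoking and family history Bernoulli); and the
trait

    trait = g + e + covariate term,   g = Gs_causal %*% effects

with the genetic part rescaled so its in-sample variance equals
`target_h2` and `var(e) = 1 - target_h2`, so the heritability knob is
conditional on covariates, matching what the screening mixed model
estimates. Case status is `trait` below the population's `case_fraction`
quantile — a liability-threshold stand-in chosen because low lung function
defines the disease and because it reproduces arbitrarily unbalanced
case/control shapes (a 30% case/control cohort next to a 10% population
cohort) with one knob. This is a declared substitute for a spirometric
case definition, not an inference of one. Cross-population architecture is
controlled by `two_population_specs(overlap = ...)`: the proportion of
causal variants shared between the groups.

What the simulator deliberately does **not** emulate: linkage
disequilibrium (variants are independent), admixture and relatedness
structure beyond the single-Fst Balding-Nichols draw, imputation
uncertainty, informative missingness, or genotyping-platform batch
effects. Passing tests therefore demonstrate the pipeline's statistical
correctness and leakage-freedom under a clean polygenic architecture, not
robustness to LD-induced redundancy in screened lists or to panel
artifacts of real arrays.

A consequence worth knowing: under Fst 0.15 with ancestral MAF down to
0.05, drift pushes many variants below the 5% QC MAF floor in at least
one population, including causal ones — the realized post-QC SNP
heritability can then sit well below `target_h2`, differently per
population. That is faithful to the cross-ancestry setting. The standard
study in `scripts/acceptance.R` draws ancestral frequencies from 0.15–0.5
so its designed architecture survives QC in both groups.

# Numerical choices

- HWE exact test: Levene-Haldane conditional distribution evaluated by
  the term recurrence `P(h+2)/P(h) = 4 hom_r hom_c / ((h+1)(h+2))` in log
  space; two-sided p-value sums all heterozygote counts with probability
  at most `(1 + 1e-12)` times the observed one. At `n = 10` the smallest
  attainable p-value is about `1.4e-3`, so tiny fixtures that must fail an
  HWE filter need a raised floor.
- QC boundaries are strict: removal requires `missingness > 0.05`,
  `MAF < 0.05`, `HWE p < 1e-5`; equality survives. Attribution precedence
  (missingness, MAF, HWE; sample: missingness, sex, covariates) affects
  report bookkeeping only.
- Missing dosages are mean-imputed per variant *after* QC, before any
  matrix algebra; QC statistics always use observed genotypes.
- GRM eigenvalues are clamped at zero; `K^-1` in the BLUP adds a ridge
  jitter `1e-8 * trace(K)/n` when the smallest eigenvalue is below
  `1e-10`. REML and BLUP share one eigendecomposition.
- A/T and C/G variants are dropped as strand-ambiguous during cohort
  intersection regardless of apparent label agreement.
- Probability clipping at `1e-12` bounds a single sample's deviance
  contribution at `-log(1e-12) ~ 27.6`.
- All stochastic stages (simulation, fold assignment, splits) derive
  their seeds deterministically from one user seed; reruns are
  byte-identical, which the pipeline manifest's md5 hashes make checkable.

# Test-suite problem sizes

The suite exercises every stage on simulated cohorts sized so that each
check has adequate statistical resolution while the whole suite stays a
desk-scale run. The main choices, fixed from sampling-error arithmetic
(`SE(h2_hat) ~ sqrt(2m)/n` for an unrelated-sample GRM of `m` independent
variants):

- REML recovery: `n = 800`, `m = 1000`, 20 seeds per `h2` in
  {0, 0.2, 0.4, 0.6} — per-seed SE ≈ 0.056, SE of the 20-seed mean ≈
  0.013 against a ±0.05 bias band, with a 50×50 grid-optimality check per
  fit.
- Leakage detector: null cohorts `n = 300`, `m = 400`, genetics-only
  models, 10 seeds — SE of the mean outer AUC ≈ 0.007 against the
  [0.45, 0.55] window.
- Transfer experiment: two populations of 800, `m = 2000`, 10 causal
  variants per population, disjoint; 10 seeds.
- Overlap experiment: `n = 1200` per population, `m = 8000`, 10
  large-effect causal variants each — the few-common-large-effect regime
  in which three disjoint 400-sample splits each recover most causal
  variants in their top-100, putting the within-group overlap far above
  the hypergeometric null `p^2/m` while the between-group overlap stays
  at it.
- Pipeline determinism: two populations of 250, `m = 600`, full 5-outer /
  10-inner CV, run twice and compared byte for byte.

# Known limitations

- No LD means screened lists have no redundancy; with real data,
  correlated variants would share rank and the top-`p` lists would carry
  fewer independent signals than their length suggests. LD-aware clumping
  is out of scope.
- The liability/quantile case definition couples case status
  deterministically to the trait within a population; real spirometric
  definitions add measurement noise and criteria (e.g. ratio thresholds)
  the simulator does not model.
- Heritability is estimated on the observed scale of the continuous
  trait; no liability-scale transform for the binary outcome is provided.
- The BLUP score's absolute scale follows the printed `1/sigma_g2` form
  (see above) and is not comparable across tools.
- The partitioned REML is dense (`O(n^3)` per iteration) and intended for
  the cohort sizes the simulator produces, not biobank-scale data.
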