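---
title: "Robust analysis of method-of-limits detection thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust analysis of method-of-limits detection thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermolimits)
```

## The measurement problem

In a method-of-limits thermal detection task, a thermode resting at a
32 °C baseline ramps warmer or cooler until the participant signals a
sensation; the temperature at that moment estimates the detection
threshold. A typical protocol collects two blocks of five trials per
modality (10 warm, 10 cool per subject), with the device clamped to
0–50 °C. Thresholds are reported as the positive change from baseline.

Two features of such data drive every design choice in this package:

* **Right skew and outliers.** Per-subject threshold distributions are
  skewed with occasional extreme trials, so means and t-tests are
  poorly behaved.
* **Intra-individual variability is itself a signal.** The spread of a
  subject's ten trials (their "perceptual noise") is correlated with
  their estimated threshold and can masquerade as a group difference
  in threshold.

## Per-subject summaries

Each subject's trials are reduced to a *Harrell-Davis median* and a
*Gini mean difference* (GMD), computed on the change-from-baseline
scale.

The Harrell-Davis estimator of the `q`-th quantile is an L-estimator:
with `n` sorted values `x_(i)`, the weights are increments of a
Beta((n+1)q, (n+1)(1−q)) distribution function,

    w_i = I_{i/n}(a, b) − I_{(i−1)/n}(a, b),   estimate = Σ w_i x_(i),

where `I` is the regularized incomplete beta function. Weighting all
order statistics makes the estimator markedly more efficient than the
sample median for small, skewed samples. We evaluate the weights with
exact `pbeta` calls (no bootstrap approximation); the unit tests check
them against independent numeric integration of the Beta density to
1e-10.

The GMD is the mean absolute difference over all ordered pairs,
`Σ_{i≠j} |x_i − x_j| / (n(n−1))`. We state the denominator explicitly
because "all pairs" is ambiguous about `i = j`; with the `n(n−1)`
convention the statistic is the usual unbiased Gini dispersion and is
zero exactly when all trials agree. It is computed via the
order-statistic identity (O(n log n)) and tested against brute-force
pair enumeration.

Pooling trials across blocks is justified when the per-block medians
agree; `icc_consistency_avg()` quantifies this with the two-way mixed,
consistency, average-measures ICC (Shrout–Fleiss 3,k with k = 2),
`(MS_rows − MS_error)/MS_rows`, with the standard F-based interval.
The consistency form deliberately ignores a fixed block offset
(habituation shifts both blocks equally).

Outliers are flagged by the boxplot rule, `[Q1 − 1.5·IQR, Q3 +
1.5·IQR]`, with type-7 (linear interpolation) quartiles — the common
software convention; variants such as Carling's modification exist,
and we chose the plain Tukey fences because the downstream analysis
only uses flags descriptively. Fences are computed **within each
diagnostic group**, since a heavy-tailed clinical group would
otherwise absorb the comparison group's fence.

## Group comparisons: dominance effects and equivalence

Group differences are expressed as Cliff's delta,
`δ = P(X > Y) − P(X < Y)`, estimated by the mean of the dominance
matrix `d_ij = sign(x_i − y_j)` (ties count zero). Its variance uses
Cliff's consistent estimator built from the row means, column means
and the full matrix:

    s² = [ n2² Σ(d_i· − δ)² + n1² Σ(d_·j − δ)² − ΣΣ(d_ij − δ)² ] /
         [ n1 n2 (n1 − 1)(n2 − 1) ].

When this evaluates to zero at |δ̂| = 1 (complete separation), the
minimum positive substitute `(1 − δ̂² + 1/(n1 n2))/(n1 n2)` is used
and δ̂ is nudged to ±(n1·n2 − 1)/(n1·n2) for inference, following
Cliff's boundary recommendation. Confidence intervals use Cliff's
bounded asymmetric transformation, which keeps the interval inside
[−1, 1] and is asymmetric near the boundaries.

Equivalence is tested with two one-sided tests (TOST) against a
smallest effect of interest of |δ| = 0.33 — the conventional boundary
of a "medium" dominance effect (δ of 0.148, 0.33, 0.474 correspond to
Cohen's d of 0.2, 0.5, 0.8 under normality). Each one-sided p-value is
obtained by **inverting the asymmetric confidence bound**: the p-value
for H0: δ ≥ 0.33 is `1 − Φ(z*)` where `z*` solves
`upper_ci(z*) = 0.33`, available in closed form as the root of a
quadratic in `(z s)²`. We chose the CI-inversion construction over a
plain normal z-statistic on the δ scale because the two differ
materially at small samples (the bounded transform respects the
statistic's range), and because only the inversion form reproduces the
reference Monte-Carlo power values for this design (0.93 at group
sizes 83/59 under a true δ of 0). With this construction "p_equiv <
α" coincides exactly with the 1−2α asymmetric CI lying inside
(−0.33, 0.33), which is why the comparison tables report 90%
intervals alongside α = 0.05 tests.

`mc_power_delta()` estimates the power of this equivalence test by
simulating homoskedastic normal samples whose mean shift corresponds
to the population dominance effect (`Δ = √2·Φ⁻¹((δ+1)/2)·σ`), and
re-estimates the variance within every replicate — it simulates the
full test, not a plug-in approximation.

Categorical group comparisons use the Pearson chi-square without
continuity correction (`N(ad − bc)²` over the margin product, with
`Φ = √(χ²/N)`) and Fisher's exact test by direct hypergeometric
enumeration.

## Rank correlations with equivalence bounds

Associations are Spearman correlations (Pearson on midranks). Tests
use the Fisher-z transform with the rank-correlation standard error
`√((1 + r²/2)/(n − 3))` — the Caruso–Cliff/Bonett–Wright family; the
fixed `√(1.06/(n − 3))` alternative is available via `se_method`. The
default was retained because it reproduces the reference equivalence
powers at all four sample sizes (142, 56, 86, 83) within Monte-Carlo
error, while the fixed-constant variant misses at n = 56. This SE is
mildly conservative below n ≈ 30 (empirical type-I ≈ 0.03–0.04 at
n = 20); the test suite asserts that it is never anticonservative.

Equivalence uses TOST on the atanh scale against ±atanh(0.30).
`mc_power_corr()` draws uncorrelated (or correlated) bivariate
normals and applies the full Spearman + TOST chain. Note the
calibration subtlety: a bivariate normal with Pearson ρ has population
Spearman `(6/π)·asin(ρ/2)`, so the rejection rate equals α at
`ρ = 2·sin(π·bound/6)`, not at `ρ = bound`; the tests use the former.

Differences between correlations use Zou's confidence intervals: each
correlation gets a Fisher-z interval, and the limits combine by the
root-sum-of-squares rule, with the Pearson–Filon covariance term
correcting for overlap in the dependent (shared-variable) case.

## Regression: cumulative probability models

Because thresholds are skewed, covariate effects are modelled
semi-parametrically with a proportional-odds cumulative probability
model (CPM): every distinct outcome value is an ordered category and

    P(Y ≥ y_(j) | X) = logistic(α_j + Xβ),

with strictly decreasing intercepts. Continuous outcomes are **not
binned** — with `n` distinct values the model has `n − 1` intercepts.
The CPM generalizes the Wilcoxon–Mann–Whitney test to multiple
predictors and is invariant to monotone transformation of the outcome
(the tests verify β̂ is bit-identical under `rank(y)` and `log(y)`).

The likelihood is maximized by a damped Newton method with analytic
gradient and Hessian. The intercept block of the Hessian is
tridiagonal (an observation in category `c` touches only `α_{c−1}` and
`α_c`), so each step costs O(J) for the intercepts plus a p×p Schur
complement for the slopes; fits with hundreds of intercepts take
milliseconds. Steps are halved under an Armijo sufficient-increase
rule and rejected if they break intercept monotonicity. Because the
iteration starts at the intercept-only MLE (the empirical exceedance
logits, which are exactly the no-covariate solution) the monotonicity
constraint never binds at convergence, so no reparameterization of the
intercepts is needed. Convergence is declared at a gradient norm below
1e-8 (maximum 100 iterations); extreme coefficients trigger a
complete-separation warning and a flagged fit.

Model-level inference uses the likelihood ratio against the
intercept-only model and Nagelkerke's normalized pseudo-R²,
`(1 − exp(−LR/n)) / (1 − exp(2·LL₀/n))`; coefficient-level inference
uses Wald statistics with adjusted odds ratios `exp(β)`.

### Best-subset selection and the three-step hierarchy

`best_subset_bic()` fits all `2^k` candidate subsets (base covariates
forced in), scores them with `BIC = −2LL + k·log(n)` where `k` counts
intercepts and slopes, and converts BIC differences to weights
`w_m ∝ exp(−ΔBIC/2)` — interpretable as approximate posterior model
probabilities, with evidence ratios and per-predictor inclusion
probabilities (the weight mass of models containing the predictor).
Since the intercept count is fixed for a given outcome, ΔBIC depends
only on slope counts. `n` is the subject count of the analysis sample.

`hierarchical_models()` runs the three-step structure: (1) baseline
covariates — diagnosis (ASD = 1), age, sex (male = 1), counterbalance
order (warm-first = 1), codings chosen so reported rows read
"Diagnosis (ASD)", "Sex (Male)"; (2) baseline plus the BIC-best subset
of candidate predictors; (3) the step-2 model plus the matching GMD.
Step 3 asks whether apparent covariate effects on thresholds survive
adjustment for trial-to-trial variability. Constant or collinear
predictors are dropped with a warning before fitting.

## Missing covariates

Questionnaire and IQ covariates are incomplete in realistic cohorts;
outcomes (thresholds, GMD) never are, and are never imputed.
`pmm_multiple_impute()` implements predictive mean matching with the
standard bootstrap flavor: for each of M = 20 imputations the rows are
resampled, each incomplete variable is regressed on a numeric basis of
all other variables (including the outcome — omitting it would bias
covariate-outcome associations toward zero), and each missing cell
receives the observed value of a random draw from the k = 3 donors
with the nearest predicted means. Imputed values therefore always lie
in the observed support. The regression basis is linear; flexible
additive transformations would be a refinement, but pooled Wald
statistics at these sample sizes are insensitive to it, which the
coverage tests confirm. Degenerate regressions fall back to random
donors with a warning.

Estimates are pooled by Rubin's rules (`T = W̄ + (1 + 1/M)B`) with a
large-sample normal reference. Model selection under imputation is an
open design point (select once vs. per-imputation); we select the
subset minimizing the **across-imputation mean BIC**, which keeps one
model interpretation while letting every completed dataset vote.

## The synthetic cohort generator

`synthetic_config()` + `generate_cohort()` + `generate_trials()`
produce data with the structure the analysis assumes, so the entire
pipeline is testable without participant data. Default parameters
describe the study conditions the package targets: 83 ASD and 59
comparison subjects, about 61% children, male fractions 62/83 and
40/59 per group.

* **Latent thresholds are lognormal** (right-skewed, positive):
  comparison-group warm changes have log-mean `log(1.55)` and log-SD
  0.6, calibrated so group medians and interquartile ranges land near
  the reported descriptives (≈1.9 °C median warm change in the
  clinical group, IQR ≈ [1.2, 2.9]); cool changes share the subject's
  latent factor with a `log(2.18/1.56)` offset.
* **Noise coupling on the log scale**: a subject's trial-noise SD is
  `exp(coupling·log μ + ν)` with coupling 1.0 (proportional noise) and
  `ν ~ N(log(0.45/1.7), 0.6²)`. This is the simplest mechanism that
  reproduces the observed rank correlation between threshold medians
  and GMD (≈0.65–0.7; the accepted band 0.5–0.85 was chosen from a
  simulation sweep) together with an outlier-prone upper tail.
* **Group effects as dominance targets**: the clinical shift is
  specified as a Cliff's delta and converted to a normal shift on the
  log scale via `Δ = √2·Φ⁻¹((δ+1)/2)·σ` (exact because δ is invariant
  to the exp transform). Defaults: 0.17 on thresholds, 0.22 on
  trial-noise SDs; the ν-shift subtracts the part already induced
  through the coupling. Questionnaire instruments get the same
  calibration on their own scales (e.g. social-responsiveness T-score
  δ = 0.971).
* **Covariate effects** (`piq_effect`, `sex_effect`) act additively on
  the log-mean, i.e. multiplicatively on thresholds, with PIQ centered
  at 105.
* **Truncation, not resampling**, clamps trials to the device range
  (0–18 °C change for warm, 0–32 for cool), mirroring the physical
  clamp.
* **Missingness is MCAR** at per-variable rates chosen to match the
  reported per-instrument Ns (e.g. ≈0.22 for the SRS-2 T-score); the
  real mechanism is unknown, and MCAR is the weakest assumption the
  imputation machinery needs.
* The joint distribution of covariates is mostly independent within
  group; real cohorts have covariate correlations (e.g. PIQ with sex)
  the generator does not emulate, so passing tests speak to the
  statistics, not to any particular population structure.

Every generator accepts a seed and is bit-reproducible; trials use
`seed + 1` and missingness a caller-supplied seed so stages can be
regenerated independently.

## Numerical and scale choices

* Monte-Carlo power uses B = 10,000 replicates (MC SE ≤ 0.005); the
  acceptance script recomputes seven power values in ~10 s.
* Calibration tests average empirical deltas over a few seeds so the
  Monte-Carlo error (sd ≈ 0.04 per 400-subject cohort) sits well
  inside the ±0.05 acceptance band.
* The Wald-coverage check uses 1000 CPM fits at n = 300; the null
  rejection-rate check uses 2000 simulated 20+20-subject cohorts
  through the full generate→summarize→test chain.
* Ties: dominance ties contribute 0; Spearman uses midranks; tied
  outcome values share a CPM category.
* Degenerate inputs: constant vectors are errors for correlations,
  flagged for the ICC; empty strata in the comparison table are
  returned with `computed = FALSE` rather than guessed.

## Known limitations

* The TOST construction is asymptotic; below ~15 subjects per group
  its type-I error drifts from nominal (conservative in our checks).
* The CPM assumes proportional odds; no test of that assumption is
  provided.
* PMM with a linear basis can be biased under strongly nonlinear
  covariate relations; MNAR missingness is out of scope.
* The generator does not model reaction-time processes, device
  physics, medication effects, or covariate cross-correlations; the
  ASD-only regression stratum therefore has severity score as its only
  group-specific candidate predictor.
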