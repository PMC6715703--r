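# thermolimits

Robust statistical analysis of method-of-limits detection thresholds,
built for thermal (warm/cool) psychophysics in clinical group
comparisons — for example, contrasting autistic and non-autistic
cohorts where threshold distributions are right-skewed, outlier-prone,
and contaminated by trial-to-trial "perceptual noise".

The package is aimed at researchers who need the full inferential
chain for such data, not just a point estimate:

* **Per-subject summaries** — Harrell-Davis quantile estimator
  (Beta-CDF-weighted order statistics), Gini's mean difference
  (GMD, the mean |xᵢ − xⱼ| over all pairs) as an index of
  intra-individual variability, ICC(3,2) block reliability, and
  within-group boxplot-rule outlier flags.
* **Group comparisons** — Cliff's dominance effect
  δ = P(X>Y) − P(X<Y) with its consistent variance estimator and
  bounded asymmetric confidence interval; equivalence testing by two
  one-sided tests (TOST) against |δ| = 0.33, with one-sided p-values
  obtained by closed-form inversion of the asymmetric CI; Monte-Carlo
  power for equivalence designs; Pearson χ² (no continuity
  correction) and Fisher's exact test for 2×2 tables.
* **Correlations** — Spearman coefficients, Fisher-z tests with the
  rank-correlation SE √((1 + r²/2)/(n − 3)), TOST equivalence at
  |r_s| = 0.30, Monte-Carlo power, and Zou's confidence intervals for
  differences between independent or dependent overlapping
  correlations.
* **Regression** — semi-parametric proportional-odds cumulative
  probability models (CPMs) for continuous outcomes
  (P(Y ≥ yⱼ | X) = logistic(αⱼ + Xβ), one intercept per distinct
  outcome value, damped-Newton fit with a tridiagonal intercept
  Hessian), likelihood-ratio and Wald inference with Nagelkerke R²,
  best-subset selection with BIC weights and inclusion
  probabilities, and the three-step hierarchy (baseline covariates →
  best subset → + GMD).
* **Missing data** — 20-fold multiple imputation by predictive mean
  matching and Rubin's-rules pooling.
* **Synthetic cohorts** — a generator producing lognormal latent
  thresholds with log-scale noise coupling, dominance-calibrated
  group effects, and MCAR missingness, so every stage is testable
  end-to-end without participant data.

## Worked example

Simulate a study-sized cohort (83 + 59 subjects, 10 warm and 10 cool
trials each), summarize it, and compare warm thresholds:

```r
library(thermolimits)

cfg      <- synthetic_config(seed = 7)
subjects <- generate_cohort(cfg)
trials   <- generate_trials(subjects, cfg)
summ     <- summarize_thresholds(trials)
diag     <- subjects$diagnosis[match(summ$subject_id, subjects$id)]

cliffs_delta(summ$warm_threshold[diag == "ASD"],
             summ$warm_threshold[diag == "TD"], conf = 0.90)
#> Cliff's delta = 0.154, 90% CI [-0.011, 0.311], z = 1.555, p = 0.1200

delta_tost(summ$warm_threshold[diag == "ASD"],
           summ$warm_threshold[diag == "TD"])
#> TOST (|bound| = 0.33): p_equiv = 0.0317 (equivalent at alpha = 0.05)
```

The dominance effect (0.154) is small and not significantly different
from zero, while the equivalence test rejects |δ| ≥ 0.33: the groups
are statistically equivalent at the smallest effect size of interest.
Block reliability supports pooling trials across blocks:

```r
icc_consistency_avg(summ$warm_block1, summ$warm_block2)
#> ICC(3,2) = 0.967, 95% CI [0.954, 0.976] (n = 142)
```

How much power does an equivalence design of this size have when the
groups truly do not differ?

```r
mc_power_delta(83, 59, true_delta = 0, bound = 0.33, B = 10000, seed = 1)
#> Monte-Carlo power = 0.925 (B = 10000, MC SE = 0.0026)
```

The three-step CPM hierarchy shows the package's central scientific
point — trial-to-trial variability (GMD), not diagnosis, carries the
explanatory power for thresholds:

```r
dat <- merge(subjects, summ, by.x = "id", by.y = "subject_id")
dat$diagnosis_asd <- as.numeric(dat$diagnosis == "ASD")
dat$sex_male <- as.numeric(dat$sex == "M")
dat$counterbalance_warm_first <- as.numeric(dat$counterbalance == "warm_first")

h <- hierarchical_models(dat$warm_threshold, dat,
  baseline = c("diagnosis_asd", "age", "sex_male",
               "counterbalance_warm_first"),
  candidates = c("viq", "piq", "srs_t"), gmd_col = "warm_gmd")
print(h$stats$step3)
#> Model fit: chi2(5) = 101.11, p = 0.0000, Nagelkerke R2 = 0.509
#>                  predictor   beta    se    aor aor_low aor_high wald_chi2     p
#>              diagnosis_asd -0.135 0.313  0.874   0.473    1.614     0.186 0.666
#>                        age  0.012 0.014  1.012   0.984    1.040     0.677 0.411
#>                   sex_male -0.069 0.327  0.933   0.491    1.772     0.045 0.832
#>  counterbalance_warm_first -0.321 0.299  0.726   0.404    1.303     1.152 0.283
#>                   warm_gmd  2.907 0.338 18.301   9.444   35.465    74.163 0.000
```

Adding GMD at step 3 raises Nagelkerke R² by 0.478 and attenuates the
diagnosis odds ratio toward 1 — higher trial-to-trial variability, not
group membership, predicts higher threshold estimates.

A thin command line lives behind `cli_main()` (subcommands `simulate`,
`summarize`, `compare`, `correlate`, `regress`, `power`); see
`inst/scripts/thermolimits`.

## Package layout

| Path | Contents |
|---|---|
| `R/thresholds.R` | HD quantiles, GMD, ICC, outlier flags |
| `R/effect-sizes.R` | Cliff's delta, TOST, MC power, 2×2 tests |
| `R/correlations.R` | Spearman inference, TOST, Zou intervals |
| `R/cpm.R`, `R/cpm-inference.R` | CPM fitting, LR/Wald, best-subset BIC |
| `R/imputation.R` | PMM multiple imputation, Rubin pooling |
| `R/synthetic-data.R` | cohort/trial generators, table and config IO |
| `R/pipeline.R`, `R/cli.R` | end-to-end comparison/regression tables, CLI |
| `vignettes/robust-threshold-analysis.Rmd` | methods and design rationale |
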