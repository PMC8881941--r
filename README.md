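# metabjnd

Can people consciously feel a change in their own metabolic rate? For
exoskeleton designers this is a live question: state-of-the-art devices
reduce the metabolic cost of walking by ~10–15%, but a benefit the wearer
cannot perceive is unlikely to drive adoption. **metabjnd** implements the
complete statistical pipeline for estimating the Just-Noticeable
Difference (JND) of metabolic rate from sequential forced-choice walking
experiments — and a synthetic-study generator with known ground truth so
the whole chain can be exercised, calibrated and tested without laboratory
data.

The pipeline:

1. **Metabolics** — fit a first-order transient
   `y(t) = y_ss + (y0 − y_ss) e^(−t/τ)` to each two-minute trial's
   breath-by-breath calorimetry, subtract the four-minute standing
   baseline, and pair consecutive trials within a block into comparisons
   with reference-normalized stimulus `x = 100·(B − A)/A` (%).
2. **Psychometrics** — the fixed-lapse logistic
   `Ψ(x) = γ + (1 − λ − γ) / (1 + e^(−β(x − α)))` with `α = 0`,
   `γ = λ = 0.02`, and slope `β` its only free parameter; the JND (the
   change detected with 75% accuracy) is `k/β` with
   `k = ½·ln[((0.75 − γ)(1 − λ − 0.25)) / ((1 − λ − 0.75)(0.25 − γ))]`.
3. **Inference** — per-participant JND posteriors by MCMC (JAGS) under a
   uniform 0–70% prior; posterior-mode point estimates, equal-tailed 95%
   credible intervals, convergence diagnostics, and a brute-force
   grid-integration posterior as an independent correctness oracle.
4. **Model comparison** — pooled (one cohort JND), independent (one per
   participant) and variable-Weber-fraction (two per participant, split at
   the median reference cost) structures scored by WAIC on the elpd scale.
5. **Cohort analysis** — mean/SD/SE, KS normality check,
   fitness-covariate regressions with slope F-tests, a
   perception-probability calculator, and a prior-sensitivity sweep.

## Worked example

```r
library(metabjnd)

study  <- generate_study(study_config(), seed = 1)   # 10 x 11 x 10 design
result <- run_pipeline(
  study = study, seed = 1,
  mcmc        = mcmc_settings(chains = 2, tune = 1000, draws = 2000),
  mcmc_pooled = mcmc_settings(chains = 2, tune = 1000, draws = 2000))
print(result)
```

```
Metabolic-rate perception pipeline
Cohort JND (n = 10): mean 37.5%, SD 16.7%, SE 5.28%, range [10.2, 56.8]
  KS normality: D = 0.203, p = 0.734
  WAIC ranking:
    independent  elpd   -522.64 (se 15.10)  delta 0.00
    variable_wf  elpd   -525.02 (se 15.09)  delta 2.38
    pooled       elpd   -537.01 (se 15.40)  delta 14.36
  P(perceive 9.6% change) = 0.570
```

The cohort here was generated with true JNDs uniform on 6–70%, so the mean
near 38% simply reflects that draw. WAIC correctly selects the independent
model (the generating structure: every participant has their own single
JND), and the comparison bookkeeping gives 9 comparisons per 10-trial
block, 99 per participant. Comparing estimates to the generator's truth
shows the expected pattern — low-JND participants are recovered tightly,
while high-JND participants (whose psychometric curve the ±stimulus range
barely bends) carry flat, right-skewed posteriors and less accurate modes:

```r
data.frame(true      = round(study$truth$true_jnd, 1),
           estimated = round(unname(point_estimates(result$fits$independent)), 1))
#>    true estimated
#> 1  23.0      29.6
#> 5  11.8      14.9
#> 7   7.8      10.2
#> 10 68.7      55.4   # broad posterior: 95% CI [34.4, 68.8] reaches the prior bound
```

The headline calculator evaluates the cohort-average curve at any change:
for a cohort-mean JND of 22.7%, a 9.6% rate reduction — the typical benefit
of a modern exoskeleton — is perceived with probability

```r
perceive_probability(22.7, 9.6)
#> [1] 0.6149501
```

i.e. barely above chance, while by construction
`perceive_probability(22.7, 22.7)` is exactly 0.75.

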