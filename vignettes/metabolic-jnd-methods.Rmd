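---
title: "Estimating the just-noticeable difference of metabolic rate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the just-noticeable difference of metabolic rate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Lower-limb exoskeletons are evaluated chiefly by how much they reduce the
metabolic cost of walking, yet a benefit a wearer cannot feel is unlikely to
drive adoption. **metabjnd** implements the full analysis chain for
quantifying how large a change in one's own metabolic rate must be before it
is consciously perceivable — the Just-Noticeable Difference (JND), defined
as the percent change detected with 75% accuracy in a forced-choice task.

The experimental design the package models is sequential: a participant
walks in blocks of ten two-minute trials, each trial imposing a different
metabolic rate through randomized exoskeleton assistance. After every trial
but the first of a block, the participant answers whether the current
exertion feels higher than the previous one. Ten trials therefore yield
nine comparisons per block; with roughly eleven blocks, each participant
contributes on the order of one hundred binary responses.

## The psychometric model

Each comparison is summarized by the reference-normalized stimulus
$x = 100\,(B - A)/A$, the percent change of the comparison trial's net
metabolic rate $B$ relative to the preceding reference $A$. Working in
percent units makes the JND a Weber fraction: under the constant-Weber-
fraction assumption, a single curve describes discrimination across the
whole range of absolute rates tested.

The probability of responding "higher" is the fixed-lapse logistic

$$\Psi(x) = \gamma + \frac{1 - \lambda - \gamma}{1 + e^{-\beta (x - \alpha)}},$$

with the threshold $\alpha = 0$ (no response bias), the lapse rate
$\lambda = 0.02$ and false-positive rate $\gamma = 0.02$ fixed at the
value conventional for discrimination tasks, and the slope $\beta$ the
single free parameter. The JND follows from the quartile construction —
half the distance between $\Psi^{-1}(0.75)$ and $\Psi^{-1}(0.25)$ — which
for this parameterization collapses to

$$\mathrm{JND} = k/\beta, \qquad
k = \tfrac{1}{2}\ln\!\left[\frac{(0.75-\gamma)(1-\lambda-0.25)}
{(1-\lambda-0.75)(0.25-\gamma)}\right],$$

so $k$ depends only on the fixed rates ($k = \ln 3 \approx 1.0986$ when
$\gamma = \lambda = 0$, and $\approx 1.1550$ at the defaults).
`jnd_from_quartiles()` retains the numerical inversion (bisection,
tolerance $10^{-10}$, safe because $\Psi$ is strictly monotone) purely as a
cross-check of the closed form.

## Bayesian estimation

`fit_independent()` places a uniform prior on the JND itself — support 0
to 70%, spanning near-perfect perception up to just below the ~100%
energetic change of breaking into a run — and samples the posterior by
MCMC (JAGS), with the slope set to $k/\mathrm{JND}$ inside the Bernoulli
likelihood. Design choices worth making explicit:

* **Sampling the JND directly** (rather than $\beta$) keeps the prior
  exactly as stated and makes the posterior directly interpretable.
* **Prior floor.** The lower bound is lifted to 0.1% so $\beta$ stays
  finite; this is far below any plausible human threshold and has no
  practical effect on the posterior.
* **Point estimate.** With a uniform prior, the posterior mode is the
  maximum-likelihood estimate on the support. `posterior_mode()` extracts
  it as the peak of a Gaussian KDE (Silverman bandwidth, 1000-point grid
  over the prior support). A near-flat density — max/mean ratio below 1.1,
  as produced by a chance-level responder — is flagged as non-identified
  rather than silently reported.
* **Credible intervals** are equal-tailed (2.5th/97.5th percentiles):
  reproducible without density estimation, at the cost of being slightly
  conservative for the right-skewed posteriors of high-JND participants.
* **Diagnostics.** Every fit records split-half $\widehat{R}$ and effective
  sample size; fits exceeding $\widehat{R} = 1.05$ warn rather than fail,
  leaving the decision with the analyst.
* **Default settings** are 4 chains with 8000 tuning iterations and 4000
  retained draws (2000/2000 for the pooled model, whose concatenated
  response set is an order of magnitude larger). The 1-D bounded posterior
  mixes fast, so simulation studies in the test suite use 2 chains and a
  few hundred tuning iterations without loss of calibration.

Because the posterior is one-dimensional on a bounded interval, it can also
be computed by brute force: `grid_posterior()` evaluates the likelihood on
a 2000-point grid and normalizes by trapezoidal quadrature. This
deterministic route is the package's independent oracle — the test suite
requires MCMC and grid moments to agree within 0.5 (mean) and 0.3 (SD)
percentage points — and is never used as the estimator itself.

## Model structures and WAIC

Three structures are compared on the identical response set:

* **Pooled** — one JND for everyone (a single cohort-wide Weber fraction);
* **Independent** — one JND per participant;
* **Variable WF** — two JNDs per participant, split at that participant's
  median absolute reference rate (W/kg), allowing the Weber fraction to
  depend on the magnitude of the reference cost.

`compute_waic()` scores each on the expected-log-pointwise-predictive-
density scale (higher is better), penalizing by the summed posterior
variance of the pointwise log-likelihoods, with a log-sum-exp-stable
reduction; `compare_models()` reports differences to the top model with
standard errors from the paired pointwise contributions. The pointwise
unit is one binary response throughout, which is what makes the three
structures comparable.

## The synthetic-study generator

`generate_study()` produces complete studies with known ground truth so
every downstream stage is testable without laboratory data. Its defaults
are the study conditions, not tuning knobs:

| quantity | default | rationale |
|---|---|---|
| participants × blocks × trials | 10 × 11 × 10 | the experimental design |
| net rate range | 1.5–6.6 W/kg | range of reference costs the protocol imposed |
| transient time constant $\tau$ | 42 s | cardiopulmonary response time |
| trial / standing duration | 120 s / 240 s | protocol timing |
| breath interval | 4 ± 1 s | physiologically plausible; ~30 breaths per trial |
| breath noise SD | 8% of local steady state | yields a few-percent steady-state estimation error over two minutes, consistent with published estimates for this trial length |
| true JNDs | uniform 6–70% | spans the sharply identified and the nearly flat posterior regimes |
| generating lapse | 0.02 | equals the analysis's fixed $\lambda$; overridable to study misspecification |

Two components are deliberate surrogates. The torque-profile parameters
(onset uniform on 25–50% of stride, magnitude uniform on 15–25 A, duration
uniform up to 60% with a floor of 10%, raised to 20% for onsets before 30%)
follow the experimental randomization, but the map from profile to net
metabolic rate is unknown physiology; the package uses a fixed
positive-coefficient quadratic in the normalized parameters, rescaled
affinely into the configured rate range. It is deterministic per profile,
spans the full range, and produces realistic between-trial variation —
nothing downstream depends on its biomechanical realism. Likewise breath
noise is additive i.i.d. Gaussian; real calorimetry has autocorrelated,
occasionally artifactual breaths. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the assumed noise
model, not that real-world deviations from it are harmless.

`simulate_comparisons()` is the lightweight companion used by the
inference-focused simulation studies (parameter recovery, WAIC model
recovery): it pairs true rates into comparisons directly, skipping breath
synthesis, with stimuli spanning roughly −40% to +60% — the informative
region of the psychometric curve that the protocol was designed to sample.

## Metabolics processing

Per-trial steady-state rates come from fitting
$y(t) = y_{ss} + (y_0 - y_{ss})e^{-t/\tau}$ to each trial's breath series
(Levenberg–Marquardt with all three parameters free, $\tau$ bounded to
10–120 s and initialized at 42 s). Leaving $y_0$ free subsumes any
convention about what the first trial of a block relaxes from. On a
degenerate series the fit falls back to the mean of the final 60 s. The
standing baseline — the mean over a four-minute quiet-standing record — is
subtracted to give net rates, and normalization uses these **net** rates
for both reference and comparison, isolating the energetics of the walking
condition itself. Pairs whose reference is non-positive (possible under
noise) are dropped with a count rather than an error, since a ratio
statistic is undefined there; comparisons never cross block boundaries.

## Cohort analysis

`summarize_cohort()` reports mean, SD (n−1), SE = SD/√n and range of the
per-participant estimates; SE is always recomputed from the SD rather than
carried separately. `ks_normality()` follows the stated procedure — a
one-sample Kolmogorov–Smirnov test against a normal with sample-estimated
parameters — and its output carries the caveat that estimated parameters
make the classical p-value approximate (the Lilliefors correction is not
applied, by fidelity to the procedure). `fitness_regression()` is ordinary
least squares of JND on one covariate with the slope F-test (identical to
the overall F with one predictor) and a 95% confidence band for the mean
response. No multiplicity correction is applied across covariates.
`perceive_probability()` evaluates the cohort-average curve at a given
percent change; by construction it returns 0.5 at zero change and 0.75 at
one JND. `prior_sensitivity()` refits the independent model under
alternative prior upper bounds with a shared seed, so only the prior
varies.

## Problem sizes and reproducibility

The simulation studies in the test suite use the study-scale designs: 99
comparisons per participant, 200 simulated participants for
coverage/bias calibration, 20 + 20 cohort replicates for model-structure
recovery, and 200 replicates for transient-estimation accuracy, with
2-chain reduced MCMC settings for the bulk runs and 4 × 4000 draws where
posterior moments are compared to the grid oracle at tenth-of-a-point
precision. All randomness is seed-derived: `generate_study()` restores the
caller's RNG state, and every fit derives per-participant, per-chain seeds
deterministically from its base seed, so identical inputs give identical
draws.

## Known limitations

* The real stimulus spacing is not under experimental control (energetics
  are manipulated only indirectly), so real posteriors are wider than
  synthetic ones at equal trial counts.
* High-JND participants produce right-skewed posteriors whose upper
  credible limit can sit at the prior bound; their point estimates are
  bounded below better than above, and the flatness flag should be heeded.
* The KS normality check at n = 10 has little power, and the fitness
  regressions at n = 10 are exploratory; the type-I-error simulation in
  the test suite confirms the nominal 5% level, not power.
* Gross-rate normalization (not subtracting the standing baseline) is
  available by passing a zero baseline, but net normalization is the
  supported default.
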