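#' Cohort summary of JND point estimates
#'
#' @param jnd Vector of per-participant JND point estimates, percent.
#' @return List of class `cohort_summary`: `n`, `mean_jnd`, `sd_jnd`
#'   (n-1 denominator), `se_jnd` (= sd / sqrt(n)), `min_jnd`, `max_jnd`.
#' @export
summarize_cohort <- function(jnd) {
  if (length(jnd) < 2) stop("need at least 2 participants")
  if (!all(is.finite(jnd))) stop("non-finite JND estimates")
  structure(list(n = length(jnd),
                 mean_jnd = mean(jnd),
                 sd_jnd = stats::sd(jnd),
                 se_jnd = stats::sd(jnd) / sqrt(length(jnd)),
                 min_jnd = min(jnd), max_jnd = max(jnd)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort JND (n = %d): mean %.1f%%, SD %.1f%%, SE %.2f%%, range [%.1f, %.1f]\n",
              x$n, x$mean_jnd, x$sd_jnd, x$se_jnd, x$min_jnd, x$max_jnd))
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests the per-participant JND estimates against a normal reference whose
#' mean and SD are estimated from the same sample. Because the reference
#' parameters are estimated, the classical KS p-value is conservative
#' (the Lilliefors correction would be needed for exact critical values);
#' the returned record carries this caveat.
#'
#' @param jnd Vector of JND estimates (percent), length >= 5 with positive SD.
#' @return List: `statistic`, `p_value`, `note`.
#' @export
ks_normality <- function(jnd) {
  if (length(jnd) < 5) stop("need at least 5 estimates")
  s <- stats::sd(jnd)
  if (s == 0) stop("zero sample SD: normality test undefined")
  kt <- suppressWarnings(stats::ks.test(jnd, "pnorm", mean(jnd), s))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       note = paste("reference parameters estimated from the sample;",
                    "p-value is approximate (no Lilliefors correction)"))
}

#' Probability that a rate change is perceived
#'
#' Evaluates the cohort-average psychometric curve at a given percent change
#' in metabolic rate: the probability that an average observer with the
#' given mean JND judges the change correctly, using the fixed-lapse
#' logistic with `beta = k / mean_jnd` and `alpha = 0`. By construction it
#' returns 0.5 at zero change (a coin flip) and 0.75 at a change equal to
#' the JND.
#'
#' @param mean_jnd Cohort mean JND, percent (> 0).
#' @param delta Percent change in metabolic rate to evaluate.
#' @param gamma,lambda Fixed psychometric constants.
#' @return Probability in (gamma, 1 - lambda).
#' @examples
#' perceive_probability(22.7, 9.6)   # ~0.61
#' @export
perceive_probability <- function(mean_jnd, delta, gamma = 0.02, lambda = 0.02) {
  if (mean_jnd <= 0) stop("`mean_jnd` must be positive")
  m <- psychometric_model(jnd = mean_jnd, gamma = gamma, lambda = lambda)
  psychometric_prob(delta, m)
}

#' Simple regression of JND on a fitness covariate
#'
#' Ordinary least squares of the JND estimates on one covariate (e.g. weekly
#' endurance hours, athletic years, BMI), with the overall F-test — which,
#' with a single predictor, is exactly the test of the slope — and a 95%
#' confidence band for the mean response over the covariate range.
#'
#' @param jnd Per-participant JND estimates, percent.
#' @param covariate Covariate values, same length, non-degenerate.
#' @param n_band Number of points in the confidence band grid.
#' @return List: `slope`, `intercept`, `F_statistic`, `p_value`, and `band`
#'   (data frame `covariate`, `fit`, `lower`, `upper`).
#' @export
fitness_regression <- function(jnd, covariate, n_band = 100) {
  if (length(jnd) != length(covariate)) stop("length mismatch")
  if (length(jnd) < 3) stop("need at least 3 observations")
  if (stats::sd(covariate) == 0) stop("degenerate covariate (zero variance)")
  fit <- stats::lm(jnd ~ covariate)
  sm <- summary(fit)
  grid <- data.frame(covariate = seq(min(covariate), max(covariate),
                                     length.out = n_band))
  ci <- stats::predict(fit, newdata = grid, interval = "confidence",
                       level = 0.95)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F_statistic = unname(sm$fstatistic["value"]),
       p_value = unname(stats::pf(sm$fstatistic["value"],
                                  sm$fstatistic["numdf"],
                                  sm$fstatistic["dendf"], lower.tail = FALSE)),
       band = data.frame(covariate = grid$covariate, fit = ci[, "fit"],
                         lower = ci[, "lwr"], upper = ci[, "upr"]))
}

#' Sensitivity of the cohort mean JND to the prior's upper bound
#'
#' Refits the independent model for every participant under a sequence of
#' uniform priors differing in their upper bound, and reports the cohort
#' mean of the posterior-mode estimates for each, plus the shift relative to
#' the default bound. Informative data should make the cohort mean nearly
#' invariant; participants whose JND sits near a bound get clipped by
#' tighter priors.
#'
#' @param comparisons Comparisons data frame for the cohort.
#' @param upper_bounds Vector of prior upper bounds (percent) to sweep.
#' @param reference_bound The bound treated as the default when reporting
#'   shifts (must be among `upper_bounds`).
#' @param lower Prior lower bound.
#' @param mcmc An [mcmc_settings()].
#' @param seed Base seed (shared across bounds so only the prior varies).
#' @param ... Passed to [fit_independent()].
#' @return Data frame: `upper_bound`, `mean_jnd`, `shift_vs_reference`.
#' @export
prior_sensitivity <- function(comparisons,
                              upper_bounds = c(60, 70, 80),
                              reference_bound = 70, lower = 0,
                              mcmc = mcmc_settings(), seed = 1, ...) {
  if (!reference_bound %in% upper_bounds) {
    upper_bounds <- sort(c(upper_bounds, reference_bound))
  }
  means <- vapply(upper_bounds, function(ub) {
    fit <- fit_independent(comparisons, prior = jnd_prior(lower, ub),
                           mcmc = mcmc, seed = seed, ...)
    mean(point_estimates(fit))
  }, numeric(1))
  ref <- means[match(reference_bound, upper_bounds)]
  data.frame(upper_bound = upper_bounds, mean_jnd = means,
             shift_vs_reference = means - ref)
}
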