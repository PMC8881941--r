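#' Uniform prior on the JND
#'
#' The analysis places a uniform prior on the JND itself (not on the slope).
#' The default support 0-70% spans plausible human perceptual ability, from
#' near-perfect discrimination up to just below the ~100% energetic change of
#' switching from walking to running. A small floor (default 0.1%) keeps the
#' slope `beta = k / JND` finite at the lower edge; it is far below any
#' plausible human threshold.
#'
#' @param lower,upper Prior bounds in percent.
#' @param floor Numerical floor applied to `lower`.
#' @return A list of class `jnd_prior`.
#' @export
jnd_prior <- function(lower = 0, upper = 70, floor = 0.1) {
  if (lower < 0 || upper <= lower) stop("need 0 <= lower < upper")
  structure(list(lower = lower, upper = upper, floor = floor,
                 lower_eff = max(lower, floor), shape = "uniform"),
            class = "jnd_prior")
}

#' MCMC settings
#'
#' Defaults follow the reference analysis: 4 chains, 8000 tuning iterations
#' and 4000 retained draws per chain for the independent and variable-WF
#' models. The pooled model conventionally uses 2000/2000
#' (see [fit_pooled()]). Tuning iterations are split between sampler
#' adaptation (up to 1000) and burn-in.
#'
#' @param chains Number of chains.
#' @param tune Tuning (adaptation + burn-in) iterations per chain.
#' @param draws Retained posterior draws per chain.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4, tune = 8000, draws = 4000) {
  stopifnot(chains >= 1, tune >= 100, draws >= 100)
  structure(list(chains = as.integer(chains), tune = as.integer(tune),
                 draws = as.integer(draws)),
            class = "mcmc_settings")
}

# JAGS model: uniform prior on the JND, fixed-lapse logistic likelihood.
.jnd_model_string <- "
model {
  jnd ~ dunif(lo, hi)
  for (i in 1:n) {
    p[i] <- gamma + (1 - lambda - gamma) / (1 + exp(-(kk / jnd) * x[i]))
    r[i] ~ dbern(p[i])
  }
}
"

# Split-half potential-scale-reduction statistic on an iterations x chains
# matrix of draws.
split_rhat <- function(draws_mat) {
  n <- nrow(draws_mat)
  half <- floor(n / 2)
  pieces <- cbind(draws_mat[seq_len(half), , drop = FALSE],
                  draws_mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(pieces)
  if (m < 2 || half < 2) return(NA_real_)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Core sampler: one JND under a uniform prior, Bernoulli logistic likelihood.
# Returns pooled draws plus per-chain matrix and convergence diagnostics.
fit_jnd_mcmc <- function(x, response, prior = jnd_prior(),
                         mcmc = mcmc_settings(), seed = 1,
                         gamma = 0.02, lambda = 0.02) {
  if (length(x) == 0) stop("no comparisons to fit")
  if (length(x) != length(response)) stop("`x` and `response` lengths differ")
  if (!all(response %in% c(0, 1))) stop("responses must be 0/1")
  stopifnot(inherits(prior, "jnd_prior"), inherits(mcmc, "mcmc_settings"))

  k <- scale_constant_k(gamma, lambda)
  data <- list(n = length(x), x = as.numeric(x), r = as.integer(response),
               lo = prior$lower_eff, hi = prior$upper,
               gamma = gamma, lambda = lambda, kk = k)
  # overdispersed deterministic inits: spread across the prior support
  qs <- (seq_len(mcmc$chains) - 0.5) / mcmc$chains
  inits <- lapply(seq_len(mcmc$chains), function(c) {
    list(jnd = prior$lower_eff + qs[c] * (prior$upper - prior$lower_eff),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(seed) * 97 + c) %% 2147483646) + 1L)
  })
  n_adapt <- min(mcmc$tune, 1000L)
  n_burn <- mcmc$tune - n_adapt
  jm <- rjags::jags.model(textConnection(.jnd_model_string), data = data,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) stats::update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "jnd", n.iter = mcmc$draws,
                              progress.bar = "none")
  draws_mat <- vapply(samp, function(ch) as.numeric(ch[, "jnd"]),
                      numeric(mcmc$draws))
  if (mcmc$chains == 1) draws_mat <- matrix(draws_mat, ncol = 1)
  list(draws = as.numeric(draws_mat),
       draws_matrix = draws_mat,
       rhat = split_rhat(draws_mat),
       ess = tryCatch(sum(coda::effectiveSize(samp)), error = function(e) NA_real_),
       n_obs = length(x), seed = as.integer(seed))
}

#' Posterior mode of JND draws
#'
#' The point estimate of the analysis: with a uniform prior the posterior
#' mode is the maximum-likelihood estimate on the prior support. It is
#' extracted as the peak of a Gaussian kernel-density estimate (Silverman's
#' bandwidth) evaluated on a 1000-point grid over the support. A near-flat
#' density — a non-identified participant, e.g. one responding at chance —
#' is flagged via the `flat` attribute.
#'
#' @param draws JND posterior draws, percent; at least 100.
#' @param support Length-2 support over which to evaluate the density
#'   (typically the prior bounds).
#' @param flat_ratio Densities whose max/mean ratio falls below this are
#'   flagged as flat.
#' @return The mode in percent, with logical attribute `flat`.
#' @export
posterior_mode <- function(draws, support = c(0.1, 70), flat_ratio = 1.1) {
  if (length(draws) < 100) stop("need at least 100 draws")
  if (stats::sd(draws) == 0) {
    return(structure(draws[1], flat = FALSE))
  }
  d <- stats::density(draws, bw = "nrd0", from = support[1], to = support[2],
                      n = 1000)
  mode <- d$x[which.max(d$y)]
  structure(mode, flat = max(d$y) / mean(d$y) < flat_ratio)
}

#' Equal-tailed credible interval
#'
#' @param draws Posterior draws; at least 100.
#' @param level Credibility level in (0, 1); default 0.95 gives the 2.5th
#'   and 97.5th percentiles.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) < 100) stop("need at least 100 draws")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lower = q[1], upper = q[2])
}

# Wrap raw MCMC output into a summarized posterior object.
summarize_posterior <- function(raw, prior) {
  mode <- posterior_mode(raw$draws, support = c(prior$lower_eff, prior$upper))
  structure(
    list(draws = raw$draws, draws_matrix = raw$draws_matrix,
         point_estimate = as.numeric(mode), flat = attr(mode, "flat"),
         ci95 = credible_interval(raw$draws, 0.95),
         diagnostics = list(chains = ncol(raw$draws_matrix), rhat = raw$rhat,
                            ess = raw$ess, n_obs = raw$n_obs),
         prior = prior, seed = raw$seed),
    class = "jnd_posterior"
  )
}

#' @export
print.jnd_posterior <- function(x, ...) {
  cat(sprintf("JND posterior: mode %.2f%% [95%% CI %.2f, %.2f]%s\n",
              x$point_estimate, x$ci95["lower"], x$ci95["upper"],
              if (isTRUE(x$flat)) "  (flat posterior: poorly identified)" else ""))
  cat(sprintf("  %d draws over %d chains, split-Rhat %.3f, n_obs %d\n",
              length(x$draws), x$diagnostics$chains, x$diagnostics$rhat,
              x$diagnostics$n_obs))
  invisible(x)
}

check_comparisons <- function(comparisons) {
  req <- c("participant", "x_percent", "response", "A_w_kg")
  miss <- setdiff(req, names(comparisons))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(comparisons) == 0) stop("no comparisons supplied")
  invisible(comparisons)
}

# deterministic per-(participant, model) sub-seed below 2^31
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 20011 + as.numeric(offset)) %% 2147483647)
}

#' Fit the independent-JND model
#'
#' One JND per participant, each with its own uniform prior and fit on that
#' participant's comparisons only. This is the model structure selected by
#' WAIC in the reference analysis.
#'
#' @param comparisons Comparisons data frame (see [build_comparisons()]).
#' @param prior A [jnd_prior()].
#' @param mcmc An [mcmc_settings()]; defaults to 4 chains, 8000 tune,
#'   4000 draws.
#' @param seed Integer base seed; per-participant chain seeds are derived
#'   from it deterministically.
#' @param gamma,lambda Fixed psychometric constants.
#' @param check_rhat Warn if any split-Rhat exceeds this (set `Inf` to
#'   disable).
#' @return A `jnd_fit` object: model label, named list of `jnd_posterior`
#'   objects (one per participant), and the settings used.
#' @export
fit_independent <- function(comparisons, prior = jnd_prior(),
                            mcmc = mcmc_settings(), seed = 1,
                            gamma = 0.02, lambda = 0.02, check_rhat = 1.05) {
  check_comparisons(comparisons)
  ids <- sort(unique(comparisons$participant))
  posteriors <- lapply(seq_along(ids), function(i) {
    ci <- comparisons[comparisons$participant == ids[i], ]
    raw <- fit_jnd_mcmc(ci$x_percent, ci$response, prior, mcmc,
                        seed = sub_seed(seed, i), gamma = gamma, lambda = lambda)
    summarize_posterior(raw, prior)
  })
  names(posteriors) <- as.character(ids)
  fit <- structure(list(model = "independent", posteriors = posteriors,
                        prior = prior, mcmc = mcmc, seed = as.integer(seed),
                        gamma = gamma, lambda = lambda),
                   class = "jnd_fit")
  warn_rhat(fit, check_rhat)
  fit
}

#' Fit the pooled model
#'
#' A single JND shared by the whole cohort, fit on the concatenated response
#' set. Following the reference analysis, the default MCMC settings are
#' lighter (2000 tuning iterations, 2000 draws) because the pooled response
#' set is large.
#'
#' @inheritParams fit_independent
#' @return A `jnd_fit` with one posterior named `"pooled"`.
#' @export
fit_pooled <- function(comparisons, prior = jnd_prior(),
                       mcmc = mcmc_settings(chains = 4, tune = 2000,
                                            draws = 2000),
                       seed = 1, gamma = 0.02, lambda = 0.02,
                       check_rhat = 1.05) {
  check_comparisons(comparisons)
  raw <- fit_jnd_mcmc(comparisons$x_percent, comparisons$response, prior, mcmc,
                      seed = sub_seed(seed, 0L), gamma = gamma, lambda = lambda)
  fit <- structure(list(model = "pooled",
                        posteriors = list(pooled = summarize_posterior(raw, prior)),
                        prior = prior, mcmc = mcmc, seed = as.integer(seed),
                        gamma = gamma, lambda = lambda),
                   class = "jnd_fit")
  warn_rhat(fit, check_rhat)
  fit
}

#' Fit the variable-Weber-fraction model
#'
#' Two JNDs per participant: comparisons are split at the participant's
#' median absolute reference rate (W/kg), and separate JNDs are fit to the
#' lower-reference and upper-reference halves. A better WAIC score for this
#' model than for the independent model would indicate a Weber fraction that
#' varies with the absolute magnitude of the reference cost.
#'
#' @inheritParams fit_independent
#' @return A `jnd_fit`; `posteriors` maps each participant to a list with
#'   elements `low`, `high` (both `jnd_posterior`) and `split` (W/kg).
#' @export
fit_variable_wf <- function(comparisons, prior = jnd_prior(),
                            mcmc = mcmc_settings(), seed = 1,
                            gamma = 0.02, lambda = 0.02, check_rhat = 1.05) {
  check_comparisons(comparisons)
  ids <- sort(unique(comparisons$participant))
  posteriors <- lapply(seq_along(ids), function(i) {
    ci <- comparisons[comparisons$participant == ids[i], ]
    refs <- abs(ci$A_w_kg)
    split_val <- stats::median(refs)
    low_idx <- refs <= split_val
    if (all(low_idx) || !any(low_idx)) {
      stop("cannot split participant ", ids[i],
           ": all reference magnitudes identical")
    }
    fit_half <- function(sel, off) {
      raw <- fit_jnd_mcmc(ci$x_percent[sel], ci$response[sel], prior, mcmc,
                          seed = sub_seed(seed, 2L * i + off),
                          gamma = gamma, lambda = lambda)
      summarize_posterior(raw, prior)
    }
    list(low = fit_half(low_idx, 0L), high = fit_half(!low_idx, 1L),
         split = split_val)
  })
  names(posteriors) <- as.character(ids)
  fit <- structure(list(model = "variable_wf", posteriors = posteriors,
                        prior = prior, mcmc = mcmc, seed = as.integer(seed),
                        gamma = gamma, lambda = lambda),
                   class = "jnd_fit")
  warn_rhat(fit, check_rhat)
  fit
}

# collect every jnd_posterior inside a fit, flattening variable_wf halves
collect_posteriors <- function(fit) {
  if (fit$model == "variable_wf") {
    out <- list()
    for (id in names(fit$posteriors)) {
      out[[paste0(id, ":low")]] <- fit$posteriors[[id]]$low
      out[[paste0(id, ":high")]] <- fit$posteriors[[id]]$high
    }
    out
  } else {
    fit$posteriors
  }
}

warn_rhat <- function(fit, threshold) {
  if (!is.finite(threshold)) return(invisible(fit))
  rhats <- vapply(collect_posteriors(fit),
                  function(p) p$diagnostics$rhat, numeric(1))
  bad <- rhats[!is.na(rhats) & rhats > threshold]
  if (length(bad)) {
    warning("split-Rhat above ", threshold, " for: ",
            paste(names(bad), collapse = ", "),
            " (max ", sprintf("%.3f", max(bad)), "); inspect convergence")
  }
  invisible(fit)
}

#' @export
print.jnd_fit <- function(x, ...) {
  cat(sprintf("JND fit, %s model (%d chains, %d tune, %d draws, seed %d)\n",
              x$model, x$mcmc$chains, x$mcmc$tune, x$mcmc$draws, x$seed))
  ps <- collect_posteriors(x)
  est <- vapply(ps, function(p) p$point_estimate, numeric(1))
  for (nm in names(est)) {
    ci <- ps[[nm]]$ci95
    cat(sprintf("  %-10s mode %6.2f%%  [%.2f, %.2f]\n", nm, est[nm],
                ci["lower"], ci["upper"]))
  }
  invisible(x)
}

#' Point estimates from a fit
#'
#' @param fit A `jnd_fit`.
#' @return Named numeric vector of posterior-mode JNDs (percent).
#' @export
point_estimates <- function(fit) {
  stopifnot(inherits(fit, "jnd_fit"))
  vapply(collect_posteriors(fit), function(p) p$point_estimate, numeric(1))
}

#' Brute-force grid posterior (test oracle)
#'
#' Computes the normalized posterior density of a single JND by direct 1-D
#' quadrature: density proportional to `exp(log-likelihood) * prior` on an
#' equally spaced grid over the prior support, normalized by the trapezoidal
#' rule to integrate to one. With zero comparisons it returns the prior.
#' This deterministic route is the independent correctness check for the
#' MCMC sampler.
#'
#' @param x,response Comparison stimuli (percent) and 0/1 responses.
#' @param prior A [jnd_prior()].
#' @param n_grid Number of grid points (default 2000).
#' @param gamma,lambda Fixed psychometric constants.
#' @return A data frame of class `jnd_grid` with columns `jnd`, `density`;
#'   attributes `mean`, `sd` hold quadrature-based posterior moments.
#' @export
grid_posterior <- function(x, response, prior = jnd_prior(), n_grid = 2000,
                           gamma = 0.02, lambda = 0.02) {
  stopifnot(inherits(prior, "jnd_prior"))
  grid <- seq(prior$lower_eff, prior$upper, length.out = n_grid)
  if (length(x) == 0) {
    log_dens <- rep(0, n_grid)
  } else {
    if (!all(response %in% c(0, 1))) stop("responses must be 0/1")
    log_dens <- vapply(grid, function(j)
      response_log_likelihood(x, response, j, gamma, lambda), numeric(1))
  }
  log_dens <- log_dens - max(log_dens)   # uniform prior: constant, absorbed
  dens <- exp(log_dens)
  h <- diff(grid[1:2])
  z <- h * (sum(dens) - (dens[1] + dens[n_grid]) / 2)
  dens <- dens / z
  mu <- h * sum(grid * dens) - h * (grid[1] * dens[1] + grid[n_grid] * dens[n_grid]) / 2
  m2 <- h * sum(grid^2 * dens) - h * (grid[1]^2 * dens[1] + grid[n_grid]^2 * dens[n_grid]) / 2
  structure(data.frame(jnd = grid, density = dens),
            mean = mu, sd = sqrt(max(m2 - mu^2, 0)),
            class = c("jnd_grid", "data.frame"))
}

#' Pointwise log-likelihood matrix for WAIC
#'
#' Evaluates the Bernoulli log-likelihood of every response under every
#' posterior draw of the relevant JND, producing the draws x responses
#' matrix WAIC needs. Rows are posterior draws (aligned across participants
#' by draw index; chains concatenated), columns are responses in the row
#' order of `comparisons`. For the pooled model the single JND applies to
#' all responses; for the variable-WF model each response uses the draws of
#' the half its reference magnitude falls in.
#'
#' @param fit A `jnd_fit`.
#' @param comparisons The same comparisons the fit was run on.
#' @return Numeric matrix, `min draws` x `nrow(comparisons)`.
#' @export
pointwise_loglik <- function(fit, comparisons) {
  stopifnot(inherits(fit, "jnd_fit"))
  check_comparisons(comparisons)
  ps <- collect_posteriors(fit)
  S <- min(vapply(ps, function(p) length(p$draws), integer(1)))
  n <- nrow(comparisons)
  ll <- matrix(NA_real_, S, n)
  k <- scale_constant_k(fit$gamma, fit$lambda)

  fill <- function(draws, idx) {
    beta <- k / draws[seq_len(S)]
    eta <- outer(beta, comparisons$x_percent[idx])     # S x n_idx
    p <- fit$gamma + (1 - fit$lambda - fit$gamma) / (1 + exp(-eta))
    r <- comparisons$response[idx]
    block <- log(p)
    if (any(r == 0)) block[, r == 0] <- log1p(-p[, r == 0, drop = FALSE])
    ll[, idx] <<- block
  }

  if (fit$model == "pooled") {
    fill(fit$posteriors$pooled$draws, seq_len(n))
  } else if (fit$model == "independent") {
    for (id in names(fit$posteriors)) {
      idx <- which(as.character(comparisons$participant) == id)
      fill(fit$posteriors[[id]]$draws, idx)
    }
  } else {
    for (id in names(fit$posteriors)) {
      pp <- fit$posteriors[[id]]
      pidx <- which(as.character(comparisons$participant) == id)
      refs <- abs(comparisons$A_w_kg[pidx])
      low <- refs <= pp$split
      if (any(low)) fill(pp$low$draws, pidx[low])
      if (any(!low)) fill(pp$high$draws, pidx[!low])
    }
  }
  if (anyNA(ll)) stop("internal error: unfilled pointwise cells")
  ll
}

#' Watanabe-Akaike information criterion
#'
#' Computes WAIC on the expected-log-pointwise-predictive-density (elpd)
#' scale, where higher is better: per response,
#' `elpd_i = log mean_d exp(ll[d, i]) - var_d(ll[d, i])`, with the log-mean
#' computed by a log-sum-exp-stable reduction. The penalty
#' `p_eff = sum_i var_d(ll[d, i])` is the effective parameter count and
#' `se = sqrt(n * var_i(elpd_i))`.
#'
#' @param ll Matrix of pointwise log-likelihoods, draws x responses, e.g.
#'   from [pointwise_loglik()]; all entries finite, at least 100 draws.
#' @return A list of class `waic_result`: `score` (elpd_waic), `se`,
#'   `p_eff`, and the `pointwise` elpd vector.
#' @export
compute_waic <- function(ll) {
  if (!is.matrix(ll)) stop("`ll` must be a draws x responses matrix")
  if (nrow(ll) < 100) stop("need at least 100 draws")
  if (!all(is.finite(ll))) stop("non-finite log-likelihood entries")
  S <- nrow(ll); n <- ncol(ll)
  M <- apply(ll, 2, max)
  lppd <- M + log(colMeans(exp(sweep(ll, 2, M, "-"))))
  mean_ll <- colMeans(ll)
  p_i <- (colSums(ll^2) - S * mean_ll^2) / (S - 1)
  pointwise <- lppd - p_i
  structure(list(score = sum(pointwise),
                 se = sqrt(n * stats::var(pointwise)),
                 p_eff = sum(p_i),
                 pointwise = pointwise),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC (elpd scale): %.2f (se %.2f), p_eff %.2f, n = %d\n",
              x$score, x$se, x$p_eff, length(x$pointwise)))
  invisible(x)
}

#' Rank models by WAIC
#'
#' Sorts models by elpd-scale WAIC (higher is better) and reports, for each,
#' the difference to the top model with the standard error of that
#' difference computed from the paired pointwise contributions. All models
#' must have been scored on the identical response set.
#'
#' @param waics Named list of `waic_result` objects.
#' @return Data frame with columns `model`, `elpd_waic`, `se`, `p_eff`,
#'   `delta_elpd`, `se_delta`, ordered best first.
#' @export
compare_models <- function(waics) {
  if (is.null(names(waics)) || any(names(waics) == "")) {
    stop("`waics` must be a named list")
  }
  ns <- vapply(waics, function(w) length(w$pointwise), integer(1))
  if (length(unique(ns)) != 1) {
    stop("models were scored on different response sets")
  }
  scores <- vapply(waics, function(w) w$score, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  top <- waics[[ord[1]]]
  res <- data.frame(
    model = names(waics)[ord],
    elpd_waic = scores[ord],
    se = vapply(waics[ord], function(w) w$se, numeric(1)),
    p_eff = vapply(waics[ord], function(w) w$p_eff, numeric(1)),
    delta_elpd = scores[ord[1]] - scores[ord],
    se_delta = vapply(waics[ord], function(w) {
      d <- top$pointwise - w$pointwise
      sqrt(length(d) * stats::var(d))
    }, numeric(1)),
    row.names = NULL
  )
  res
}
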