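test_that("grid posterior is a normalized density", {
  set.seed(41)
  cmp <- sim_participant(20)
  g <- grid_posterior(cmp$x_percent, cmp$response)
  # independent trapezoid quadrature of the returned density
  z <- sum(diff(g$jnd) * (head(g$density, -1) + tail(g$density, -1)) / 2)
  expect_equal(z, 1, tolerance = 1e-6)
  # zero comparisons: the prior comes back
  g0 <- grid_posterior(numeric(0), integer(0), jnd_prior(0, 70))
  expect_equal(diff(range(g0$density)), 0, tolerance = 1e-12)
  expect_equal(attr(g0, "mean"), (0.1 + 70) / 2, tolerance = 0.05)
})

test_that("MCMC posterior agrees with the grid-integration oracle", {
  set.seed(42)
  cmp <- sim_participant(25)
  fit <- fit_independent(cmp, mcmc = mcmc_settings(4, 1000, 4000), seed = 5)
  post <- fit$posteriors[["1"]]
  g <- grid_posterior(cmp$x_percent, cmp$response)
  expect_lt(abs(mean(post$draws) - attr(g, "mean")), 0.5)
  expect_lt(abs(sd(post$draws) - attr(g, "sd")), 0.3)
  expect_lt(post$diagnostics$rhat, 1.02)
})

test_that("MCMC fits are deterministic given the seed", {
  set.seed(43)
  cmp <- sim_participant(20)
  f1 <- fit_independent(cmp, mcmc = quick_mcmc(), seed = 9)
  f2 <- fit_independent(cmp, mcmc = quick_mcmc(), seed = 9)
  expect_identical(f1$posteriors[["1"]]$draws, f2$posteriors[["1"]]$draws)
  expect_error(fit_independent(cmp[0, ], mcmc = quick_mcmc()), "no comparisons")
})

test_that("chance-level responders push the posterior to high JNDs", {
  set.seed(44)
  cmp <- sim_participant(20)
  cmp$response <- rbinom(99, 1, 0.5)   # responses carry no information
  fit <- fit_independent(cmp, mcmc = quick_mcmc(), seed = 3)
  post <- fit$posteriors[["1"]]
  expect_gt(post$ci95["upper"], 50)
  # the grid oracle shows the same upper-bound-hugging shape
  g <- grid_posterior(cmp$x_percent, cmp$response)
  expect_gt(attr(g, "mean"), 25)
})

test_that("pooled fit on one participant matches the independent fit", {
  set.seed(45)
  cmp <- sim_participant(22)
  fi <- fit_independent(cmp, mcmc = quick_mcmc(2, 1000, 2000), seed = 2)
  fp <- fit_pooled(cmp, mcmc = quick_mcmc(2, 1000, 2000), seed = 12)
  expect_lt(abs(mean(fi$posteriors[["1"]]$draws) -
                mean(fp$posteriors$pooled$draws)), 1.5)
})

test_that("pooled fit brackets a heterogeneous cohort", {
  set.seed(46)
  cmp <- simulate_comparisons(c(8, 60))
  fp <- fit_pooled(cmp, mcmc = quick_mcmc(), seed = 4)
  est <- fp$posteriors$pooled$point_estimate
  expect_gt(est, 8)
  expect_lt(est, 60)
})

test_that("variable-WF split is the median of reference magnitudes", {
  cmp <- data.frame(participant = 1, block = 1, pair = 1:4,
                    A_w_kg = c(2, 3, 4, 5), B_w_kg = c(3, 4, 5, 6),
                    x_percent = c(50, 33.3, 25, 20),
                    response = c(1L, 1L, 0L, 1L))
  fit <- fit_variable_wf(cmp, mcmc = quick_mcmc(), seed = 6,
                         check_rhat = Inf)
  pp <- fit$posteriors[["1"]]
  expect_equal(pp$split, 3.5)
  expect_equal(pp$low$diagnostics$n_obs, 2)
  expect_equal(pp$high$diagnostics$n_obs, 2)
  cmp$A_w_kg <- rep(3, 4)
  expect_error(fit_variable_wf(cmp, mcmc = quick_mcmc()), "identical")
})

test_that("variable-WF model recovers a reference-dependent JND", {
  set.seed(47)
  ordered_ok <- 0
  for (rep in 1:50) {
    A <- runif(99, 1.5, 6.6)
    x <- runif(99, -40, 60)
    jnd_true <- ifelse(A <= median(A), 10, 40)
    cmp <- data.frame(participant = 1, block = 1, pair = 1:99, A_w_kg = A,
                      B_w_kg = A * (1 + x / 100), x_percent = x,
                      response = simulate_response(x, jnd_true))
    fit <- fit_variable_wf(cmp, mcmc = quick_mcmc(2, 300, 500), seed = rep,
                           check_rhat = Inf)
    pp <- fit$posteriors[["1"]]
    if (pp$low$point_estimate < pp$high$point_estimate) {
      ordered_ok <- ordered_ok + 1
    }
  }
  expect_gte(ordered_ok, 45)   # >= 90% of replicates
})

test_that("variable-WF halves overlap under a constant-WF truth", {
  set.seed(48)
  overlap <- 0
  for (rep in 1:50) {
    cmp <- sim_participant(20)
    fit <- fit_variable_wf(cmp, mcmc = quick_mcmc(2, 300, 500), seed = rep,
                           check_rhat = Inf)
    pp <- fit$posteriors[["1"]]
    lo <- pp$low$ci95; hi <- pp$high$ci95
    if (lo["lower"] <= hi["upper"] && hi["lower"] <= lo["upper"]) {
      overlap <- overlap + 1
    }
  }
  expect_gte(overlap, 45)
})

test_that("posterior mode extraction behaves on known densities", {
  expect_equal(as.numeric(posterior_mode(rep(20, 500))), 20)
  set.seed(49)
  d <- rnorm(16000, 25, 2)
  d <- d[d > 0 & d < 70]
  m <- posterior_mode(d, support = c(0.1, 70))
  expect_lt(abs(as.numeric(m) - 25), 0.5)
  expect_false(attr(m, "flat"))
  # a uniform posterior is flagged as non-identified
  u <- runif(16000, 0.1, 70)
  expect_true(attr(posterior_mode(u, support = c(0.1, 70)), "flat"))
  expect_error(posterior_mode(1:50), "100 draws")
})

test_that("credible intervals are equal-tailed quantiles", {
  draws <- (1:10000) / 100
  ci <- credible_interval(draws)
  expect_equal(unname(ci), c(2.5, 97.5), tolerance = 0.02)
  expect_equal(unname(credible_interval(rep(7, 200))), c(7, 7))
  expect_equal(unname(credible_interval(draws, level = 0.5)), c(25, 75),
               tolerance = 0.02)
  expect_error(credible_interval(draws, level = 1.2), "level")
  expect_error(credible_interval(1:10), "100 draws")
})

test_that("WAIC matches a literal two-pass oracle", {
  # constant log-likelihood: no posterior variance, zero penalty
  ll <- matrix(-0.3, nrow = 200, ncol = 17)
  w <- compute_waic(ll)
  expect_equal(w$score, 17 * -0.3, tolerance = 1e-12)
  expect_equal(w$p_eff, 0, tolerance = 1e-12)
  # random matrix vs unstabilized formula
  set.seed(50)
  ll <- matrix(log(runif(200 * 50, 0.2, 0.9)), nrow = 200)
  w <- compute_waic(ll)
  pointwise <- numeric(50)
  for (i in 1:50) {
    pointwise[i] <- log(mean(exp(ll[, i]))) - var(ll[, i])
  }
  expect_equal(w$score, sum(pointwise), tolerance = 1e-8)
  expect_equal(w$pointwise, pointwise, tolerance = 1e-8)
  expect_equal(w$se, sqrt(50 * var(pointwise)), tolerance = 1e-8)
  # duplicating a response duplicates its contribution
  w2 <- compute_waic(cbind(ll, ll[, 1]))
  expect_equal(w2$score, w$score + pointwise[1], tolerance = 1e-8)
  expect_error(compute_waic(matrix(c(1, NA), 150, 2)), "finite")
  expect_error(compute_waic(ll[1:50, ]), "100 draws")
})

test_that("model comparison ranks by elpd and propagates pairwise SEs", {
  set.seed(51)
  ll <- matrix(log(runif(200 * 30, 0.2, 0.9)), nrow = 200)
  wa <- compute_waic(ll)
  wb <- compute_waic(ll + 0.1)   # uniformly better by 0.1 per point
  tab <- compare_models(list(a = wa, b = wb))
  expect_equal(tab$model, c("b", "a"))
  expect_equal(tab$delta_elpd, c(0, 3), tolerance = 1e-8)
  expect_equal(tab$se_delta, c(0, 0), tolerance = 1e-8)
  # identical models tie exactly
  tab2 <- compare_models(list(a = wa, b = wa))
  expect_equal(tab2$delta_elpd, c(0, 0))
  wc <- compute_waic(ll[, 1:10])
  expect_error(compare_models(list(a = wa, c = wc)), "different response sets")
})

test_that("pointwise likelihood matrices route responses to the right draws", {
  set.seed(52)
  cmp <- rbind(sim_participant(15), transform(sim_participant(45), participant = 2))
  fit <- fit_independent(cmp, mcmc = quick_mcmc(2, 300, 500), seed = 8)
  ll <- pointwise_loglik(fit, cmp)
  expect_equal(ncol(ll), nrow(cmp))
  expect_equal(nrow(ll), 2 * 500)
  # oracle: recompute one cell per participant by hand
  k <- scale_constant_k()
  for (pid in c("1", "2")) {
    i <- which(cmp$participant == as.numeric(pid))[1]
    d <- fit$posteriors[[pid]]$draws[3]
    m <- psychometric_model(jnd = d)
    p <- psychometric_prob(cmp$x_percent[i], m)
    expect_equal(ll[3, i],
                 if (cmp$response[i] == 1) log(p) else log(1 - p),
                 tolerance = 1e-12)
  }
})
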