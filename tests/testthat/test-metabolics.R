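test_that("first-order fit is exact on noiseless series in its model class", {
  t <- seq(0, 120, by = 4)
  for (pars in list(c(y0 = 1, y_ss = 3, tau = 42),
                    c(y0 = 5.5, y_ss = 2.2, tau = 70),
                    c(y0 = 2, y_ss = 6, tau = 15))) {
    y <- pars["y_ss"] + (pars["y0"] - pars["y_ss"]) * exp(-t / pars["tau"])
    f <- fit_first_order(t, y)
    expect_true(f$converged)
    expect_equal(f$y_ss, unname(pars["y_ss"]), tolerance = 1e-6)
    expect_equal(f$y0, unname(pars["y0"]), tolerance = 1e-6)
    expect_equal(f$tau, unname(pars["tau"]), tolerance = 1e-6)
  }
})

test_that("degenerate constant series falls back to the plain mean", {
  t <- seq(0, 120, by = 4)
  f <- fit_first_order(t, rep(2.5, length(t)))
  expect_equal(f$y_ss, 2.5, tolerance = 1e-9)
  expect_equal(f$rss, 0, tolerance = 1e-12)
  expect_error(fit_first_order(1:4, 1:4), "at least 5")
  expect_error(fit_first_order(c(1, 2, 2, 3, 4), rep(1, 5)), "increasing")
  expect_error(fit_first_order(1:5, c(1, 2, NA, 4, 5)), "finite")
})

test_that("steady-state error shrinks with series duration", {
  set.seed(31)
  med_err <- vapply(c(60, 120, 240), function(dur) {
    errs <- replicate(80, {
      br <- simulate_breath_series(1.3, 4, tau = 42, noise_sd = 0.32,
                                   duration_s = dur)
      abs(fit_first_order(br$t_s, br$power_w_kg)$y_ss - 4) / 4
    })
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("standing baseline is the interval mean", {
  expect_equal(standing_baseline(rep(1.2, 60)), 1.2)
  expect_equal(standing_baseline(c(1.0, 1.4)), 1.2)
  expect_error(standing_baseline(numeric(0)), "empty")
  set.seed(32)
  # noisy standing series: mean within 2 SE of truth
  s <- simulate_breath_series(1.25, 1.25, noise_sd = 0.05, duration_s = 240)
  se <- 0.05 / sqrt(nrow(s))
  expect_lt(abs(standing_baseline(s$power_w_kg) - 1.25), 2 * se + 1e-3)
})

test_that("net rate subtracts the baseline and flags pathological trials", {
  expect_equal(net_rate(4.2, 1.2), 3.0)
  expect_equal(net_rate(2.5, 0), 2.5)
  expect_warning(out <- net_rate(1.0, 1.2), "non-positive")
  expect_equal(out, -0.2)
})

test_that("sequential pairing yields n-1 comparisons per block", {
  set.seed(33)
  trials <- make_trials(list(runif(10, 2, 6)), list(rbinom(9, 1, 0.5)))
  cmp <- build_comparisons(trials)
  expect_equal(nrow(cmp), 9)
  expect_equal(attr(cmp, "n_dropped"), 0)
  # explicit arithmetic: A = 4.0, B = 4.4 is a +10% change
  tr2 <- make_trials(list(c(4.0, 4.4)), list(1L))
  expect_equal(build_comparisons(tr2)$x_percent, 10.0, tolerance = 1e-12)
})

test_that("comparisons never span block boundaries", {
  set.seed(34)
  net1 <- runif(10, 2, 6); net2 <- runif(10, 2, 6)
  trials <- make_trials(list(net1, net2),
                        list(rbinom(9, 1, 0.5), rbinom(9, 1, 0.5)))
  cmp <- build_comparisons(trials)
  expect_equal(nrow(cmp), 18)
  # no pair uses block 1's last trial as reference for block 2's first
  expect_false(any(cmp$A_w_kg == net1[10] & cmp$B_w_kg == net2[1]))
  expect_equal(sum(cmp$block == 1), 9)
})

test_that("x is a pure ratio statistic and bad references are dropped", {
  set.seed(35)
  net <- runif(10, 2, 6)
  resp <- rbinom(9, 1, 0.5)
  a <- build_comparisons(make_trials(list(net), list(resp)))
  b <- build_comparisons(make_trials(list(net * 3.7), list(resp)))
  expect_equal(a$x_percent, b$x_percent, tolerance = 1e-12)
  # a non-positive reference invalidates exactly the pairs that use it
  net_bad <- net; net_bad[4] <- -0.1
  expect_message(
    cmp <- build_comparisons(make_trials(list(net_bad), list(resp))),
    "non-positive")
  expect_equal(nrow(cmp), 8)
  expect_equal(attr(cmp, "n_dropped"), 1)
})

test_that("malformed trial tables are rejected", {
  trials <- make_trials(list(c(2, 3, 4)), list(c(1L, NA)))
  expect_error(build_comparisons(trials), "missing response")
  dup <- rbind(make_trials(list(c(2, 3)), list(1L)),
               make_trials(list(c(2, 3)), list(1L)))
  expect_error(build_comparisons(dup), "duplicate")
  expect_error(build_comparisons(data.frame(participant = 1)), "missing column")
})

test_that("whole-study rate estimation recovers the surrogate truth", {
  study <- generate_study(study_config(n_participants = 2,
                                       blocks_per_participant = 2),
                          seed = 36)
  trials <- estimate_trial_rates(study)
  expect_true(all(c("y_ss_w_kg", "baseline_w_kg", "net_w_kg") %in%
                    names(trials)))
  # baseline estimates near the true standing rates
  expect_equal(unique(trials$baseline_w_kg)[order(unique(trials$participant))],
               study$truth$standing_rate_w_kg, tolerance = 0.05)
  # net estimates track the true net rates
  expect_gt(cor(trials$net_w_kg, trials$true_net_w_kg), 0.85)
  expect_lt(median(abs(trials$net_w_kg - trials$true_net_w_kg) /
                     trials$true_net_w_kg), 0.15)
})
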