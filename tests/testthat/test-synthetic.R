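test_that("torque-profile draws respect their bounds and constraints", {
  set.seed(1)
  p <- sample_torque_profile(10000)
  expect_true(all(p$onset >= 0.25 & p$onset <= 0.50))
  expect_true(all(p$magnitude_A >= 15 & p$magnitude_A <= 25))
  expect_true(all(p$duration <= 0.60))
  expect_true(all(p$duration >= 0.10))
  # early onsets carry the stricter device-wear duration floor
  early <- p$onset < 0.30
  expect_true(any(early))
  expect_true(all(p$duration[early] >= 0.20))
})

test_that("torque magnitude is uniform on 15-25 A (Monte-Carlo mean)", {
  set.seed(2)
  p <- sample_torque_profile(100000)
  expect_equal(mean(p$magnitude_A), 20, tolerance = 0.1 / 20)
})

test_that("rate surrogate is deterministic, in range and non-degenerate", {
  set.seed(3)
  p <- sample_torque_profile(10000)
  r1 <- surrogate_metabolic_rate(p)
  r2 <- surrogate_metabolic_rate(p)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 1.5 & r1 <= 6.6))
  expect_gt(sd(r1), 0.3)
  expect_error(surrogate_metabolic_rate(p, rate_range = c(5, 2)), "range")
})

test_that("breath series follows the first-order transient", {
  # fixed point: no transient, no noise
  s <- simulate_breath_series(3, 3, noise_sd = 0)
  expect_true(all(s$power_w_kg == 3))
  expect_true(all(diff(s$t_s) > 0))
  # closed-form value one time constant into the response
  s <- simulate_breath_series(1, 3, tau = 42, noise_sd = 0,
                              breath_interval_s = 42, breath_jitter_s = 0)
  expect_equal(s$power_w_kg[1], 3 - 2 * exp(-1), tolerance = 1e-12)
  expect_equal(s$t_s[1], 42)
  expect_error(simulate_breath_series(1, 3, tau = 0), "tau")
  expect_error(simulate_breath_series(1, 3, breath_interval_s = 0.5,
                                      breath_jitter_s = 1), "interval")
})

test_that("simulated responses follow the psychometric function", {
  set.seed(4)
  # zero difference: a coin flip
  expect_equal(mean(simulate_response(rep(0, 20000), 20)), 0.5,
               tolerance = 0.01 / 0.5)
  # a difference of one JND: detected 75% of the time
  expect_equal(mean(simulate_response(rep(20, 20000), 20)), 0.75,
               tolerance = 0.01 / 0.75)
  # saturation at 1 - lapse
  expect_equal(mean(simulate_response(rep(1e4, 20000), 20)), 0.98,
               tolerance = 0.005)
  expect_error(simulate_response(0, -5), "positive")
})

test_that("binned response frequencies converge to the psychometric curve", {
  set.seed(5)
  jnd <- 25
  x <- runif(40000, -60, 60)
  r <- simulate_response(x, jnd)
  m <- psychometric_model(jnd = jnd)
  bins <- cut(x, breaks = seq(-60, 60, by = 10))
  for (b in levels(bins)) {
    idx <- bins == b
    phat <- mean(r[idx])
    p <- mean(psychometric_prob(x[idx], m))
    se <- sqrt(p * (1 - p) / sum(idx))
    expect_lt(abs(phat - p), 4 * se + 1e-3)
  }
})

test_that("generated studies have the experiment's block structure", {
  study <- generate_study(study_config(), seed = 10)
  cfg <- study$config
  expect_equal(nrow(study$trials), 10 * 11 * 10)
  expect_equal(nrow(study$truth), 10)
  responses <- tapply(!is.na(study$trials$response),
                      study$trials$participant, sum)
  expect_true(all(responses == 99))   # nine comparisons across ten trials
  expect_true(all(study$truth$true_jnd >= cfg$jnd_range[1] &
                  study$truth$true_jnd <= cfg$jnd_range[2]))
  expect_true(all(study$truth$tau_s == 42))
  # invariants hold on every generated study
  expect_silent(validate_study(study))
})

test_that("study generation is reproducible and leaves the RNG alone", {
  cfg <- study_config(n_participants = 2, blocks_per_participant = 3)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  s1 <- generate_study(cfg, seed = 7)
  after <- runif(1)
  expect_identical(before, after)   # caller's stream untouched
  s2 <- generate_study(cfg, seed = 7)
  expect_identical(s1, s2)
  # byte-identical on disk too
  d1 <- tempfile(); d2 <- tempfile()
  write_study(s1, d1); write_study(s2, d2)
  for (f in c("trials.csv", "breaths.csv", "standing.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(s1, generate_study(cfg, seed = 8)))
})

test_that("degenerate and invalid configurations are handled", {
  s <- generate_study(study_config(n_participants = 1,
                                   blocks_per_participant = 2,
                                   trials_per_block = 2), seed = 1)
  expect_equal(sum(!is.na(s$trials$response)), 2)  # one comparison per block
  expect_error(study_config(trials_per_block = 1), ">= 2")
  expect_error(study_config(jnd_range = c(10, 5)), "jnd_range")
  expect_error(study_config(tau = -1), "tau")
})

test_that("simulate_comparisons mirrors the study's comparison structure", {
  set.seed(6)
  cmp <- simulate_comparisons(c(15, 40), blocks_per_participant = 11)
  expect_equal(nrow(cmp), 2 * 11 * 9)
  expect_equal(attr(cmp, "true_jnd"), c(15, 40))
  expect_equal(cmp$x_percent, 100 * (cmp$B_w_kg - cmp$A_w_kg) / cmp$A_w_kg,
               tolerance = 1e-12)
  expect_true(all(cmp$response %in% 0:1))
})
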