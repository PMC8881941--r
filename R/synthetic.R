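#' Configuration for a synthetic perception-of-metabolic-rate study
#'
#' Bundles and validates the knobs of the synthetic-study generator. The
#' defaults reproduce the design of the walking experiment the package
#' analyzes: 10 participants, ~11 blocks each, 10 two-minute trials per block
#' (hence 9 sequential comparisons), net metabolic rates spanning roughly
#' 1.5-6.6 W/kg, a 42 s cardiopulmonary time constant, and a 2% lapse rate.
#'
#' @param n_participants Number of participants (default 10).
#' @param blocks_per_participant Blocks of continuous walking per participant
#'   (default 11).
#' @param trials_per_block Trials per block (default 10; must be >= 2 so each
#'   block yields at least one comparison).
#' @param jnd_range Range (percent) from which true participant JNDs are drawn
#'   uniformly. Default `c(6, 70)`, exercising both sharply identified and
#'   nearly flat posterior regimes.
#' @param rate_range Range (W/kg) of net steady-state rates reachable by the
#'   torque-profile surrogate. Default `c(1.5, 6.6)`.
#' @param standing_range Range (W/kg) of standing baseline rates, drawn
#'   uniformly per participant. Default `c(1.0, 1.5)`.
#' @param tau Cardiopulmonary time constant of the first-order metabolic
#'   transient, seconds. Default 42.
#' @param noise_frac Breath-to-breath noise SD as a fraction of the local
#'   steady-state rate. Default 0.08.
#' @param trial_duration_s Walking trial length in seconds (default 120).
#' @param standing_duration_s Standing baseline length in seconds (default 240).
#' @param breath_interval_s Mean breath spacing in seconds (default 4).
#' @param breath_jitter_s Half-width of the uniform jitter on breath spacing
#'   (default 1, i.e. intervals in 3-5 s).
#' @param lapse Lapse/false-positive rate used when generating responses
#'   (default 0.02, matching the analysis's fixed value; override to study
#'   lapse misspecification).
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_participants = 10,
                         blocks_per_participant = 11,
                         trials_per_block = 10,
                         jnd_range = c(6, 70),
                         rate_range = c(1.5, 6.6),
                         standing_range = c(1.0, 1.5),
                         tau = 42,
                         noise_frac = 0.08,
                         trial_duration_s = 120,
                         standing_duration_s = 240,
                         breath_interval_s = 4,
                         breath_jitter_s = 1,
                         lapse = 0.02) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    blocks_per_participant = as.integer(blocks_per_participant),
    trials_per_block = as.integer(trials_per_block),
    jnd_range = as.numeric(jnd_range),
    rate_range = as.numeric(rate_range),
    standing_range = as.numeric(standing_range),
    tau = as.numeric(tau),
    noise_frac = as.numeric(noise_frac),
    trial_duration_s = as.numeric(trial_duration_s),
    standing_duration_s = as.numeric(standing_duration_s),
    breath_interval_s = as.numeric(breath_interval_s),
    breath_jitter_s = as.numeric(breath_jitter_s),
    lapse = as.numeric(lapse)
  )
  if (cfg$n_participants < 1) stop("need at least one participant")
  if (cfg$blocks_per_participant < 1) stop("need at least one block")
  if (cfg$trials_per_block < 2) {
    stop("`trials_per_block` must be >= 2 (a block needs at least one comparison)")
  }
  if (length(cfg$jnd_range) != 2 || cfg$jnd_range[1] <= 0 ||
      diff(cfg$jnd_range) <= 0) stop("invalid `jnd_range`")
  if (length(cfg$rate_range) != 2 || diff(cfg$rate_range) <= 0) {
    stop("invalid `rate_range` (min must be below max)")
  }
  if (cfg$tau <= 0) stop("`tau` must be positive")
  if (cfg$noise_frac < 0) stop("`noise_frac` must be non-negative")
  if (cfg$breath_interval_s <= cfg$breath_jitter_s) {
    stop("`breath_interval_s` must exceed `breath_jitter_s`")
  }
  if (cfg$lapse < 0 || cfg$lapse >= 0.5) stop("`lapse` must be in [0, 0.5)")
  class(cfg) <- "study_config"
  cfg
}

#' Sample exoskeleton torque-profile parameters
#'
#' Draws the three parameters of the square-pulse ankle-assistance current
#' profile: onset timing uniform on 25-50% of stride, pulse magnitude uniform
#' on 15-25 A, and pulse duration uniform between a variable lower bound and
#' 60% of stride. The lower bound is 10% of stride, raised to 20% for onsets
#' earlier than 30% of stride (a device-wear constraint of the original
#' hardware).
#'
#' Uses the current R random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param n Number of profiles to draw.
#' @return A data frame with columns `onset`, `magnitude_A`, `duration`
#'   (onset and duration as fractions of stride).
#' @export
sample_torque_profile <- function(n = 1) {
  onset <- stats::runif(n, 0.25, 0.50)
  magnitude <- stats::runif(n, 15, 25)
  d_min <- ifelse(onset < 0.30, 0.20, 0.10)
  duration <- stats::runif(n, d_min, 0.60)
  data.frame(onset = onset, magnitude_A = magnitude, duration = duration)
}

#' Surrogate map from torque profile to net metabolic rate
#'
#' A deterministic, smooth quadratic response surface in the three normalized
#' profile parameters, rescaled affinely into `rate_range`. This is an
#' explicitly synthetic surrogate: the real profile-to-energetics map is an
#' unknown property of human physiology, and downstream inference needs only
#' realistic, reproducible rate variation across trials, not biomechanical
#' fidelity. Raising pulse magnitude or duration raises the imposed rate;
#' later onsets amplify the magnitude effect.
#'
#' @param profile Data frame as returned by [sample_torque_profile()].
#' @param rate_range Numeric length-2, target net-rate range in W/kg.
#' @return Net steady-state metabolic rate(s), W/kg, one per profile row.
#' @export
surrogate_metabolic_rate <- function(profile, rate_range = c(1.5, 6.6)) {
  if (length(rate_range) != 2 || rate_range[1] >= rate_range[2]) {
    stop("invalid `rate_range` (min must be below max)")
  }
  u_on <- (profile$onset - 0.25) / 0.25
  u_mag <- (profile$magnitude_A - 15) / 10
  u_dur <- (profile$duration - 0.10) / 0.50
  # positive-coefficient quadratic with exact range [0, 1] over the unit box
  q <- (0.55 * u_mag + 0.30 * u_dur + 0.15 * u_on * u_mag)
  rate_range[1] + diff(rate_range) * q
}

#' Simulate a breath-by-breath metabolic power series
#'
#' Instantaneous metabolic power follows a first-order transient from the
#' previous steady state toward the current target,
#' `y(t) = target + (prev - target) * exp(-t / tau)`, sampled at
#' breath-spaced timestamps with additive Gaussian noise.
#'
#' @param prev_rate Steady-state rate carried in from the previous interval
#'   (W/kg).
#' @param target_rate Steady-state rate of the current interval (W/kg).
#' @param tau First-order time constant, seconds (default 42).
#' @param noise_sd SD of additive breath noise (W/kg).
#' @param duration_s Length of the interval, seconds.
#' @param breath_interval_s Mean breath spacing, seconds.
#' @param breath_jitter_s Half-width of uniform jitter on spacing, seconds.
#' @return Data frame with strictly increasing `t_s` and `power_w_kg`.
#' @export
simulate_breath_series <- function(prev_rate, target_rate, tau = 42,
                                   noise_sd = 0, duration_s = 120,
                                   breath_interval_s = 4, breath_jitter_s = 1) {
  if (tau <= 0) stop("`tau` must be positive")
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (breath_interval_s <= breath_jitter_s || breath_interval_s <= 0) {
    stop("breath interval must be positive and exceed its jitter")
  }
  n_max <- ceiling(duration_s / (breath_interval_s - breath_jitter_s)) + 1
  gaps <- stats::runif(n_max, breath_interval_s - breath_jitter_s,
                       breath_interval_s + breath_jitter_s)
  t <- cumsum(gaps)
  t <- t[t <= duration_s]
  y <- target_rate + (prev_rate - target_rate) * exp(-t / tau)
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
  data.frame(t_s = t, power_w_kg = y)
}

#' Simulate a forced-choice response
#'
#' Draws a Bernoulli response ("the current exertion is higher": 1) with
#' success probability given by the fixed-lapse logistic psychometric
#' function evaluated at the true percent rate change, with slope
#' `beta = k / true_jnd` and `gamma = lambda = lapse`.
#'
#' @param x_percent True percent change of the comparison rate relative to
#'   the reference rate.
#' @param true_jnd True JND of the simulated participant, percent.
#' @param lapse Lapse/false-positive rate.
#' @return Integer vector of 0/1 responses, one per element of `x_percent`.
#' @export
simulate_response <- function(x_percent, true_jnd, lapse = 0.02) {
  if (any(true_jnd <= 0)) stop("`true_jnd` must be positive")
  m <- psychometric_model(jnd = true_jnd[1], gamma = lapse, lambda = lapse)
  if (length(true_jnd) > 1) {
    k <- m$k
    p <- lapse + (1 - 2 * lapse) / (1 + exp(-(k / true_jnd) * x_percent))
  } else {
    p <- psychometric_prob(x_percent, m)
  }
  stats::rbinom(length(x_percent), 1L, p)
}

#' Generate a complete synthetic study with ground truth
#'
#' Builds a full forced-choice walking study: per participant, a true JND
#' drawn uniformly from `jnd_range`, a standing baseline rate, a standing
#' breath series, and `blocks_per_participant` blocks of
#' `trials_per_block` trials. Each trial carries a sampled torque profile,
#' a true net steady-state rate from the deterministic surrogate, a noisy
#' breath series following the first-order transient from the previous
#' trial's (gross) rate, and — for every trial after the first of a block —
#' a binary response generated from the true psychometric function at the
#' true percent rate change.
#'
#' The result is bit-reproducible given `(config, seed)`; the caller's RNG
#' state is left untouched.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return An object of class `jnd_study`: a list with data frames
#'   `trials` (participant, block, trial, torque parameters, true net rate,
#'   response), `breaths`, `standing`, a `truth` data frame of per-participant
#'   ground truth, and the `config` and `seed` used.
#' @examples
#' study <- generate_study(study_config(n_participants = 2,
#'                                      blocks_per_participant = 2), seed = 1)
#' table(is.na(study$trials$response))
#' @export
generate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  trials_list <- list()
  breaths_list <- list()
  standing_list <- list()
  truth_list <- list()

  for (p in seq_len(config$n_participants)) {
    true_jnd <- stats::runif(1, config$jnd_range[1], config$jnd_range[2])
    standing_rate <- stats::runif(1, config$standing_range[1],
                                  config$standing_range[2])
    truth_list[[p]] <- data.frame(
      participant = p, true_jnd = true_jnd, lapse = config$lapse,
      standing_rate_w_kg = standing_rate, tau_s = config$tau
    )
    stand <- simulate_breath_series(
      standing_rate, standing_rate, tau = config$tau,
      noise_sd = config$noise_frac * standing_rate,
      duration_s = config$standing_duration_s,
      breath_interval_s = config$breath_interval_s,
      breath_jitter_s = config$breath_jitter_s
    )
    standing_list[[p]] <- cbind(participant = p, stand)

    for (b in seq_len(config$blocks_per_participant)) {
      prev_gross <- standing_rate
      prev_net <- NA_real_
      for (tr in seq_len(config$trials_per_block)) {
        prof <- sample_torque_profile(1)
        net <- surrogate_metabolic_rate(prof, config$rate_range)
        gross <- net + standing_rate
        br <- simulate_breath_series(
          prev_gross, gross, tau = config$tau,
          noise_sd = config$noise_frac * gross,
          duration_s = config$trial_duration_s,
          breath_interval_s = config$breath_interval_s,
          breath_jitter_s = config$breath_jitter_s
        )
        breaths_list[[length(breaths_list) + 1L]] <-
          cbind(participant = p, block = b, trial = tr, br)
        response <- NA_integer_
        if (tr > 1L) {
          x <- 100 * (net - prev_net) / prev_net
          response <- simulate_response(x, true_jnd, config$lapse)
        }
        trials_list[[length(trials_list) + 1L]] <- data.frame(
          participant = p, block = b, trial = tr,
          onset = prof$onset, magnitude_A = prof$magnitude_A,
          duration = prof$duration, true_net_w_kg = net, response = response
        )
        prev_gross <- gross
        prev_net <- net
      }
    }
  }

  study <- structure(
    list(
      trials = do.call(rbind, trials_list),
      breaths = do.call(rbind, breaths_list),
      standing = do.call(rbind, standing_list),
      truth = do.call(rbind, truth_list),
      config = config,
      seed = as.integer(seed)
    ),
    class = "jnd_study"
  )
  rownames(study$trials) <- NULL
  rownames(study$breaths) <- NULL
  rownames(study$standing) <- NULL
  rownames(study$truth) <- NULL
  validate_study(study)
  study
}

#' Assert the structural invariants of a study
#'
#' Checks block/trial/response bookkeeping (each block of `m` trials carries
#' exactly `m - 1` responses), strictly increasing breath timestamps within
#' each interval, finite rates within the configured range, and positive
#' ground-truth JNDs. Called automatically by [generate_study()].
#'
#' @param study A `jnd_study`.
#' @return `study`, invisibly; errors on any violation.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "jnd_study"))
  cfg <- study$config
  tr <- study$trials
  counts <- table(tr$participant, tr$block)
  if (!all(counts == cfg$trials_per_block)) {
    stop("every block must contain exactly ", cfg$trials_per_block, " trials")
  }
  first <- tr$trial == 1L
  if (!all(is.na(tr$response[first]))) {
    stop("first trial of a block cannot carry a response")
  }
  if (anyNA(tr$response[!first])) stop("missing response on a non-first trial")
  if (!all(tr$response[!first] %in% c(0L, 1L))) stop("responses must be 0/1")
  if (!all(is.finite(tr$true_net_w_kg)) ||
      any(tr$true_net_w_kg < cfg$rate_range[1] - 1e-9) ||
      any(tr$true_net_w_kg > cfg$rate_range[2] + 1e-9)) {
    stop("true net rates outside the configured range")
  }
  if (any(tr$onset < 0.25 | tr$onset > 0.50)) stop("onset outside [0.25, 0.50]")
  if (any(tr$magnitude_A < 15 | tr$magnitude_A > 25)) {
    stop("magnitude outside [15, 25] A")
  }
  if (any(tr$duration > 0.60) ||
      any(tr$duration < ifelse(tr$onset < 0.30, 0.20, 0.10))) {
    stop("duration violates its onset-dependent bounds")
  }
  by_int <- split(study$breaths$t_s,
                  interaction(study$breaths$participant, study$breaths$block,
                              study$breaths$trial, drop = TRUE))
  if (!all(vapply(by_int, function(t) all(diff(t) > 0), logical(1)))) {
    stop("breath timestamps must be strictly increasing within a trial")
  }
  if (any(study$truth$true_jnd <= 0)) stop("true JNDs must be positive")
  invisible(study)
}

#' @export
print.jnd_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic forced-choice study: %d participants x %d blocks x %d trials (seed %d)\n",
    x$config$n_participants, x$config$blocks_per_participant,
    x$config$trials_per_block, x$seed))
  cat(sprintf("  %d trials, %d responses, %d breaths\n",
              nrow(x$trials), sum(!is.na(x$trials$response)), nrow(x$breaths)))
  invisible(x)
}

#' Simulate forced-choice comparisons directly from true rates
#'
#' Lightweight companion to [generate_study()]: skips breath-series synthesis
#' and transient fitting, pairing the surrogate's true net rates directly
#' into sequential comparisons with psychometric responses. Useful for
#' inference-focused simulation studies (parameter recovery, model-structure
#' recovery) where calorimetry noise is not the object of study.
#'
#' @param true_jnd Vector of true JNDs, one per participant (percent).
#' @param blocks_per_participant,trials_per_block Study structure.
#' @param rate_range Net-rate range for the surrogate, W/kg.
#' @param lapse Generating lapse rate.
#' @return A comparisons data frame (`participant`, `block`, `pair`,
#'   `A_w_kg`, `B_w_kg`, `x_percent`, `response`) with the vector of true
#'   JNDs attached as attribute `true_jnd`.
#' @export
simulate_comparisons <- function(true_jnd, blocks_per_participant = 11,
                                 trials_per_block = 10,
                                 rate_range = c(1.5, 6.6), lapse = 0.02) {
  if (any(true_jnd <= 0)) stop("`true_jnd` must be positive")
  out <- list()
  for (p in seq_along(true_jnd)) {
    for (b in seq_len(blocks_per_participant)) {
      prof <- sample_torque_profile(trials_per_block)
      net <- surrogate_metabolic_rate(prof, rate_range)
      A <- net[-length(net)]
      B <- net[-1]
      x <- 100 * (B - A) / A
      r <- simulate_response(x, true_jnd[p], lapse)
      out[[length(out) + 1L]] <- data.frame(
        participant = p, block = b, pair = seq_along(x),
        A_w_kg = A, B_w_kg = B, x_percent = x, response = r
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "true_jnd") <- true_jnd
  res
}
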