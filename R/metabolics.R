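#' Fit a first-order transient to a breath-by-breath series
#'
#' Estimates the steady-state metabolic rate of a walking trial by
#' least-squares fitting of
#' `y(t) = y_ss + (y0 - y_ss) * exp(-t / tau)`
#' to the breath-by-breath data, via Levenberg-Marquardt with box
#' constraints. All three parameters are free; `tau` is bounded to
#' `tau_bounds` (default 10-120 s, bracketing the ~42 s cardiopulmonary
#' time constant) and initialized at `tau_init`. If the optimizer fails —
#' typically on a degenerate, transient-free series — the fallback estimate
#' is the mean of the final `fallback_window_s` seconds, with `tau` and `y0`
#' reported as `NA`.
#'
#' @param t Breath timestamps, seconds since trial start, strictly
#'   increasing.
#' @param y Instantaneous metabolic power at each breath, W/kg.
#' @param tau_bounds Length-2 bounds on the time constant, seconds.
#' @param tau_init Initial value for the time constant, seconds.
#' @param fallback_window_s Averaging window used when the fit fails.
#' @return A list of class `first_order_fit`: `y_ss`, `y0`, `tau`, `rss`,
#'   `converged` (logical; `FALSE` means the fallback was used), `n`.
#' @examples
#' t <- seq(0, 120, by = 4)
#' y <- 3 + (1 - 3) * exp(-t / 42)
#' fit_first_order(t, y)
#' @export
fit_first_order <- function(t, y, tau_bounds = c(10, 120), tau_init = 42,
                            fallback_window_s = 60) {
  if (length(t) != length(y)) stop("`t` and `y` lengths differ")
  if (length(t) < 5) stop("need at least 5 breaths to fit a transient")
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  if (!all(is.finite(y))) stop("`y` must be finite")
  stopifnot(tau_bounds[1] > 0, tau_bounds[1] < tau_bounds[2])

  tail_mean <- mean(y[t >= max(t) - fallback_window_s])
  start <- list(y_ss = tail_mean, y0 = y[1], tau = tau_init)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y_ss + (y0 - y_ss) * exp(-t / tau),
      start = start,
      lower = c(y_ss = -Inf, y0 = -Inf, tau = tau_bounds[1]),
      upper = c(y_ss = Inf, y0 = Inf, tau = tau_bounds[2]),
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(y_ss = tail_mean, y0 = y[1], tau = NA_real_,
                rss = sum((y - tail_mean)^2), converged = FALSE,
                n = length(t))
  } else {
    cf <- stats::coef(fit)
    out <- list(y_ss = unname(cf["y_ss"]), y0 = unname(cf["y0"]),
                tau = unname(cf["tau"]),
                rss = sum(stats::residuals(fit)^2), converged = TRUE,
                n = length(t))
  }
  class(out) <- "first_order_fit"
  out
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("First-order transient fit (n = %d breaths)\n", x$n))
  cat(sprintf("  y_ss = %.4f W/kg, y0 = %.4f W/kg, tau = %s s, rss = %.4g%s\n",
              x$y_ss, x$y0,
              if (is.na(x$tau)) "NA" else sprintf("%.1f", x$tau), x$rss,
              if (x$converged) "" else "  [fallback: mean of final window]"))
  invisible(x)
}

#' Standing baseline metabolic rate
#'
#' The baseline is the arithmetic mean of instantaneous metabolic power over
#' the quiet-standing interval (four minutes in the reference protocol).
#'
#' @param y Breath-by-breath power over the standing interval, W/kg.
#' @return Mean rate, W/kg.
#' @export
standing_baseline <- function(y) {
  if (length(y) == 0) stop("empty standing series")
  if (!all(is.finite(y))) stop("standing series must be finite")
  mean(y)
}

#' Net metabolic rate
#'
#' Subtracts the standing baseline from a trial's steady-state rate to
#' isolate the energetic effect of the walking condition. A non-positive net
#' rate is physiologically pathological (walking costing less than standing)
#' but can arise from measurement noise; it is returned as-is with a warning
#' so the caller can drop the affected comparisons.
#'
#' @param y_ss Steady-state rate(s), W/kg.
#' @param baseline Standing baseline rate, W/kg.
#' @return `y_ss - baseline`, W/kg.
#' @export
net_rate <- function(y_ss, baseline) {
  stopifnot(all(is.finite(y_ss)), is.finite(baseline))
  net <- y_ss - baseline
  n_bad <- sum(net <= 0)
  if (n_bad > 0) {
    warning(n_bad, " non-positive net rate(s); affected comparisons should be dropped")
  }
  net
}

#' Estimate per-trial net steady-state rates for a whole study
#'
#' Applies [fit_first_order()] to every trial's breath series,
#' [standing_baseline()] to each participant's standing series, and returns
#' the trials table augmented with `y_ss_w_kg`, `baseline_w_kg` and
#' `net_w_kg` columns.
#'
#' @param study A `jnd_study` (or any list with `trials`, `breaths`,
#'   `standing` data frames in the same schema).
#' @param ... Passed on to [fit_first_order()].
#' @return The `trials` data frame with estimated-rate columns added.
#' @export
estimate_trial_rates <- function(study, ...) {
  trials <- study$trials
  baselines <- vapply(
    split(study$standing$power_w_kg, study$standing$participant),
    standing_baseline, numeric(1))
  key <- interaction(study$breaths$participant, study$breaths$block,
                     study$breaths$trial, drop = TRUE)
  idx <- split(seq_len(nrow(study$breaths)), key)
  trial_key <- as.character(interaction(trials$participant, trials$block,
                                        trials$trial, drop = TRUE))
  y_ss <- vapply(trial_key, function(k) {
    i <- idx[[k]]
    if (is.null(i)) stop("no breath series for trial key ", k)
    fit_first_order(study$breaths$t_s[i], study$breaths$power_w_kg[i], ...)$y_ss
  }, numeric(1))
  trials$y_ss_w_kg <- unname(y_ss)
  trials$baseline_w_kg <- unname(baselines[as.character(trials$participant)])
  net <- trials$y_ss_w_kg - trials$baseline_w_kg
  n_bad <- sum(net <= 0)
  if (n_bad > 0) {
    warning(n_bad, " trial(s) with non-positive net rate; ",
            "downstream comparisons using them as reference will be dropped")
  }
  trials$net_w_kg <- net
  trials
}

#' Build sequential forced-choice comparisons from ordered trials
#'
#' Within each `(participant, block)` group, pairs every consecutive trial
#' `(i, i+1)` into one comparison: the earlier trial's net rate is the
#' reference `A`, the later trial's is the comparison `B`, the stimulus is
#' the reference-normalized percent difference `x = 100 * (B - A) / A`, and
#' the response is the one given after trial `i+1`. Comparisons never span
#' block boundaries (rest between blocks breaks the sequential-reference
#' design). Pairs whose reference is non-positive are excluded — the ratio
#' statistic is undefined there — and counted in the `n_dropped` attribute.
#'
#' @param trials Data frame with columns `participant`, `block`, `trial`,
#'   `net_w_kg` and `response` (NA on the first trial of each block). Rows
#'   are ordered internally by (participant, block, trial).
#' @return Data frame of class `jnd_comparisons` with columns `participant`,
#'   `block`, `pair`, `A_w_kg`, `B_w_kg`, `x_percent`, `response`;
#'   attribute `n_dropped` counts excluded non-positive-reference pairs.
#' @export
build_comparisons <- function(trials) {
  req <- c("participant", "block", "trial", "net_w_kg", "response")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  o <- order(trials$participant, trials$block, trials$trial)
  trials <- trials[o, , drop = FALSE]
  key <- interaction(trials$participant, trials$block, drop = TRUE)
  if (anyDuplicated(paste(trials$participant, trials$block, trials$trial))) {
    stop("duplicate (participant, block, trial) keys")
  }
  out <- lapply(split(seq_len(nrow(trials)), key), function(i) {
    g <- trials[i, , drop = FALSE]
    if (nrow(g) < 2) return(NULL)
    if (anyNA(g$response[-1])) {
      stop("missing response on a non-first trial (participant ",
           g$participant[1], ", block ", g$block[1], ")")
    }
    n <- nrow(g)
    data.frame(
      participant = g$participant[1], block = g$block[1],
      pair = seq_len(n - 1),
      A_w_kg = g$net_w_kg[-n], B_w_kg = g$net_w_kg[-1],
      x_percent = 100 * (g$net_w_kg[-1] - g$net_w_kg[-n]) / g$net_w_kg[-n],
      response = as.integer(g$response[-1])
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  keep <- res$A_w_kg > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " comparison(s) with non-positive reference")
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$participant, res$block, res$pair), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- n_dropped
  class(res) <- c("jnd_comparisons", "data.frame")
  res
}
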