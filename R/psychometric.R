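#' Scale constant linking the logistic slope to the JND
#'
#' For the fixed-lapse logistic psychometric function used throughout this
#' package, the Just-Noticeable Difference (the stimulus change detected with
#' 75% accuracy) is `k / beta`, where `k` depends only on the fixed
#' false-positive rate `gamma` and lapse rate `lambda`:
#' \deqn{k = \tfrac{1}{2}\ln\!\left[\frac{(0.75-\gamma)(1-\lambda-0.25)}
#'   {(1-\lambda-0.75)(0.25-\gamma)}\right].}
#' With `gamma = lambda = 0` this reduces to `log(3)`.
#'
#' @param gamma False-positive (guess) rate; must be below 0.25.
#' @param lambda Lapse rate; must be below 0.25.
#' @return The scale constant `k` (unitless, positive).
#' @examples
#' scale_constant_k(0, 0)        # log(3)
#' scale_constant_k(0.02, 0.02)  # the analysis default, ~1.155
#' @export
scale_constant_k <- function(gamma = 0.02, lambda = 0.02) {
  stopifnot(is.numeric(gamma), is.numeric(lambda))
  if (any(gamma >= 0.25) || any(lambda >= 0.25) || any(gamma < 0) || any(lambda < 0)) {
    stop("scale_constant_k() requires 0 <= gamma < 0.25 and 0 <= lambda < 0.25")
  }
  num <- (0.75 - gamma) * (1 - lambda - 0.25)
  den <- (1 - lambda - 0.75) * (0.25 - gamma)
  0.5 * log(num / den)
}

#' Construct a fixed-lapse logistic psychometric model
#'
#' The model maps a reference-normalized stimulus difference `x` (percent
#' change in net metabolic rate between the comparison and the reference
#' trial) to the probability of responding "the comparison is greater":
#' \deqn{\Psi(x) = \gamma + \frac{1-\lambda-\gamma}{1 + e^{-\beta (x-\alpha)}}.}
#' The threshold `alpha` is fixed at 0 (no response bias), and `gamma` and
#' `lambda` are fixed constants of the analysis; the slope `beta` is the only
#' free parameter. Exactly one of `beta` or `jnd` must be supplied; the other
#' is derived through `jnd = k / beta`.
#'
#' @param jnd Just-Noticeable Difference in percent (> 0).
#' @param beta Logistic slope in units of per-percentage-point (> 0).
#' @param alpha Threshold point on the x axis (percent). Fixed at 0 in the
#'   standard analysis.
#' @param gamma False-positive rate in `[0, 0.25)`.
#' @param lambda Lapse rate in `[0, 0.25)`.
#' @return An object of class `psychometric_model`: a list with elements
#'   `alpha`, `beta`, `gamma`, `lambda`, `k` and `jnd`.
#' @examples
#' m <- psychometric_model(jnd = 22.7)
#' psychometric_prob(c(0, 9.6, 22.7), m)
#' @export
psychometric_model <- function(jnd = NULL, beta = NULL, alpha = 0,
                               gamma = 0.02, lambda = 0.02) {
  if (is.null(jnd) == is.null(beta)) {
    stop("supply exactly one of `jnd` or `beta`")
  }
  if (gamma + lambda >= 0.5) stop("gamma + lambda must be < 0.5")
  k <- scale_constant_k(gamma, lambda)
  if (is.null(beta)) {
    if (jnd <= 0) stop("`jnd` must be positive")
    beta <- k / jnd
  } else {
    if (beta <= 0) stop("`beta` must be positive")
    jnd <- k / beta
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
         k = k, jnd = jnd),
    class = "psychometric_model"
  )
}

#' @export
print.psychometric_model <- function(x, ...) {
  cat("Fixed-lapse logistic psychometric model\n")
  cat(sprintf("  slope beta  : %.5f per percent\n", x$beta))
  cat(sprintf("  JND (k/beta): %.2f %%\n", x$jnd))
  cat(sprintf("  alpha = %g, gamma = %g, lambda = %g, k = %.5f\n",
              x$alpha, x$gamma, x$lambda, x$k))
  invisible(x)
}

#' Evaluate the psychometric function
#'
#' @param x Stimulus difference(s), percent change of net metabolic rate
#'   relative to the reference.
#' @param model A [psychometric_model()].
#' @return Probability of responding "greater" for each `x`; strictly
#'   increasing in `x` and bounded in `(gamma, 1 - lambda)`.
#' @export
psychometric_prob <- function(x, model) {
  stopifnot(inherits(model, "psychometric_model"))
  model$gamma + (1 - model$lambda - model$gamma) /
    (1 + exp(-model$beta * (x - model$alpha)))
}

#' Convert between the logistic slope and the JND
#'
#' The two are reciprocal up to the scale constant `k`: `jnd = k / beta`.
#'
#' @param beta Slope (per percentage point), positive.
#' @param jnd JND (percent), positive.
#' @param k Scale constant, e.g. from [scale_constant_k()].
#' @return The converted quantity.
#' @seealso [scale_constant_k()]
#' @export
jnd_from_beta <- function(beta, k = scale_constant_k()) {
  if (any(beta <= 0)) stop("`beta` must be positive")
  k / beta
}

#' @rdname jnd_from_beta
#' @export
beta_from_jnd <- function(jnd, k = scale_constant_k()) {
  if (any(jnd <= 0)) stop("`jnd` must be positive")
  k / jnd
}

# Invert the monotone psychometric function at probability p by bisection.
# Unconditionally safe because Psi is strictly increasing.
invert_psychometric <- function(p, model, tol = 1e-10) {
  if (p <= model$gamma || p >= 1 - model$lambda) {
    stop("probability outside the attainable range (gamma, 1 - lambda)")
  }
  f <- function(x) psychometric_prob(x, model) - p
  lo <- model$alpha - 1
  hi <- model$alpha + 1
  while (f(lo) > 0) lo <- model$alpha - 2 * (model$alpha - lo)
  while (f(hi) < 0) hi <- model$alpha + 2 * (hi - model$alpha)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' JND from the quartile construction
#'
#' Computes the JND as defined operationally: half the distance between the
#' stimulus values at which the psychometric function crosses 0.75 and 0.25.
#' For the fixed-lapse logistic this equals `k / beta` analytically (the
#' closed form is derived from exactly this construction), so the function
#' serves as a numerical cross-check of the conversion.
#'
#' @param model A [psychometric_model()].
#' @param tol Bisection tolerance on the stimulus axis.
#' @return JND in percent.
#' @export
jnd_from_quartiles <- function(model, tol = 1e-10) {
  x75 <- invert_psychometric(0.75, model, tol = tol)
  x25 <- invert_psychometric(0.25, model, tol = tol)
  (x75 - x25) / 2
}

#' Bernoulli log-likelihood of forced-choice responses
#'
#' Sums `r * log(Psi(x)) + (1 - r) * log(1 - Psi(x))` over comparisons, with
#' the slope set through `beta = k / jnd`. Always finite because `Psi` is
#' bounded away from 0 and 1 whenever `gamma > 0` and `lambda > 0`.
#'
#' @param x Stimulus differences (percent), one per comparison.
#' @param response Binary responses (0/1), same length as `x`.
#' @param jnd Candidate JND in percent (> 0).
#' @param gamma,lambda Fixed false-positive and lapse rates.
#' @param alpha Threshold point (percent), 0 by default.
#' @return Scalar log-likelihood.
#' @export
response_log_likelihood <- function(x, response, jnd,
                                    gamma = 0.02, lambda = 0.02, alpha = 0) {
  if (length(x) != length(response)) stop("`x` and `response` lengths differ")
  if (!all(response %in% c(0, 1))) stop("`response` must be 0/1")
  if (jnd <= 0) stop("`jnd` must be positive")
  m <- psychometric_model(jnd = jnd, alpha = alpha, gamma = gamma, lambda = lambda)
  p <- psychometric_prob(x, m)
  sum(response * log(p) + (1 - response) * log1p(-p))
}
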