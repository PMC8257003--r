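#' Bias profile of an agent's prior
#'
#' A bias profile describes an agent's a-priori preference over the two
#' variants of a binary linguistic feature as a Beta distribution over the
#' Bernoulli parameter \eqn{h} (the probability of producing variant "1").
#' `mu0` is the mode of that prior (the preferred value of \eqn{h}) and
#' `lambda0` its strength on a 0--1 scale: `lambda0 = 0` is an immovable
#' ("fixed") preference that no amount of data can shift, values near 1 give
#' a near-flat, weakly held preference.
#'
#' @param mu0 Mode of the prior Beta distribution, strictly inside (0, 1).
#' @param lambda0 Bias-strength parameter in \[0, 1\]; 0 means fixed.
#' @return An object of class `"bias_profile"`: a list with elements
#'   `mu0`, `lambda0` and `fixed` (`TRUE` iff `lambda0 == 0`).
#' @examples
#' bias_profile(0.1, 0.6)   # a flexible bias towards variant "0"
#' bias_profile(0.5, 0.9)   # the near-flat unbiased profile
#' @export
bias_profile <- function(mu0, lambda0) {
  stopifnot(is.numeric(mu0), length(mu0) == 1L, is.finite(mu0),
            is.numeric(lambda0), length(lambda0) == 1L, is.finite(lambda0))
  if (mu0 <= 0 || mu0 >= 1)
    stop("'mu0' must lie strictly in (0, 1)", call. = FALSE)
  if (lambda0 < 0 || lambda0 > 1)
    stop("'lambda0' must lie in [0, 1]", call. = FALSE)
  structure(list(mu0 = mu0, lambda0 = lambda0, fixed = lambda0 == 0),
            class = "bias_profile")
}

#' @export
print.bias_profile <- function(x, ...) {
  cat(sprintf("Bias profile: mode mu0 = %g, strength lambda0 = %g%s\n",
              x$mu0, x$lambda0, if (x$fixed) " (fixed)" else ""))
  invisible(x)
}

# Concentration nu of the prior as a function of bias strength:
# nu = 70 * (1 - lambda0)^2. Near-flat at lambda0 = 0.9 (nu = 0.7),
# moderately concentrated at 0.6 (nu = 11.2), strongly peaked and slow to
# move at 0.1 (nu = 56.7). The constants are calibrated so that replicated
# 150-agent sweeps reproduce the published aggregated language values of
# the systematic bias-effects design (see the methods vignette); the
# mapping is isolated here so alternatives can be swapped in. lambda0 = 0
# never reaches this function: it is the qualitatively distinct fixed
# (point-mass) agent, handled in prior_from_bias().
prior_concentration <- function(lambda0) {
  70 * (1 - lambda0)^2
}

#' Beta prior parameters induced by a bias profile
#'
#' Maps a `(mu0, lambda0)` bias profile to the shape parameters
#' `(alpha0, beta0)` of the agent's prior Beta distribution. With
#' concentration \eqn{\nu = 70 (1 - \lambda_0)^2}, the mapping is
#' \eqn{\alpha_0 = 1 + \mu_0 \nu}, \eqn{\beta_0 = 1 + (1 - \mu_0)\nu},
#' which guarantees \eqn{\alpha_0, \beta_0 \ge 1}, places the mode of the
#' density exactly at `mu0`, and makes the density flatter as `lambda0`
#' grows; the scale and exponent of \eqn{\nu} are calibrated against
#' published replicated-sweep outcomes (see the methods vignette). A fixed
#' profile (`lambda0 = 0`) corresponds to a point mass at `mu0` and is
#' returned as a fixed marker instead of shape parameters.
#'
#' @param profile A [bias_profile()].
#' @return For `lambda0 > 0`, a named numeric vector `c(alpha, beta)`.
#'   For `lambda0 = 0`, a list with `fixed = TRUE` and `value = mu0`.
#' @examples
#' prior_from_bias(bias_profile(0.5, 0.9))  # near-flat around 0.5
#' prior_from_bias(bias_profile(0.1, 0))    # fixed point mass at 0.1
#' @export
prior_from_bias <- function(profile) {
  if (!inherits(profile, "bias_profile"))
    profile <- bias_profile(profile$mu0, profile$lambda0)
  if (profile$fixed)
    return(list(fixed = TRUE, value = profile$mu0))
  nu <- prior_concentration(profile$lambda0)
  c(alpha = 1 + profile$mu0 * nu, beta = 1 + (1 - profile$mu0) * nu)
}

#' Conjugate Beta posterior update from a batch of utterances
#'
#' Given current shape parameters and a batch of `n` heard utterances of
#' which `k` were variant "1", returns the posterior shape parameters
#' `(alpha + k, beta + n - k)`. The Beta prior is conjugate to the
#' Bernoulli/binomial likelihood, so updating reduces to count arithmetic.
#'
#' @param alpha,beta Current shape parameters, each at least 1.
#' @param k Number of "1" utterances heard (nonnegative).
#' @param n Total number of utterances heard (`n >= k`).
#' @return Named numeric vector `c(alpha, beta)` of the posterior.
#' @examples
#' update_posterior(2, 10, k = 4, n = 4)  # -> alpha 6, beta 10
#' @export
update_posterior <- function(alpha, beta, k, n) {
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha >= 1, beta >= 1)
  if (!is.numeric(k) || !is.numeric(n) || k < 0 || n < 0 || k > n)
    stop("invalid utterance batch: need 0 <= k <= n", call. = FALSE)
  c(alpha = unname(alpha + k), beta = unname(beta + n - k))
}

#' Mode of a Beta distribution with both shapes at least 1
#'
#' The mode \eqn{(\alpha - 1)/(\alpha + \beta - 2)} of a Beta density, which
#' is the agent's language value. In the degenerate uniform case
#' \eqn{\alpha = \beta = 1} the mode is taken to be 0.5 (symmetric limit).
#'
#' @param alpha,beta Shape parameters, each at least 1. Vectorized.
#' @return Mode(s) in \[0, 1\].
#' @examples
#' beta_mode(6, 10)  # 5/14
#' beta_mode(1, 1)   # 0.5 by convention
#' @export
beta_mode <- function(alpha, beta) {
  if (any(alpha < 1) || any(beta < 1))
    stop("beta_mode() requires alpha >= 1 and beta >= 1", call. = FALSE)
  den <- alpha + beta - 2
  ifelse(den <= 0, 0.5, (alpha - 1) / den)
}

#' Produce utterances from an agent state
#'
#' An agent produces a binary utterance in two steps: it first settles on a
#' language value \eqn{h} -- a SAM ("sampler") agent draws
#' \eqn{h \sim Beta(\alpha, \beta)} afresh for every utterance, a MAP agent
#' always uses the posterior mode, and a fixed agent always uses `mu0` --
#' and then throws a coin, emitting "1" with probability \eqn{h}. Producing
#' never alters the producer's own state.
#'
#' @param alpha,beta Shape parameters of the agent's current Beta belief
#'   (ignored for fixed agents).
#' @param strategy `"SAM"` or `"MAP"`.
#' @param fixed_value If non-`NULL`, the agent is fixed and emits
#'   `Bernoulli(fixed_value)` regardless of `alpha`, `beta`, `strategy`.
#' @param ndraws Number of independent utterances to produce.
#' @return Integer vector of 0/1 utterances of length `ndraws`.
#' @examples
#' set.seed(1)
#' mean(produce_utterance(6, 10, "SAM", ndraws = 1e4))  # ~ 6/16
#' @export
produce_utterance <- function(alpha, beta, strategy = c("SAM", "MAP"),
                              fixed_value = NULL, ndraws = 1L) {
  if (!is.null(fixed_value)) {
    stopifnot(fixed_value >= 0, fixed_value <= 1)
    return(stats::rbinom(ndraws, 1L, fixed_value))
  }
  strategy <- match.arg(strategy)
  h <- switch(strategy,
              SAM = stats::rbeta(ndraws, alpha, beta),
              MAP = rep(beta_mode(alpha, beta), ndraws))
  stats::rbinom(ndraws, 1L, h)
}

#' Language value of an agent
#'
#' The language value is the mode of the Beta distribution representing the
#' agent's internal belief about the frequency of variant "1"; for a fixed
#' agent it is the constant `mu0`.
#'
#' @inheritParams produce_utterance
#' @return Language value(s) in \[0, 1\].
#' @export
agent_language_value <- function(alpha, beta, fixed_value = NULL) {
  if (!is.null(fixed_value)) return(fixed_value)
  beta_mode(alpha, beta)
}
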