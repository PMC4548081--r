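# Hyperbolic discounting value model and softmax choice rule.

#' Hyperbolic subjective value
#'
#' Subjective value of an amount `A` delivered after delay `D` under hyperbolic
#' discounting with rate `k`: `SV = A / (1 + k * D)`. Strictly decreasing in
#' both `k` and `D` (for `D > 0`); `k = 0` disables discounting.
#'
#' @param A amount (EUR), > 0. Vectorized.
#' @param k discount rate (1/days), >= 0.
#' @param D delay (days), >= 0.
#' @return subjective value in EUR.
#' @export
#' @examples
#' subjective_value(40, 0.1, 10) # 20
subjective_value <- function(A, k, D) {
  if (any(A <= 0)) stop("amounts must be > 0")
  if (any(k < 0)) stop("discount rate k must be >= 0")
  if (any(D < 0)) stop("delay D must be >= 0")
  A / (1 + k * D)
}

#' Softmax probability of choosing the larger-but-later option
#'
#' Converts the subjective values of the larger-but-later (LL) and
#' smaller-but-sooner (SS) options into a choice probability,
#' `p_LL = exp(SV_LL / beta) / (exp(SV_LL / beta) + exp(SV_SS / beta))`,
#' evaluated in the overflow-safe logistic form
#' `1 / (1 + exp(-(SV_LL - SV_SS) / beta))`.
#'
#' `beta` is a temperature divisor: larger `beta` means noisier choice
#' (p -> 0.5), smaller `beta` means more deterministic value maximisation.
#'
#' @param sv_ll,sv_ss subjective values (EUR). Vectorized.
#' @param beta decision noise (EUR), > 0.
#' @return probability of an LL choice; `p_LL + p_SS = 1` by construction.
#' @export
#' @examples
#' choice_probability(21, 20, 1) # plogis(1) = 0.7310586
choice_probability <- function(sv_ll, sv_ss, beta) {
  if (any(beta <= 0)) stop("beta must be > 0")
  if (any(!is.finite(sv_ll)) || any(!is.finite(sv_ss))) stop("values must be finite")
  stats::plogis((sv_ll - sv_ss) / beta)
}

#' Bernoulli log-likelihood of a choice dataset at fixed (k, beta)
#'
#' Sums `log p_LL` over LL choices and `log(1 - p_LL)` over SS choices, with
#' per-trial probabilities from the hyperbolic value model and softmax rule.
#' Used by tests as a likelihood oracle and by the shrinkage diagnostics for
#' independent (no-pooling) maximum-likelihood fits.
#'
#' @param trials a choice-trial data frame (see [choice_columns()]).
#' @param k,beta parameter values.
#' @return scalar log-likelihood.
#' @export
choice_loglik <- function(trials, k, beta) {
  sv_ll <- subjective_value(trials$ll_amount, k, trials$ll_delay)
  sv_ss <- subjective_value(trials$ss_amount, k, trials$ss_delay)
  d <- (sv_ll - sv_ss) / beta
  y <- trials$choice == "LL"
  # log probabilities evaluated on the log scale so near-deterministic trials
  # do not underflow to log(0)
  sum(stats::plogis(ifelse(y, d, -d), log.p = TRUE))
}
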