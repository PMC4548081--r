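# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' Expands a single master seed into independent substream seeds so that, e.g.,
#' adding or removing a participant does not perturb the random draws of the
#' others. A small multiplicative hash keeps results inside the 32-bit integer
#' range R requires for `set.seed()`.
#'
#' @param seed master seed (single integer).
#' @param index substream index (participant number, stage number, ...).
#' @param stream optional character tag separating named streams that share an
#'   index (e.g. "cohort" vs "task").
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, index, stream = "") {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream))) %% 1000003
  # 2^31 - 1 is prime; coefficients are arbitrary odd constants
  val <- (as.double(seed) %% 2147483647) * 69621 + index * 19349663 + h * 83492791
  as.integer(val %% 2147483647)
}

#' Truncated normal draws via inverse-CDF sampling
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal; `sd = 0` returns
#'   the mean clamped into the bounds.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower <= upper)
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  out <- stats::qnorm(u, mean, sd)
  # guard against qnorm(1) = Inf from floating-point round-up
  pmin(pmax(out, lower), upper)
}

#' Mean of a truncated normal distribution
#' @keywords internal
truncnorm_mean <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  out <- mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  # far-tail evaluations lose precision; the true mean always lies inside
  min(max(out, lower), upper)
}

#' Parent-normal location giving a target truncated mean
#'
#' Truncating a normal at (lower, upper) shifts its mean; this solves for the
#' parent location `mu` such that the truncated distribution has exactly the
#' requested mean, so configured covariate means are the sampling means.
#'
#' @keywords internal
match_truncnorm_mean <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  if (target <= lower || target >= upper) {
    stop("target mean must lie strictly inside the truncation bounds")
  }
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, lower, upper) - target,
                 interval = c(target - 6 * sd, target + 6 * sd),
                 extendInt = "upX", tol = 1e-10)$root
}

#' z-transform a vector
#' @param x numeric vector with non-zero variance.
#' @return `(x - mean(x)) / sd(x)`.
#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-transform a constant (zero-variance) vector")
  }
  (x - mean(x)) / s
}

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (strict && x <= lower) stop(sprintf("'%s' must be > %g", name, lower))
  if (!strict && x < lower) stop(sprintf("'%s' must be >= %g", name, lower))
  invisible(TRUE)
}
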