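# MCMC plumbing shared by the discounting and rating-model fits: sampler
# settings, seeding, and convergence diagnostics computed from raw samples.

#' MCMC sampler settings
#'
#' @param chains number of chains (>= 1; >= 2 needed for split-R-hat).
#' @param adapt JAGS adaptation iterations.
#' @param burnin discarded iterations after adaptation.
#' @param draws retained iterations per chain.
#' @param thin thinning interval.
#' @return list of class `td_mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, adapt = 500, burnin = 500, draws = 1000,
                        thin = 1) {
  stopifnot(chains >= 1, adapt >= 100, burnin >= 0, draws >= 100, thin >= 1)
  structure(list(chains = chains, adapt = adapt, burnin = burnin,
                 draws = draws, thin = thin),
            class = "td_mcmc_config")
}

# deterministic per-chain RNG inits for JAGS
jags_inits <- function(seed, chains, extra = NULL) {
  lapply(seq_len(chains), function(ch) {
    c(extra, list(.RNG.name = "base::Mersenne-Twister",
                  .RNG.seed = derive_seed(seed, ch, "jags")))
  })
}

run_jags <- function(model_string, data, monitor, config, seed, inits_extra = NULL) {
  inits <- jags_inits(seed, config$chains, inits_extra)
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = config$chains,
                          n.adapt = config$adapt, quiet = TRUE)
  if (config$burnin > 0) update(jm, config$burnin, progress.bar = "none")
  rjags::coda.samples(jm, monitor, n.iter = config$draws, thin = config$thin,
                      progress.bar = "none")
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends are detected even with a single chain.
#'
#' @param x iterations x chains matrix of posterior draws for one parameter.
#' @return scalar R-hat (1 = converged; values > ~1.05 indicate trouble).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  pieces <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# diagnostics for an mcmc.list restricted to `pars`
mcmc_diagnostics <- function(samples, pars = NULL) {
  mat1 <- as.matrix(samples[[1]])
  if (is.null(pars)) pars <- colnames(mat1)
  rhat <- vapply(pars, function(p) {
    split_rhat(sapply(samples, function(ch) as.matrix(ch)[, p]))
  }, numeric(1))
  ess <- tryCatch({
    e <- coda::effectiveSize(samples)
    e[pars]
  }, error = function(e) rep(NA_real_, length(pars)))
  data.frame(parameter = pars, rhat = rhat, ess = as.numeric(ess),
             row.names = NULL, stringsAsFactors = FALSE)
}
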