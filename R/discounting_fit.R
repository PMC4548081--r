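# Hierarchical Bayesian estimation of the hyperbolic discount rate k and
# softmax decision noise beta, with separate group-level distributions.
#
# Participant-level (log k, log beta) are drawn from group-specific normal
# distributions; per-trial choices are Bernoulli with the softmax probability
# of the larger-but-later option. Group placement on the log scale enforces
# positivity of k and beta and is the standard identifiable choice.

hier_model_string <- function() {
"model {
  for (g in 1:G) {
    mu_k[g] ~ dnorm(mu_k_mean, mu_k_prec)
    la_k[g] ~ dgamma(la_shape, la_rate)
    mu_b[g] ~ dnorm(mu_b_mean, mu_b_prec)
    la_b[g] ~ dgamma(la_shape, la_rate)
  }
  for (s in 1:S) {
    log_k[s] ~ dnorm(mu_k[grp[s]], la_k[grp[s]])
    log_beta[s] ~ dnorm(mu_b[grp[s]], la_b[grp[s]])
  }
  for (t in 1:N) {
    sv_ll[t] <- ll_amt[t] / (1 + exp(log_k[sub[t]]) * ll_del[t])
    sv_ss[t] <- ss_amt[t] / (1 + exp(log_k[sub[t]]) * ss_del[t])
    # squash away from 0/1 so deterministic-looking choices stay on support
    p[t] <- 1.0E-6 + (1 - 2.0E-6) * ilogit((sv_ll[t] - sv_ss[t]) / exp(log_beta[sub[t]]))
    y[t] ~ dbern(p[t])
  }
}"
}

#' Weakly informative hyperpriors for the hierarchical discounting model
#'
#' Group means of log k are Normal(-4, 2^2) (k around 0.018/day, spanning
#' roughly 0.0003-1/day within 2 SD), group means of log beta Normal(0, 2^2)
#' (beta around 1 EUR), and group precisions Gamma(1, 0.5). All exposed for
#' overriding.
#'
#' @param mu_logk_mean,mu_logk_sd prior on group means of log k.
#' @param mu_logbeta_mean,mu_logbeta_sd prior on group means of log beta.
#' @param lambda_shape,lambda_rate Gamma prior on group precisions.
#' @return named list of hyperprior constants.
#' @export
hier_priors <- function(mu_logk_mean = -4, mu_logk_sd = 2,
                        mu_logbeta_mean = 0, mu_logbeta_sd = 2,
                        lambda_shape = 1, lambda_rate = 0.5) {
  list(mu_k_mean = mu_logk_mean, mu_k_prec = 1 / mu_logk_sd^2,
       mu_b_mean = mu_logbeta_mean, mu_b_prec = 1 / mu_logbeta_sd^2,
       la_shape = lambda_shape, la_rate = lambda_rate)
}

#' Fit the hierarchical discounting model
#'
#' @param trials tidy choice table covering all participants (columns of
#'   [choice_columns()]); every participant needs at least `min_trials`
#'   choices.
#' @param groups named character vector mapping participant id to group label
#'   (e.g. "HC"/"PG"); every id in `trials` must be present.
#' @param config a [mcmc_config()].
#' @param seed integer seed (drives all chains deterministically).
#' @param priors a [hier_priors()] list.
#' @param min_trials minimum choices per participant (default 10).
#' @param on_nonconvergence "error" (default) aborts when any monitored
#'   parameter has split-R-hat > 1.05; "warn" downgrades to a warning.
#' @return object of class `td_hfit`: list with
#'   \describe{
#'     \item{participants}{data frame: id, group, n_trials, median_k, log_k
#'       (natural log of the posterior-median k), median_beta, rhat/ess per
#'       participant parameter.}
#'     \item{groups}{data frame of group-level posterior medians
#'       (mu_logk, sd_logk, mu_logbeta, sd_logbeta).}
#'     \item{samples}{`coda::mcmc.list` of all monitored parameters.}
#'     \item{diagnostics}{per-parameter split-R-hat and effective sample size.}
#'     \item{converged}{logical.}
#'   }
#' @export
fit_hierarchical <- function(trials, groups, config = mcmc_config(), seed = 1L,
                             priors = hier_priors(), min_trials = 10,
                             on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  validate_choices(trials)
  ids <- unique(trials$id)
  if (!all(ids %in% names(groups))) {
    stop("unknown group label: every participant id needs an entry in 'groups'")
  }
  counts <- table(trials$id)
  if (any(counts < min_trials)) {
    stop("every participant needs at least ", min_trials, " choices")
  }
  y <- as.integer(trials$choice == "LL")
  per_id_var <- tapply(y, trials$id, function(v) stats::var(v))
  if (all(per_id_var == 0)) {
    warning("all participants made identical choices on every trial; ",
            "parameters are weakly identified and posteriors will be wide")
  }
  glab <- sort(unique(as.character(groups[ids])))
  grp_idx <- match(as.character(groups[ids]), glab)
  sub_idx <- match(trials$id, ids)

  data <- c(list(G = length(glab), S = length(ids), N = nrow(trials),
                 grp = grp_idx, sub = sub_idx,
                 ll_amt = trials$ll_amount, ll_del = trials$ll_delay,
                 ss_amt = trials$ss_amount, ss_del = trials$ss_delay,
                 y = y),
            priors)
  monitor <- c("log_k", "log_beta", "mu_k", "la_k", "mu_b", "la_b")
  samples <- run_jags(hier_model_string(), data, monitor, config, seed,
                      inits_extra = list(log_k = rep(priors$mu_k_mean, length(ids)),
                                         log_beta = rep(priors$mu_b_mean, length(ids))))

  all_mat <- do.call(rbind, lapply(samples, as.matrix))
  med <- apply(all_mat, 2, stats::median)
  diag <- if (config$chains >= 2) mcmc_diagnostics(samples) else
    data.frame(parameter = colnames(all_mat), rhat = NA_real_, ess = NA_real_)
  converged <- all(is.na(diag$rhat)) || max(diag$rhat, na.rm = TRUE) <= 1.05
  if (!converged) {
    msg <- sprintf("MCMC did not converge: max split-R-hat = %.3f",
                   max(diag$rhat, na.rm = TRUE))
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }

  pk <- med[sprintf("log_k[%d]", seq_along(ids))]
  pb <- med[sprintf("log_beta[%d]", seq_along(ids))]
  participants <- data.frame(
    id = ids, group = glab[grp_idx[match(ids, ids)]],
    n_trials = as.integer(counts[ids]),
    median_k = exp(unname(pk)), log_k = unname(pk),
    median_beta = exp(unname(pb)),
    stringsAsFactors = FALSE)
  participants$group <- as.character(groups[ids])
  rhk <- diag$rhat[match(sprintf("log_k[%d]", seq_along(ids)), diag$parameter)]
  participants$rhat_log_k <- rhk

  groups_df <- data.frame(
    group = glab,
    mu_logk = unname(med[sprintf("mu_k[%d]", seq_along(glab))]),
    sd_logk = 1 / sqrt(unname(med[sprintf("la_k[%d]", seq_along(glab))])),
    mu_logbeta = unname(med[sprintf("mu_b[%d]", seq_along(glab))]),
    sd_logbeta = 1 / sqrt(unname(med[sprintf("la_b[%d]", seq_along(glab))])),
    stringsAsFactors = FALSE)

  structure(list(participants = participants, groups = groups_df,
                 samples = samples, diagnostics = diag, converged = converged,
                 config = config, priors = priors),
            class = "td_hfit")
}

#' Refit discounting on the combined trials of two tasks
#'
#' Concatenates the adaptive-task and fixed-item trials of each participant and
#' refits the hierarchical model, mirroring the combined-task analysis used
#' when single-task discount rates prove highly reliable across tasks.
#'
#' @param adaptive,fixed tidy choice tables for the same participants.
#' @param groups,config,seed,priors,... passed to [fit_hierarchical()].
#' @return a `td_hfit` on the concatenated data.
#' @export
combine_and_refit <- function(adaptive, fixed, groups, config = mcmc_config(),
                              seed = 1L, priors = hier_priors(), ...) {
  ids_a <- sort(unique(adaptive$id))
  ids_f <- sort(unique(fixed$id))
  if (!identical(ids_a, ids_f)) {
    stop("participant mismatch between tasks: the two datasets must cover ",
         "the same participants")
  }
  fit_hierarchical(rbind(adaptive, fixed), groups, config = config, seed = seed,
                   priors = priors, ...)
}

#' Per-participant log discount rates from a hierarchical fit
#'
#' Natural log of the posterior-median k per participant — the summary scale
#' used for all group comparisons and regressions, since raw k distributions
#' are strongly right-skewed.
#'
#' @param fit a `td_hfit`.
#' @return data frame with id, group, median_k, log_k.
#' @export
summarize_log_k <- function(fit) {
  stopifnot(inherits(fit, "td_hfit"))
  fit$participants[, c("id", "group", "median_k", "log_k")]
}

#' Independent (no-pooling) maximum-likelihood fit of one participant
#'
#' Maximizes the Bernoulli likelihood over (log k, log beta): a coarse grid
#' search over the full plausible range locates the global maximum, then
#' Nelder-Mead polishes it. Used as the unshrunken reference when checking the
#' hierarchical model's shrinkage behaviour. With few or perfectly consistent
#' choices the likelihood has flat ridges; the reported maximizer is then the
#' first grid point attaining the maximum (the instability of unpooled fits on
#' weak data is exactly what hierarchical pooling repairs).
#'
#' @param trials choice table of a single participant.
#' @param start optional starting values c(log_k, log_beta) tried in addition
#'   to the grid.
#' @param grid_log_k,grid_log_beta grid-search supports.
#' @return list with `log_k`, `log_beta`, `loglik`, `convergence`.
#' @export
fit_choice_mle <- function(trials, start = NULL,
                           grid_log_k = seq(-12, 2, by = 0.5),
                           grid_log_beta = seq(-4, 3, by = 0.5)) {
  nll <- function(par) {
    -choice_loglik(trials, exp(par[1]), exp(par[2]))
  }
  grid <- as.matrix(expand.grid(log_k = grid_log_k, log_beta = grid_log_beta))
  vals <- apply(grid, 1, nll)
  best <- grid[which.min(vals), ]
  if (!is.null(start) && nll(start) < min(vals)) best <- start
  opt <- stats::optim(best, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  list(log_k = unname(opt$par[1]), log_beta = unname(opt$par[2]),
       loglik = -opt$value, convergence = opt$convergence)
}

#' @export
print.td_hfit <- function(x, ...) {
  cat("Hierarchical discounting fit:", nrow(x$participants), "participants,",
      length(x$samples), "chains\n")
  cat("converged:", x$converged,
      "| max split-R-hat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Write posterior summaries of a hierarchical fit to CSV
#' @param fit a `td_hfit`.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_hfit_summary <- function(fit, path) {
  utils::write.csv(fit$participants, path, row.names = FALSE)
  invisible(path)
}
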