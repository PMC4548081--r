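# Shared fixtures: fast MCMC settings, deterministic agent profiles, and
# rating-law parameter samplers used by the model-selection experiments.

fast_mcmc <- function() mcmc_config(chains = 2, adapt = 300, burnin = 200, draws = 600)

# agent with known parameters; beta = 0 gives the deterministic value maximiser
make_profile <- function(id = "p1", k = 0.05, beta = 0, a_time = 0.06,
                         b_time = 0.5, a_circ = 1, b_circ = 1, pi = Inf) {
  data.frame(id = id, k = k, log_k = log(k), beta = beta, a_time = a_time,
             b_time = b_time, a_circ = a_circ, b_circ = b_circ, pi = pi,
             stringsAsFactors = FALSE)
}

# generating-parameter samplers for the three rating laws; draws are rejected
# until the noiseless rating at the longest delay stays within 95% of the
# scale, mirroring the task's own anti-ceiling design
draw_law_params <- function(law, max_stim = 190) {
  repeat {
    p <- switch(law,
      linear    = list(a = rtruncnorm_t(0.0045, 5e-4, 1e-4), b = rtruncnorm_t(0.1, 0.02, 0)),
      quadratic = list(a = rtruncnorm_t(2.2e-5, 3e-6, 1e-6), b = rtruncnorm_t(5e-4, 2e-4, 0),
                       c = rtruncnorm_t(0.1, 0.02, 0)),
      power     = list(a = rtruncnorm_t(0.06, 0.01, 1e-3), b = rtruncnorm_t(0.5, 0.08, 0.05)))
    mu <- switch(law,
      linear = p$a * max_stim + p$b,
      quadratic = p$a * max_stim^2 + p$b * max_stim + p$c,
      power = p$a * max_stim^p$b)
    if (mu <= 0.95) return(p)
  }
}

# one-draw truncated normal using the current RNG stream
rtruncnorm_t <- function(mean, sd, lower) {
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v > lower) return(v)
  }
}

# simulate both discounting tasks for every participant of a cohort and return
# the stacked trial tables
simulate_cohort_choices <- function(cohort, seed, staircase = staircase_config()) {
  lat <- cohort$latent
  adaptive <- list(); fixed <- list()
  for (i in seq_len(nrow(lat))) {
    adaptive[[i]] <- run_adaptive_task(lat[i, ], staircase,
                                       seed = derive_seed(seed, i, "a"))$trials
    fixed[[i]] <- run_fixed_item_task(lat[i, ], seed = derive_seed(seed, i, "f"))
  }
  list(adaptive = do.call(rbind, adaptive), fixed = do.call(rbind, fixed))
}

# internal helpers used directly by tests
derive_seed <- tdperception:::derive_seed
rtruncnorm <- tdperception:::rtruncnorm
truncnorm_mean <- tdperception:::truncnorm_mean
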