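# Per-participant Bayesian fits of the three candidate rating laws (linear,
# quadratic, power) with DIC model comparison, and the circle-size correction
# that inverts the participant-specific circle-production power law.
#
# Observation model (all three laws): y ~ Normal(yhat, 1/pi), with yhat the
# model prediction at the stimulus and pi a participant-specific precision.
# Fits are strictly single-participant (no pooling), so per-participant
# goodness of fit can be compared via DIC.

rating_model_strings <- list(
  linear =
"model {
  a ~ dnorm(0, 0.01)
  b ~ dnorm(0, 0.01)
  pi ~ dgamma(0.001, 0.001)
  for (i in 1:N) { yhat[i] <- a * x[i] + b
                   y[i] ~ dnorm(yhat[i], pi) }
}",
  quadratic =
"model {
  a ~ dnorm(0, 0.01)
  b ~ dnorm(0, 0.01)
  c ~ dnorm(0, 0.01)
  pi ~ dgamma(0.001, 0.001)
  for (i in 1:N) { yhat[i] <- a * x[i]^2 + b * x[i] + c
                   y[i] ~ dnorm(yhat[i], pi) }
}",
  # sampled in the log-linear parametrization (alpha = log-scale intercept at
  # the geometric-mean stimulus): the (a, b) posterior is banana-shaped, the
  # (alpha, b) posterior near-Gaussian, so chains mix and the DIC plug-in is
  # evaluated at a meaningful central point
  power =
"model {
  alpha ~ dnorm(0, 0.01)
  b ~ dnorm(0, 0.01) T(0,)
  pi ~ dgamma(0.001, 0.001)
  for (i in 1:N) { yhat[i] <- exp(alpha + b * (lx[i] - mlx))
                   y[i] ~ dnorm(yhat[i], pi) }
  a <- exp(alpha - b * mlx)
}")

rating_model_params <- list(linear = c("a", "b"),
                            quadratic = c("a", "b", "c"),
                            power = c("a", "b"))

# predictor scale: delays enter in days, circle targets as fraction of the
# 100% reference, corrected ratings keep the magnitude scale they encode
rating_predictor <- function(session) {
  switch(session$stimulus_kind[1],
         percent = session$stimulus_value / 100,
         session$stimulus_value)
}

#' Fit one rating model to one participant's session
#'
#' @param session rating session (see [simulate_time_session()] /
#'   [simulate_circle_session()]), or any data frame with `stimulus_kind`,
#'   `stimulus_value`, `diameter`; needs >= 4 distinct stimulus values and
#'   non-constant ratings.
#' @param model "linear" (`a*x + b`), "quadratic" (`a*x^2 + b*x + c`) or
#'   "power" (`a*x^b`, a and b > 0).
#' @param config a [mcmc_config()]; rating fits default to lighter settings.
#' @param seed integer seed.
#' @return object of class `td_rating_fit`: list with `model`, `samples`
#'   (draws x parameters matrix, including `pi`), `medians`, `dic`, `p_d`,
#'   `n_obs`, `diagnostics`, and the data (`x`, `y`).
#' @export
fit_rating_model <- function(session, model = c("linear", "quadratic", "power"),
                             config = mcmc_config(chains = 2, adapt = 300,
                                                  burnin = 200, draws = 800),
                             seed = 1L) {
  model <- match.arg(model)
  validate_rating_session(session)
  x <- rating_predictor(session)
  y <- session$diameter
  if (length(unique(x)) < 4) stop("need at least 4 distinct stimulus values")
  if (stats::sd(y) == 0) stop("constant ratings: curvature is non-identifiable")

  inits_extra <- switch(model,
    linear = list(a = unname(stats::coef(stats::lm(y ~ x))[2]),
                  b = unname(stats::coef(stats::lm(y ~ x))[1]), pi = 100),
    quadratic = list(a = 0, b = unname(stats::coef(stats::lm(y ~ x))[2]),
                     c = unname(stats::coef(stats::lm(y ~ x))[1]), pi = 100),
    power = {
      # log-log regression gives near-mode starting values
      llm <- stats::coef(stats::lm(log(pmax(y, 1e-4)) ~ log(x)))
      b0 <- min(max(llm[2], 0.05), 5)
      list(alpha = unname(llm[1] + b0 * mean(log(x))), b = unname(b0), pi = 100)
    })

  data <- list(x = x, y = y, N = length(y))
  if (model == "power") {
    data$lx <- log(x); data$mlx <- mean(log(x)); data$x <- NULL
  }
  samples <- run_jags(rating_model_strings[[model]], data,
                      c(rating_model_params[[model]], "pi"),
                      config, seed, inits_extra = inits_extra)
  mat <- do.call(rbind, lapply(samples, as.matrix))
  medians <- apply(mat, 2, stats::median)
  diag <- if (config$chains >= 2) mcmc_diagnostics(samples) else NULL

  fit <- structure(list(model = model, samples = mat, medians = medians,
                        n_obs = length(y), x = x, y = y, diagnostics = diag),
                   class = "td_rating_fit")
  dic <- compute_dic(fit)
  fit$dic <- dic[["dic"]]
  fit$p_d <- dic[["p_d"]]
  fit
}

rating_predict <- function(model, x, par) {
  switch(model,
         linear = par[["a"]] * x + par[["b"]],
         quadratic = par[["a"]] * x^2 + par[["b"]] * x + par[["c"]],
         power = par[["a"]] * x^par[["b"]],
         stop("unknown rating model: ", model))
}

#' Deviance information criterion of a rating-model fit
#'
#' `DIC = Dbar + p_d` with `Dbar` the posterior mean deviance and
#' `p_d = Dbar - D(thetabar)` the effective number of parameters evaluated at
#' the posterior mean of the parameters (Spiegelhalter's classic variant, not
#' the half-variance form). Deviance is `-2` times the Gaussian log-likelihood
#' of the observed ratings. Smaller DIC indicates better fit.
#'
#' @param fit a `td_rating_fit`, or any list with elements `model`, `samples`
#'   (a draws x parameters matrix whose columns include the model parameters
#'   and `pi`), `x`, `y`.
#' @return named numeric vector `c(dic = , p_d = )`.
#' @export
compute_dic <- function(fit) {
  mat <- as.matrix(fit$samples)
  pars <- c(rating_model_params[[fit$model]], "pi")
  if (!all(pars %in% colnames(mat))) stop("samples are missing model parameters")
  if (any(mat[, "pi"] <= 0)) stop("non-positive precision draws: deviance undefined")
  dev_draw <- function(par) {
    yhat <- rating_predict(fit$model, fit$x, par)
    -2 * sum(stats::dnorm(fit$y, yhat, 1 / sqrt(par[["pi"]]), log = TRUE))
  }
  devs <- apply(mat[, pars, drop = FALSE], 1, dev_draw)
  if (any(!is.finite(devs))) stop("non-finite deviance encountered")
  dbar <- mean(devs)
  par_hat <- colMeans(mat[, pars, drop = FALSE])
  if (fit$model == "power") {
    # center the scale parameter on the estimation (log) scale; the arithmetic
    # mean of `a` lies off the posterior ridge and misstates the plug-in fit
    par_hat[["a"]] <- exp(mean(log(mat[, "a"])))
  }
  dhat <- dev_draw(par_hat)
  p_d <- dbar - dhat
  c(dic = dbar + p_d, p_d = p_d)
}

#' Correct time-perception ratings for circle-production non-linearity
#'
#' Inverts the participant-specific circle power law: the corrected rating is
#' `(y / a)^(1/b)`, with `a` and `b` the posterior-median scale and exponent of
#' the participant's power-model fit to the circle-size calibration session.
#' With `a = 1, b = 1` (a linear circle producer) the operation is the
#' identity, so linear raters pass through unchanged. The result lives on the
#' subjective-magnitude scale and is refit with all three candidate laws.
#'
#' @param time_session rating session of delay ratings.
#' @param circle_fit `td_rating_fit` of model "power" on the same
#'   participant's circle calibration (or a list with `medians["a"|"b"]`).
#' @return the session with `diameter` replaced by the corrected rating and
#'   `stimulus_kind` set to "corrected_delay".
#' @export
correct_time_ratings <- function(time_session, circle_fit) {
  if (!is.null(circle_fit$model) && circle_fit$model != "power") {
    stop("circle_fit must be a power-model fit")
  }
  a <- unname(circle_fit$medians[["a"]])
  b <- unname(circle_fit$medians[["b"]])
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("circle power-law parameters must be positive")
  }
  if (any(time_session$diameter < 0)) stop("observed ratings must be non-negative")
  out <- time_session
  out$diameter <- (time_session$diameter / a)^(1 / b)
  out$stimulus_kind <- "corrected_delay"
  out
}

#' Summed-DIC model-selection table
#'
#' Sums per-participant DIC values within each (group, analysis, model) cell
#' and marks the winning (minimal-sum) model per (group, analysis). Ties are
#' broken toward the model with the fewest parameters (linear and power carry
#' two mean parameters, quadratic three; linear is treated as simplest), with
#' a warning.
#'
#' @param dic_table data frame with columns `id`, `group`,
#'   `analysis` (e.g. "delay", "circle", "corrected_delay"), `model`, `dic` —
#'   one row per participant x analysis x model, three models per cell.
#' @return data frame (class `td_dic_table`): `analysis`, `group`, `model`,
#'   `dic_sum`, `winner`.
#' @export
model_selection_table <- function(dic_table) {
  need <- c("id", "group", "analysis", "model", "dic")
  miss <- setdiff(need, names(dic_table))
  if (length(miss)) stop("dic_table missing column(s): ", paste(miss, collapse = ", "))
  models <- c("linear", "power", "quadratic") # simplicity order for ties
  cells <- unique(dic_table[, c("group", "analysis", "id")])
  for (r in seq_len(nrow(cells))) {
    sub <- dic_table[dic_table$group == cells$group[r] &
                     dic_table$analysis == cells$analysis[r] &
                     dic_table$id == cells$id[r], ]
    if (!setequal(sub$model, c("linear", "quadratic", "power"))) {
      stop("missing fits: participant ", cells$id[r], " lacks all three models",
           " for analysis '", cells$analysis[r], "'")
    }
  }
  agg <- stats::aggregate(dic ~ analysis + group + model, dic_table, sum)
  names(agg)[names(agg) == "dic"] <- "dic_sum"
  agg$winner <- FALSE
  key <- unique(agg[, c("analysis", "group")])
  for (r in seq_len(nrow(key))) {
    rows <- which(agg$analysis == key$analysis[r] & agg$group == key$group[r])
    sub <- agg[rows, ]
    best <- min(sub$dic_sum)
    cand <- sub$model[sub$dic_sum == best]
    if (length(cand) > 1) {
      warning("DIC tie in (", key$analysis[r], ", ", key$group[r],
              "): broken toward the simpler model")
      cand <- models[min(match(cand, models))]
    }
    agg$winner[rows] <- sub$model == cand
  }
  agg <- agg[order(agg$analysis, agg$group, match(agg$model, c("linear", "quadratic", "power"))), ]
  rownames(agg) <- NULL
  class(agg) <- c("td_dic_table", "data.frame")
  agg
}

#' Simulate a rating session under a chosen law
#'
#' Generates observed ratings from one of the three candidate laws plus
#' Gaussian noise of precision `pi`, clipped to (0, 1]. Complements the
#' power-law-only cohort generator when testing whether DIC model selection
#' recovers the generating law.
#'
#' @param model "linear", "quadratic" or "power".
#' @param params named parameters of the law (`a`, `b`, and `c` for quadratic).
#' @param stimuli stimulus values (delays in days, or percent for
#'   `stimulus_kind = "percent"`).
#' @param pi precision of the rating noise (`Inf` = noiseless).
#' @param seed integer seed.
#' @param stimulus_kind stored stimulus kind (default "delay").
#' @return rating session data frame.
#' @export
simulate_rating_data <- function(model, params, stimuli = default_time_delays(),
                                 pi = 400, seed = 1L, stimulus_kind = "delay") {
  if (pi <= 0) stop("precision pi must be > 0")
  x <- if (stimulus_kind == "percent") stimuli / 100 else stimuli
  mu <- rating_predict(model, x, as.list(params))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  y <- if (is.infinite(pi)) mu else mu + stats::rnorm(length(mu), 0, 1 / sqrt(pi))
  data.frame(stimulus_kind = stimulus_kind, stimulus_value = stimuli,
             diameter = pmin(pmax(y, 1e-6), 1), set = "S",
             trial_index = seq_along(stimuli), stringsAsFactors = FALSE)
}

#' Fit all three rating models to one session
#'
#' @param session rating session.
#' @param config,seed passed to [fit_rating_model()]; the seed is varied per
#'   model deterministically.
#' @return named list of three `td_rating_fit` objects.
#' @export
fit_all_rating_models <- function(session,
                                  config = mcmc_config(chains = 2, adapt = 300,
                                                       burnin = 200, draws = 800),
                                  seed = 1L) {
  models <- c("linear", "quadratic", "power")
  fits <- lapply(seq_along(models), function(i) {
    fit_rating_model(session, models[i], config = config,
                     seed = derive_seed(seed, i, "ratingmodel"))
  })
  names(fits) <- models
  fits
}

#' @export
print.td_rating_fit <- function(x, ...) {
  cat(sprintf("Rating-model fit (%s): n = %d, DIC = %.2f (p_d = %.2f)\n",
              x$model, x$n_obs, x$dic, x$p_d))
  print(round(x$medians, 5))
  invisible(x)
}
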