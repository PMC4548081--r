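# Behavioral task simulation: adaptive discounting staircase, fixed-item
# discounting, time-perception rating session, and circle-size calibration.
# A latent profile (one row of a cohort's `latent` table) acts as the agent.

#' Column names of a tidy choice-trial table
#' @return character vector of required columns.
#' @export
choice_columns <- function() {
  c("id", "task", "ss_amount", "ss_delay", "ll_amount", "ll_delay", "choice")
}

validate_choices <- function(trials) {
  miss <- setdiff(choice_columns(), names(trials))
  if (length(miss)) stop("choice table missing column(s): ", paste(miss, collapse = ", "))
  if (any(trials$ll_delay <= trials$ss_delay)) stop("ll_delay must exceed ss_delay")
  if (any(trials$ss_amount <= 0) || any(trials$ll_amount <= 0)) stop("amounts must be > 0")
  if (!all(trials$choice %in% c("SS", "LL"))) stop("choice must be 'SS' or 'LL'")
  invisible(trials)
}

# one softmax choice; beta = 0 is the deterministic value maximiser
sample_choice <- function(ll_amount, ll_delay, ss_amount, ss_delay, k, beta) {
  sv_ll <- subjective_value(ll_amount, k, ll_delay)
  sv_ss <- subjective_value(ss_amount, k, ss_delay)
  if (beta == 0) {
    return(if (sv_ll > sv_ss) "LL" else "SS")
  }
  p <- choice_probability(sv_ll, sv_ss, beta)
  if (stats::runif(1) < p) "LL" else "SS"
}

#' Configuration of the adaptive discounting staircase
#'
#' Defaults follow the standard design: a fixed smaller-but-sooner reward of
#' 20 EUR immediately, larger-but-later rewards at seven delays between 1 and
#' 180 days, and per-delay bisection of the LL amount within
#' `[amount_min, amount_max]` EUR with the adjustment step halving after every
#' choice.
#'
#' @param delays LL delays in days (>= 2 trials each are required).
#' @param ss_amount immediate reference amount (EUR).
#' @param amount_min,amount_max LL amount bounds (EUR); must exclude
#'   `ss_amount` from below so every offer dominates nominally.
#' @param n_trials staircase trials per delay (>= 2).
#' @return list of class `td_staircase_config`.
#' @export
staircase_config <- function(delays = c(1, 7, 14, 30, 60, 120, 180),
                             ss_amount = 20, amount_min = 20.5, amount_max = 80,
                             n_trials = 6) {
  if (n_trials < 2) stop("staircase needs at least 2 trials per delay")
  if (amount_min <= ss_amount) stop("amount_min must exceed the immediate amount")
  if (amount_max <= amount_min) stop("amount_max must exceed amount_min")
  if (length(delays) < 1 || any(delays <= 0)) stop("delays must be positive")
  structure(list(delays = sort(delays), ss_amount = ss_amount,
                 amount_min = amount_min, amount_max = amount_max,
                 n_trials = n_trials),
            class = "td_staircase_config")
}

#' Simulate the adaptive discounting task
#'
#' For each delay an independent bisection staircase searches for the LL amount
#' at which the agent is indifferent to the immediate reward: the midpoint of
#' the current amount bracket is offered, an LL choice lowers the upper bound
#' (the reward was still attractive), an SS choice raises the lower bound, and
#' the bracket halves each trial. The indifference point is the midpoint of the
#' final bracket; `final_step` reports the final bracket width, which bounds
#' the error against the closed-form indifference amount
#' `ss_amount * (1 + k * D)` (clamped to the amount bounds) for a
#' deterministic, choice-consistent agent.
#'
#' @param profile one-row latent profile with `log_k` (or `k`) and `beta`.
#' @param config a [staircase_config()].
#' @param seed integer seed.
#' @return list with `trials` (tidy choice table, task = "adaptive") and
#'   `indifference` (delay, indifference_point, final_step, n_trials).
#' @export
run_adaptive_task <- function(profile, config = staircase_config(), seed = 1L) {
  stopifnot(inherits(config, "td_staircase_config"))
  k <- profile_k(profile)
  beta <- profile$beta
  if (beta < 0) stop("beta must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  trials <- list()
  ips <- list()
  for (d in config$delays) {
    lo <- config$amount_min
    hi <- config$amount_max
    for (t in seq_len(config$n_trials)) {
      offer <- (lo + hi) / 2
      ch <- sample_choice(offer, d, config$ss_amount, 0, k, beta)
      trials[[length(trials) + 1L]] <- data.frame(
        id = profile$id %||% NA_character_, task = "adaptive",
        ss_amount = config$ss_amount, ss_delay = 0,
        ll_amount = offer, ll_delay = d, choice = ch,
        stringsAsFactors = FALSE)
      if (ch == "LL") hi <- offer else lo <- offer
    }
    ips[[length(ips) + 1L]] <- data.frame(
      delay = d, indifference_point = (lo + hi) / 2,
      final_step = hi - lo, n_trials = config$n_trials)
  }
  list(trials = validate_choices(do.call(rbind, trials)),
       indifference = do.call(rbind, ips))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

profile_k <- function(profile) {
  k <- if (!is.null(profile$k)) profile$k else exp(profile$log_k)
  if (!is.finite(k) || k < 0) stop("profile implies an invalid discount rate")
  k
}

#' Default fixed-item intertemporal choice set
#'
#' The bundled 27-item monetary choice questionnaire design: each item offers a
#' smaller immediate amount against a larger delayed amount (delays 7-186
#' days). Shipped as plain CSV under `extdata/`; any table with the same
#' columns can be substituted.
#'
#' @return data frame with `ss_amount`, `ss_delay`, `ll_amount`, `ll_delay`.
#' @export
default_kirby_items <- function() {
  path <- system.file("extdata", "mcq27_items.csv", package = "tdperception",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Simulate the fixed-item discounting task
#'
#' One softmax choice per item, item order preserved.
#'
#' @param profile one-row latent profile with `log_k` (or `k`) and `beta`.
#' @param items item table (see [default_kirby_items()]).
#' @param seed integer seed.
#' @return tidy choice table with task = "fixed_items".
#' @export
run_fixed_item_task <- function(profile, items = default_kirby_items(), seed = 1L) {
  if (is.null(items) || nrow(items) == 0) stop("item list must be non-empty")
  k <- profile_k(profile)
  beta <- profile$beta
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  choice <- character(nrow(items))
  for (i in seq_len(nrow(items))) {
    choice[i] <- sample_choice(items$ll_amount[i], items$ll_delay[i],
                               items$ss_amount[i], items$ss_delay[i], k, beta)
  }
  validate_choices(data.frame(
    id = profile$id %||% NA_character_, task = "fixed_items",
    ss_amount = items$ss_amount, ss_delay = items$ss_delay,
    ll_amount = items$ll_amount, ll_delay = items$ll_delay,
    choice = choice, stringsAsFactors = FALSE))
}

#' Default delay set of the time-perception task
#' @return 18 delays (days) spanning 1 to 190.
#' @export
default_time_delays <- function() {
  c(1, 2, 4, 7, 14, 21, 30, 45, 60, 75, 90, 105, 120, 135, 150, 165, 180, 190)
}

#' Simulate a time-perception rating session
#'
#' The agent expresses the subjective duration of each delay by producing a
#' circle whose diameter (as a fraction of the maximal scale) follows the
#' composition of the subjective-time power law and the circle-production power
#' law: `diameter = a_circ * (a_time * D^b_time)^b_circ`, plus Gaussian noise
#' with precision `pi`, clipped to (0, 1].
#'
#' Delays are split into two symmetric sets: odd-ranked delays form set A,
#' presented shortest-first; even-ranked delays form set B, presented
#' longest-first. Within a set, once a produced diameter exceeds
#' `ceiling_fraction` of the scale, all *longer* delays of that set are
#' excluded from the remainder of the session (the anti-ceiling rule);
#' already-produced ratings and shorter delays are unaffected.
#'
#' @param profile one-row latent profile (`a_time`, `b_time`, `a_circ`,
#'   `b_circ`, `pi`); `pi = Inf` gives noiseless production.
#' @param delays ascending delays in days.
#' @param seed integer seed.
#' @param ceiling_fraction scale fraction triggering exclusion (default 0.9).
#' @return rating session: data frame with `stimulus_kind` ("delay"),
#'   `stimulus_value`, `diameter`, `set`, `trial_index`.
#' @export
simulate_time_session <- function(profile, delays = default_time_delays(),
                                  seed = 1L, ceiling_fraction = 0.9) {
  if (is.unsorted(delays, strictly = TRUE)) stop("delays must be strictly ascending")
  if (any(delays <= 0)) stop("delays must be positive")
  if (!is.finite(profile$pi) && !is.infinite(profile$pi)) stop("invalid precision")
  if (profile$pi <= 0) stop("precision pi must be > 0")

  idx <- seq_along(delays)
  set_a <- delays[idx %% 2 == 1]               # ascending presentation
  set_b <- rev(delays[idx %% 2 == 0])          # descending presentation
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  run_set <- function(dset, label) {
    out <- list()
    exclude_above <- Inf
    trial <- 0L
    for (d in dset) {
      if (d > exclude_above) next
      trial <- trial + 1L
      mu <- profile$a_circ * (profile$a_time * d^profile$b_time)^profile$b_circ
      y <- if (is.infinite(profile$pi)) mu else mu + stats::rnorm(1, 0, 1 / sqrt(profile$pi))
      y <- min(max(y, 1e-6), 1)
      out[[trial]] <- data.frame(stimulus_kind = "delay", stimulus_value = d,
                                 diameter = y, set = label, trial_index = trial,
                                 stringsAsFactors = FALSE)
      if (y > ceiling_fraction) exclude_above <- min(exclude_above, d)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  session <- rbind(run_set(set_a, "A"), run_set(set_b, "B"))
  rownames(session) <- NULL
  session
}

#' Simulate a circle-size calibration session
#'
#' Targets are percentages of a reference circle defined as 100%; production
#' follows the circle power law `diameter = a_circ * (p/100)^b_circ` plus
#' Gaussian noise with precision `pi`, clipped to (0, 1]. By default the
#' standard reference sizes 20, 40, 60, 80% are rated, plus (when a time
#' session is supplied) every diameter the participant produced there,
#' re-expressed in percent — mirroring the calibration protocol.
#'
#' @param profile one-row latent profile (`a_circ`, `b_circ`, `pi`).
#' @param targets percentages in (0, 100]; defaults as described.
#' @param seed integer seed.
#' @param time_session optional rating session whose diameters are appended to
#'   the targets.
#' @return rating session data frame (`stimulus_kind` = "percent").
#' @export
simulate_circle_session <- function(profile, targets = NULL, seed = 1L,
                                    time_session = NULL) {
  if (is.null(targets)) {
    targets <- c(20, 40, 60, 80)
    if (!is.null(time_session)) {
      # re-rate every produced diameter, as in the calibration protocol; tiny
      # productions are floored at the smallest displayable target
      targets <- c(targets, pmax(round(100 * time_session$diameter, 2), 0.01))
    }
  }
  if (any(targets <= 0) || any(targets > 100)) stop("targets must lie in (0, 100]")
  if (profile$pi <= 0) stop("precision pi must be > 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- profile$a_circ * (targets / 100)^profile$b_circ
  y <- if (is.infinite(profile$pi)) mu else mu + stats::rnorm(length(mu), 0, 1 / sqrt(profile$pi))
  y <- pmin(pmax(y, 1e-6), 1)
  data.frame(stimulus_kind = "percent", stimulus_value = targets, diameter = y,
             set = "C", trial_index = seq_along(targets), stringsAsFactors = FALSE)
}

#' Write / read tidy trial tables
#'
#' Plain-CSV serialization with invariant checks on load: choice tables must
#' satisfy the option ordering and amount positivity constraints, rating
#' sessions must have diameters in (0, 1] and positive stimulus values.
#'
#' @param x table to write.
#' @param path CSV path.
#' @return `write_*` return the path invisibly; `read_*` return the validated
#'   data frame.
#' @export
write_choice_data <- function(x, path) {
  validate_choices(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choice_data
#' @export
read_choice_data <- function(path) {
  validate_choices(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_choice_data
#' @export
write_rating_session <- function(x, path) {
  validate_rating_session(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choice_data
#' @export
read_rating_session <- function(path) {
  validate_rating_session(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_rating_session <- function(x) {
  need <- c("stimulus_kind", "stimulus_value", "diameter")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("rating session missing column(s): ", paste(miss, collapse = ", "))
  if (any(x$diameter <= 0)) stop("diameters must be positive")
  raw <- x$stimulus_kind %in% c("delay", "percent")
  if (any(x$diameter[raw] > 1)) stop("raw diameters must lie in (0, 1]")
  if (any(x$stimulus_value <= 0)) stop("stimulus values must be positive")
  invisible(x)
}
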