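# Synthetic cohort generation: participants, questionnaire covariates, and the
# latent behavioral parameters that drive the simulated tasks downstream.

#' Default generator configuration for a synthetic cohort
#'
#' Covariate means and SDs default to the published group moments of the
#' gambling-addiction sample this pipeline emulates (healthy controls, HC, vs
#' pathological gamblers, PG): Beck Depression Inventory (BDI), Fagerstrom Test
#' for Nicotine Dependence (FTND), Alcohol Use Disorders Identification Test
#' (AUDIT), the KFG gambling questionnaire, and the South Oaks Gambling Screen
#' (SOGS). Latent behavioral parameters (hyperbolic discount rate k, softmax
#' decision noise beta, subjective-time and circle-production power laws,
#' rating precision, and expected internal-detail scores for autobiographical
#' memory (AM) and episodic future thinking (EFT)) have no published generative
#' values; the defaults are field-typical conventions, chosen once and exposed
#' here for overriding.
#'
#' @param ... named overrides for any top-level element of the default list.
#'   Nested elements can be replaced wholesale, e.g.
#'   `generator_config(logk = list(mean = c(HC = -4, PG = -4), sd = 1, bdi_slope = 0))`.
#' @return a list of class `td_generator_config` with elements:
#' \describe{
#'   \item{covariates}{per-covariate list of per-group `mean`, `sd`, plus
#'     truncation `lower`/`upper`.}
#'   \item{logk}{per-group mean of log k (natural log, k in 1/days), residual
#'     `sd`, and `bdi_slope`: the change in log k per within-group SD of BDI
#'     (negative = depression attenuates discounting).}
#'   \item{logbeta}{per-group mean and sd of log decision noise (beta in EUR).}
#'   \item{time_law, circle_law}{means/sds of the power-law scale `a` and
#'     exponent `b` (both truncated > 0).}
#'   \item{precision}{log-normal meanlog/sdlog of the rating precision pi
#'     (inverse variance of the Gaussian rating error).}
#'   \item{details}{per-group means, common sd, and AM-EFT correlation `rho`
#'     for the internal-detail sum scores.}
#' }
#' @export
generator_config <- function(...) {
  cfg <- list(
    covariates = list(
      bdi   = list(mean = c(HC = 4.6,  PG = 16.5), sd = c(HC = 4.07, PG = 9.48), lower = 0, upper = 63),
      ftnd  = list(mean = c(HC = 3.5,  PG = 4.45), sd = c(HC = 2.59, PG = 2.76), lower = 0, upper = 10),
      audit = list(mean = c(HC = 7.15, PG = 10.3), sd = c(HC = 7.37, PG = 6.28), lower = 0, upper = 40),
      kfg   = list(mean = c(HC = 1.75, PG = 30.15), sd = c(HC = 2.71, PG = 7.74), lower = 0, upper = 60),
      sogs  = list(mean = c(HC = 0.45, PG = 9.65), sd = c(HC = 0.60, PG = 3.01), lower = 0, upper = 20),
      age   = list(mean = c(HC = 32.55, PG = 32.9), sd = c(HC = 11, PG = 11), lower = 18, upper = 65),
      school_years = list(mean = c(HC = 10, PG = 10), sd = c(HC = 1.2, PG = 1.2), lower = 7, upper = 18)
    ),
    logk    = list(mean = c(HC = -4.5, PG = -3.8), sd = 1.0, bdi_slope = -0.35),
    logbeta = list(mean = c(HC = 0.5, PG = 0.5), sd = 0.4),
    time_law   = list(a_mean = 0.06, a_sd = 0.01, b_mean = 0.5, b_sd = 0.08),
    circle_law = list(a_mean = 1.0, a_sd = 0.05, b_mean = 0.8, b_sd = 0.08),
    precision  = list(meanlog = log(400), sdlog = 0.3),
    details    = list(mean = c(HC = 40, PG = 44), sd = 12, rho = 0.9)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown generator_config element(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_generator_config(cfg)
  structure(cfg, class = "td_generator_config")
}

validate_generator_config <- function(cfg) {
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    if (any(cv$sd < 0)) stop("covariate '", nm, "': SD must be >= 0")
    if (any(!is.finite(cv$mean))) stop("covariate '", nm, "': non-finite mean")
  }
  if (cfg$logk$sd < 0 || cfg$logbeta$sd < 0) stop("latent SDs must be >= 0")
  rho <- cfg$details$rho
  if (rho < -1 || rho > 1) stop("details$rho must lie in [-1, 1]")
  invisible(cfg)
}

#' Generate a synthetic cohort of participants and latent profiles
#'
#' Each participant receives questionnaire covariates drawn from group-specific
#' truncated normal distributions and a latent behavioral profile: hyperbolic
#' discount rate (on the natural-log scale), softmax decision noise, the
#' subjective-time and circle-production power laws, rating precision, and
#' expected AM/EFT internal-detail scores. Depression couples to discounting
#' through `config$logk$bdi_slope` (in units of log k per within-group SD of
#' BDI), so regressions on the latent truth can be validated directionally.
#'
#' Every participant consumes an independent random substream derived from the
#' master seed, so inserting or removing participants leaves the draws of the
#' others untouched.
#'
#' @param n_hc,n_pg participants per group (>= 1).
#' @param config a [generator_config()].
#' @param seed master integer seed.
#' @return an object of class `td_cohort`: a list with data frames
#'   `participants` (id, group, covariates) and `latent` (id plus all latent
#'   parameters; consumed only by task simulation and recovery reports, never
#'   by inference).
#' @export
generate_cohort <- function(n_hc, n_pg, config = generator_config(), seed = 1L) {
  if (!inherits(config, "td_generator_config")) config <- do.call(generator_config, config)
  if (n_hc < 1 || n_pg < 1) stop("n_hc and n_pg must be >= 1")
  assert_scalar_number(seed, "seed")

  groups <- c(rep("HC", n_hc), rep("PG", n_pg))
  n <- length(groups)
  # parent-normal locations matched so truncated sampling means equal the
  # configured covariate means (truncation at 0 would otherwise inflate them)
  mu_adj <- lapply(config$covariates, function(cv) {
    vapply(c("HC", "PG"), function(g) {
      match_truncnorm_mean(cv$mean[[g]], cv$sd[[g]], cv$lower, cv$upper)
    }, numeric(1))
  })
  part <- vector("list", n)
  lat <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    old <- .Random.seed_save()
    set.seed(derive_seed(seed, i, "cohort"))
    cov <- lapply(names(config$covariates), function(nm) {
      cv <- config$covariates[[nm]]
      rtruncnorm(1, mu_adj[[nm]][[g]], cv$sd[[g]], cv$lower, cv$upper)
    })
    names(cov) <- names(config$covariates)
    cov$school_years <- round(cov$school_years)
    cov$age <- round(cov$age, 1)

    bdi_sd <- config$covariates$bdi$sd[[g]]
    z_bdi <- if (bdi_sd > 0) (cov$bdi - config$covariates$bdi$mean[[g]]) / bdi_sd else 0
    log_k <- stats::rnorm(1, config$logk$mean[[g]] + config$logk$bdi_slope * z_bdi,
                          config$logk$sd)
    log_beta <- stats::rnorm(1, config$logbeta$mean[[g]], config$logbeta$sd)
    tl <- config$time_law; cl <- config$circle_law
    a_time <- rtruncnorm(1, tl$a_mean, tl$a_sd, lower = 1e-6)
    b_time <- rtruncnorm(1, tl$b_mean, tl$b_sd, lower = 1e-6)
    a_circ <- rtruncnorm(1, cl$a_mean, cl$a_sd, lower = 1e-6)
    b_circ <- rtruncnorm(1, cl$b_mean, cl$b_sd, lower = 1e-6)
    pi_rate <- if (config$precision$sdlog == 0) exp(config$precision$meanlog) else
      stats::rlnorm(1, config$precision$meanlog, config$precision$sdlog)
    det <- config$details
    sums <- generate_am_eft_scores(
      list(am_details = det$mean[[g]], eft_details = det$mean[[g]]),
      rho = det$rho, seed = derive_seed(seed, i, "details"),
      sd_am = det$sd, sd_eft = det$sd
    )
    .Random.seed_restore(old)

    id <- sprintf("%s%03d", tolower(g), i)
    part[[i]] <- data.frame(id = id, group = g, bdi = cov$bdi, ftnd = cov$ftnd,
                            audit = cov$audit, kfg = cov$kfg, sogs = cov$sogs,
                            school_years = cov$school_years, age = cov$age,
                            stringsAsFactors = FALSE)
    lat[[i]] <- data.frame(id = id, group = g, log_k = log_k, beta = exp(log_beta),
                           a_time = a_time, b_time = b_time, a_circ = a_circ,
                           b_circ = b_circ, pi = pi_rate,
                           am_details = sums[["am_sum"]], eft_details = sums[["eft_sum"]],
                           stringsAsFactors = FALSE)
  }
  out <- list(participants = do.call(rbind, part), latent = do.call(rbind, lat))
  class(out) <- "td_cohort"
  out
}

# save/restore the global RNG state so cohort generation composes with callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Draw correlated AM and EFT internal-detail sum scores
#'
#' Draws one (AM, EFT) pair from a bivariate normal with correlation `rho`,
#' truncated at zero, emulating the strong coupling between autobiographical
#' memory and episodic future thinking detail scores seen in cued-interview
#' data.
#'
#' @param profile list or one-row data frame with `am_details` and
#'   `eft_details` (expected sum scores), used as default means.
#' @param rho target correlation in [-1, 1].
#' @param seed integer seed.
#' @param sd_am,sd_eft score SDs.
#' @param mean_am,mean_eft means; default to the profile's expected scores.
#' @return named numeric vector `c(am_sum = , eft_sum = )`.
#' @export
generate_am_eft_scores <- function(profile, rho = 0.9, seed = 1L,
                                   sd_am = 12, sd_eft = 12,
                                   mean_am = profile$am_details,
                                   mean_eft = profile$eft_details) {
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  old <- .Random.seed_save()
  set.seed(seed)
  u <- stats::rnorm(1)
  w <- stats::rnorm(1)
  .Random.seed_restore(old)
  v <- rho * u + sqrt(max(0, 1 - rho^2)) * w
  c(am_sum = max(0, mean_am + sd_am * u),
    eft_sum = max(0, mean_eft + sd_eft * v))
}

#' Write a cohort to disk
#'
#' Writes `cohort.csv` (one row per participant: id, group, covariates) and
#' `latent_truth.csv` (the generative parameters). The truth table exists only
#' for parameter-recovery reports; inference functions never read it.
#'
#' @param cohort a `td_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "td_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "cohort.csv")
  p2 <- file.path(dir, "latent_truth.csv")
  utils::write.csv(cohort$participants, p1, row.names = FALSE)
  utils::write.csv(cohort$latent, p2, row.names = FALSE)
  invisible(c(cohort = p1, latent_truth = p2))
}

#' @export
print.td_cohort <- function(x, ...) {
  tab <- table(x$participants$group)
  cat("Synthetic cohort:", nrow(x$participants), "participants (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}
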