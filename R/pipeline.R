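# End-to-end pipeline: generate a cohort, simulate the four tasks, fit the
# discounting and rating models, apply the circle-size correction, run model
# selection, and compute the group-level statistics — all from one config and
# one seed. Inference stages only ever see simulated trial data; the latent
# truth table is read exclusively by recovery_report().

#' Pipeline configuration
#'
#' @param n_hc,n_pg cohort sizes per group.
#' @param seed master seed (mandatory; expands into per-stage and
#'   per-participant substreams).
#' @param generator a [generator_config()].
#' @param staircase a [staircase_config()].
#' @param hier_mcmc MCMC settings for the hierarchical discounting fits.
#' @param rating_mcmc MCMC settings for the per-participant rating fits.
#' @param stages named logical vector enabling stages: `discounting`, `time`,
#'   `stats` (cohort generation and task simulation always run).
#' @param output_dir optional directory; when given, all artifacts are written
#'   there (CSV tables plus a JSON manifest).
#' @param fit_single_tasks also fit the adaptive and fixed-item tasks
#'   separately (needed for the cross-task reliability check; default TRUE).
#' @return list of class `td_pipeline_config`.
#' @export
pipeline_config <- function(n_hc = 4, n_pg = 4, seed,
                            generator = generator_config(),
                            staircase = staircase_config(),
                            hier_mcmc = mcmc_config(chains = 2, adapt = 400,
                                                    burnin = 400, draws = 800),
                            rating_mcmc = mcmc_config(chains = 2, adapt = 300,
                                                      burnin = 200, draws = 600),
                            stages = c(discounting = TRUE, time = TRUE, stats = TRUE),
                            output_dir = NULL, fit_single_tasks = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  assert_scalar_number(seed, "seed")
  stopifnot(inherits(staircase, "td_staircase_config"),
            inherits(hier_mcmc, "td_mcmc_config"),
            inherits(rating_mcmc, "td_mcmc_config"))
  for (s in c("discounting", "time", "stats")) {
    if (is.na(stages[s])) stages[s] <- TRUE
  }
  structure(list(n_hc = n_hc, n_pg = n_pg, seed = as.integer(seed),
                 generator = generator, staircase = staircase,
                 hier_mcmc = hier_mcmc, rating_mcmc = rating_mcmc,
                 stages = stages, output_dir = output_dir,
                 fit_single_tasks = fit_single_tasks),
            class = "td_pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stage order mirrors the experimental session: discounting tasks first, then
#' the time-perception and circle-size rating procedures, then the statistical
#' layer.
#'
#' @param config a [pipeline_config()].
#' @return list of class `td_pipeline_result` with elements `cohort`, `trials`
#'   (adaptive + fixed-item choice tables), `indifference`, `fits`
#'   (hierarchical fits: `combined`, and `adaptive`/`fixed` when
#'   `fit_single_tasks`), `rating` (per-participant fits and the DIC table),
#'   `stats` (group statistics and regression), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "td_pipeline_config"))
  seed <- config$seed
  res <- list(config = config)

  res$cohort <- stage("cohort", generate_cohort(config$n_hc, config$n_pg,
                                                config$generator, seed))
  lat <- res$cohort$latent
  groups <- stats::setNames(lat$group, lat$id)

  res$trials <- stage("tasks", {
    adaptive <- list(); fixed <- list(); indiff <- list()
    for (i in seq_len(nrow(lat))) {
      prof <- lat[i, ]
      ad <- run_adaptive_task(prof, config$staircase,
                              seed = derive_seed(seed, i, "adaptive"))
      adaptive[[i]] <- ad$trials
      indiff[[i]] <- cbind(id = prof$id, ad$indifference)
      fixed[[i]] <- run_fixed_item_task(prof, seed = derive_seed(seed, i, "fixed"))
    }
    list(adaptive = do.call(rbind, adaptive), fixed = do.call(rbind, fixed),
         indifference = do.call(rbind, indiff))
  })

  if (isTRUE(config$stages[["discounting"]])) {
    res$fits <- stage("discounting", {
      fits <- list()
      if (config$fit_single_tasks) {
        fits$adaptive <- fit_hierarchical(res$trials$adaptive, groups,
                                          config$hier_mcmc,
                                          seed = derive_seed(seed, 1, "hfit"),
                                          on_nonconvergence = "warn")
        fits$fixed <- fit_hierarchical(res$trials$fixed, groups,
                                       config$hier_mcmc,
                                       seed = derive_seed(seed, 2, "hfit"),
                                       on_nonconvergence = "warn")
      }
      fits$combined <- combine_and_refit(res$trials$adaptive, res$trials$fixed,
                                         groups, config$hier_mcmc,
                                         seed = derive_seed(seed, 3, "hfit"),
                                         on_nonconvergence = "warn")
      fits
    })
  }

  if (isTRUE(config$stages[["time"]])) {
    res$rating <- stage("time", {
      dic_rows <- list(); params <- list(); sessions <- list()
      for (i in seq_len(nrow(lat))) {
        prof <- lat[i, ]
        ts <- simulate_time_session(prof, seed = derive_seed(seed, i, "time"))
        cs <- simulate_circle_session(prof, seed = derive_seed(seed, i, "circle"),
                                      time_session = ts)
        f_delay <- fit_all_rating_models(ts, config$rating_mcmc,
                                         seed = derive_seed(seed, i, "fitdelay"))
        f_circ <- fit_all_rating_models(cs, config$rating_mcmc,
                                        seed = derive_seed(seed, i, "fitcircle"))
        corrected <- correct_time_ratings(ts, f_circ$power)
        f_corr <- fit_all_rating_models(corrected, config$rating_mcmc,
                                        seed = derive_seed(seed, i, "fitcorr"))
        for (an in c("delay", "circle", "corrected_delay")) {
          fl <- switch(an, delay = f_delay, circle = f_circ,
                       corrected_delay = f_corr)
          for (m in names(fl)) {
            dic_rows[[length(dic_rows) + 1L]] <- data.frame(
              id = prof$id, group = prof$group, analysis = an, model = m,
              dic = fl[[m]]$dic, stringsAsFactors = FALSE)
          }
        }
        params[[i]] <- data.frame(
          id = prof$id, group = prof$group,
          a_circ_hat = unname(f_circ$power$medians["a"]),
          b_circ_hat = unname(f_circ$power$medians["b"]),
          a_time_hat = unname(f_corr$power$medians["a"]),
          b_time_hat = unname(f_corr$power$medians["b"]),
          pi_hat = unname(f_corr$power$medians["pi"]),
          stringsAsFactors = FALSE)
        sessions[[i]] <- list(time = ts, circle = cs, corrected = corrected)
      }
      dic_df <- do.call(rbind, dic_rows)
      list(dic = dic_df, selection = model_selection_table(dic_df),
           params = do.call(rbind, params), sessions = sessions)
    })
  }

  if (isTRUE(config$stages[["stats"]]) && !is.null(res$fits)) {
    res$stats <- stage("stats", {
      logk <- summarize_log_k(res$fits$combined)
      part <- res$cohort$participants
      ord <- match(logk$id, part$id)
      out <- list()
      out$welch_log_k <- welch_t(logk$log_k[logk$group == "HC"],
                                 logk$log_k[logk$group == "PG"])
      out$severity <- addiction_severity(part$kfg[ord], part$sogs[ord])
      out$am_eft_r <- pearson_r(lat$am_details, lat$eft_details)
      if (!is.null(res$rating) && nrow(part) > 8) {
        pr <- res$rating$params[match(logk$id, res$rating$params$id), ]
        preds <- data.frame(b_time = pr$b_time_hat, audit = part$audit[ord],
                            ftnd = part$ftnd[ord], bdi = part$bdi[ord],
                            group = as.numeric(logk$group == "PG"),
                            eft = lat$eft_details[match(logk$id, lat$id)])
        out$regression <- regress_log_k(logk$log_k, preds)
      }
      out
    })
  }

  res$manifest <- list(seed = seed, n_hc = config$n_hc, n_pg = config$n_pg,
                       stages = as.list(config$stages),
                       r_version = as.character(getRversion()),
                       package_version = as.character(utils::packageVersion("tdperception")))
  class(res) <- "td_pipeline_result"
  if (!is.null(config$output_dir)) write_pipeline_artifacts(res, config$output_dir)
  res
}

write_pipeline_artifacts <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(res$cohort, dir)
  write_choice_data(rbind(res$trials$adaptive, res$trials$fixed),
                    file.path(dir, "choice_trials.csv"))
  utils::write.csv(res$trials$indifference, file.path(dir, "indifference_points.csv"),
                   row.names = FALSE)
  if (!is.null(res$fits)) {
    write_hfit_summary(res$fits$combined, file.path(dir, "posterior_summary.csv"))
  }
  if (!is.null(res$rating)) {
    utils::write.csv(res$rating$selection, file.path(dir, "dic_table.csv"),
                     row.names = FALSE)
    utils::write.csv(res$rating$params, file.path(dir, "rating_params.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$stats)) {
    w <- res$stats$welch_log_k
    stats_df <- data.frame(
      analysis = c("welch_log_k", "welch_log_k", "welch_log_k", "am_eft_r", "am_eft_r"),
      statistic = c("t", "df", "p", "r", "p"),
      value = c(w$t, w$df, w$p, res$stats$am_eft_r$r, res$stats$am_eft_r$p))
    utils::write.csv(stats_df, file.path(dir, "group_stats.csv"), row.names = FALSE)
    if (!is.null(res$stats$regression)) {
      utils::write.csv(res$stats$regression$coefficients,
                       file.path(dir, "regression.csv"), row.names = FALSE)
    }
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Parameter-recovery report
#'
#' Joins inferred parameters to the generative truth of a synthetic cohort and
#' reports, per parameter, the recovery correlation, mean bias
#' (inferred - true), and RMSE. This is the only operation allowed to read the
#' latent truth; it refuses to run without it (real-data mode has no truth to
#' recover).
#'
#' @param result a `td_pipeline_result` (or list with `cohort$latent`, `fits`,
#'   `rating`).
#' @return data frame with one row per recovered parameter.
#' @export
recovery_report <- function(result) {
  truth <- result$cohort$latent
  if (is.null(truth)) {
    stop("no latent truth table available: recovery reports require a ",
         "synthetic cohort (real-data mode cannot be scored against truth)")
  }
  rows <- list()
  add <- function(parameter, true, est) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, r = stats::cor(true, est),
      bias = mean(est - true), rmse = sqrt(mean((est - true)^2)),
      n = length(true), stringsAsFactors = FALSE)
  }
  if (!is.null(result$fits$combined)) {
    p <- result$fits$combined$participants
    ord <- match(p$id, truth$id)
    add("log_k", truth$log_k[ord], p$log_k)
    add("log_beta", log(truth$beta[ord]), log(p$median_beta))
  }
  if (!is.null(result$rating)) {
    pr <- result$rating$params
    ord <- match(pr$id, truth$id)
    add("b_time", truth$b_time[ord], pr$b_time_hat)
    add("b_circ", truth$b_circ[ord], pr$b_circ_hat)
  }
  if (!length(rows)) stop("result contains no fitted parameters to score")
  do.call(rbind, rows)
}

#' @export
print.td_pipeline_result <- function(x, ...) {
  cat("Pipeline result: seed", x$manifest$seed, "|",
      nrow(x$cohort$participants), "participants\n")
  if (!is.null(x$fits)) cat("  discounting fit: converged =", x$fits$combined$converged, "\n")
  if (!is.null(x$rating)) {
    win <- x$rating$selection[x$rating$selection$winner, c("analysis", "group", "model")]
    cat("  winning rating models:\n")
    print(win, row.names = FALSE)
  }
  invisible(x)
}
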