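test_that("hierarchical fit recovers simulated discount rates and is reproducible", {
  co <- generate_cohort(6, 6, seed = 5)
  tr <- simulate_cohort_choices(co, seed = 5)
  groups <- setNames(co$latent$group, co$latent$id)
  fit <- combine_and_refit(tr$adaptive, tr$fixed, groups, fast_mcmc(), seed = 7,
                           on_nonconvergence = "warn")
  expect_s3_class(fit, "td_hfit")
  est <- fit$participants
  ord <- match(co$latent$id, est$id)
  expect_gt(cor(co$latent$log_k, est$log_k[ord]), 0.9)
  expect_true(all(est$median_k > 0))
  expect_identical(nrow(est), 12L)
  # concatenation: combined trial counts are the per-task sums
  expect_identical(est$n_trials,
                   as.integer(table(tr$adaptive$id)[est$id] +
                              table(tr$fixed$id)[est$id]))
  # bit-identical refit under the same seed
  fit2 <- combine_and_refit(tr$adaptive, tr$fixed, groups, fast_mcmc(), seed = 7,
                            on_nonconvergence = "warn")
  expect_identical(fit$participants, fit2$participants)
})

test_that("log-k summaries are the log of the posterior-median k", {
  co <- generate_cohort(3, 3, seed = 9)
  tr <- simulate_cohort_choices(co, seed = 9)
  groups <- setNames(co$latent$group, co$latent$id)
  fit <- fit_hierarchical(rbind(tr$adaptive, tr$fixed), groups, fast_mcmc(),
                          seed = 2, on_nonconvergence = "warn")
  s <- summarize_log_k(fit)
  expect_equal(s$log_k, log(s$median_k), tolerance = 1e-12)
  expect_true(all(diff(s$log_k[order(s$median_k)]) >= 0)) # log is monotone
})

test_that("precondition violations fail loudly", {
  co <- generate_cohort(2, 2, seed = 3)
  tr <- simulate_cohort_choices(co, seed = 3)
  groups <- setNames(co$latent$group, co$latent$id)
  expect_error(fit_hierarchical(tr$fixed, groups[-1], fast_mcmc(), seed = 1),
               "unknown group label")
  few <- tr$fixed[tr$fixed$id != co$latent$id[1] |
                    seq_len(nrow(tr$fixed)) %in% 1:5, ]
  expect_error(fit_hierarchical(few, groups, fast_mcmc(), seed = 1),
               "at least 10")
  expect_error(combine_and_refit(tr$adaptive,
                                 tr$fixed[tr$fixed$id != co$latent$id[1], ],
                                 groups, fast_mcmc(), seed = 1),
               "participant mismatch")
})

test_that("all-identical choices trigger the identifiability warning", {
  items <- default_kirby_items()
  mk <- function(id) data.frame(id = id, task = "fixed_items",
                                ss_amount = items$ss_amount, ss_delay = 0,
                                ll_amount = items$ll_amount,
                                ll_delay = items$ll_delay,
                                choice = "LL", stringsAsFactors = FALSE)
  tr <- rbind(mk("a"), mk("b"), mk("c"), mk("d"))
  groups <- c(a = "HC", b = "HC", c = "PG", d = "PG")
  expect_warning(
    fit <- fit_hierarchical(tr, groups, fast_mcmc(), seed = 4,
                            on_nonconvergence = "warn"),
    "identical choices")
})

test_that("an always-LL participant's k sits below the design bound", {
  co <- generate_cohort(3, 3, seed = 13,
                        config = generator_config(logk = list(mean = c(HC = -5, PG = -5),
                                                              sd = 0.5, bdi_slope = 0)))
  tr <- simulate_cohort_choices(co, seed = 13)
  items <- default_kirby_items()
  extreme <- data.frame(id = "always_ll", task = "fixed_items",
                        ss_amount = items$ss_amount, ss_delay = 0,
                        ll_amount = items$ll_amount, ll_delay = items$ll_delay,
                        choice = "LL", stringsAsFactors = FALSE)
  trials <- rbind(tr$adaptive, tr$fixed, extreme)
  groups <- c(setNames(co$latent$group, co$latent$id), always_ll = "HC")
  fit <- fit_hierarchical(trials, groups, fast_mcmc(), seed = 6,
                          on_nonconvergence = "warn")
  # smallest k at which any bundled item reaches indifference
  k_star <- min((items$ll_amount / items$ss_amount - 1) / items$ll_delay)
  est <- fit$participants
  expect_lt(est$median_k[est$id == "always_ll"], k_star)
})

test_that("participants with identical data get matching posteriors", {
  items <- default_kirby_items()
  one <- run_fixed_item_task(make_profile(k = 0.02, beta = 1.5), items, seed = 8)
  tr <- do.call(rbind, lapply(c("a", "b", "c", "d"), function(id) {
    x <- one; x$id <- id; x
  }))
  groups <- setNames(rep("HC", 4), c("a", "b", "c", "d"))
  fit <- fit_hierarchical(tr, groups, fast_mcmc(), seed = 9,
                          on_nonconvergence = "warn")
  expect_lt(diff(range(fit$participants$log_k)), 0.15)
})

test_that("recovery improves with the number of trials", {
  # same participants, 30 vs 120 random choice items each; averaged over seeds
  n_sub <- 14
  rec <- function(n_trials, seed) {
    co <- generate_cohort(n_sub / 2, n_sub / 2, seed = seed)
    lat <- co$latent
    groups <- setNames(lat$group, lat$id)
    tr <- do.call(rbind, lapply(seq_len(nrow(lat)), function(i) {
      s <- derive_seed(seed, i, "items")
      set.seed(s)
      items <- data.frame(ss_amount = 20, ss_delay = 0,
                          ll_amount = round(runif(n_trials, 20.5, 80), 1),
                          ll_delay = sample(c(1, 7, 14, 30, 60, 120, 180),
                                            n_trials, replace = TRUE))
      run_fixed_item_task(lat[i, ], items, seed = s + 1)
    }))
    fit <- fit_hierarchical(tr, groups, fast_mcmc(), seed = seed + 1,
                            on_nonconvergence = "warn")
    cor(lat$log_k, fit$participants$log_k[match(lat$id, fit$participants$id)])
  }
  seeds <- 101:105
  r_small <- mean(vapply(seeds, function(s) rec(30, s), numeric(1)))
  r_large <- mean(vapply(seeds, function(s) rec(120, s), numeric(1)))
  expect_gt(r_large, r_small)
})

test_that("split R-hat flags a nonstationary chain and passes a clean one", {
  set.seed(1)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(good), 1.02)
  drift <- matrix(rnorm(4000) + rep(seq(0, 3, length.out = 1000), 4), ncol = 4)
  expect_gt(split_rhat(drift), 1.1)
})
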