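test_that("noiseless rating data are recovered exactly by the matching law", {
  delays <- default_time_delays()
  lin <- simulate_rating_data("linear", list(a = 0.003, b = 0.2), delays, pi = Inf)
  f_lin <- fit_rating_model(lin, "linear", fast_mcmc(), seed = 1)
  expect_lt(abs(f_lin$medians[["a"]] - 0.003), 1e-3)
  expect_lt(abs(f_lin$medians[["b"]] - 0.2), 1e-3)
  pow <- simulate_rating_data("power", list(a = 0.05, b = 0.5), delays, pi = Inf)
  f_pow <- fit_rating_model(pow, "power", fast_mcmc(), seed = 2)
  expect_lt(abs(f_pow$medians[["b"]] - 0.5), 0.02)
  expect_lt(abs(f_pow$medians[["a"]] - 0.05), 0.005)
})

test_that("degenerate rating inputs are rejected", {
  delays <- default_time_delays()
  flat <- simulate_rating_data("linear", list(a = 0, b = 0.4), delays, pi = Inf)
  expect_error(fit_rating_model(flat, "linear"), "constant ratings")
  few <- simulate_rating_data("linear", list(a = 0.002, b = 0.1),
                              c(10, 10, 10, 20), pi = 400, seed = 1)
  expect_error(fit_rating_model(few, "linear"), "4 distinct")
  expect_error(simulate_rating_data("power", list(a = 0.05, b = 0.5), pi = -1),
               "pi")
})

test_that("DIC matches a brute-force deviance evaluation on a fixed fixture", {
  # hand-built posterior: 200 draws around a known line, 6 observations
  set.seed(42)
  x <- c(2, 5, 9, 14, 20, 27)
  y <- 0.01 * x + 0.1 + rnorm(6, 0, 0.03)
  draws <- cbind(a = rnorm(200, 0.01, 0.002),
                 b = rnorm(200, 0.1, 0.01),
                 pi = rgamma(200, 50, 0.05))
  fit <- list(model = "linear", samples = draws, x = x, y = y)
  got <- compute_dic(fit)
  # independent re-evaluation with the explicit Gaussian deviance formula
  dev_at <- function(a, b, pi) {
    s2 <- 1 / pi
    yhat <- a * x + b
    -2 * sum(-0.5 * log(2 * pi_const * s2) - (y - yhat)^2 / (2 * s2))
  }
  pi_const <- base::pi
  devs <- vapply(1:200, function(i) dev_at(draws[i, 1], draws[i, 2], draws[i, 3]),
                 numeric(1))
  dbar <- mean(devs)
  dhat <- dev_at(mean(draws[, 1]), mean(draws[, 2]), mean(draws[, 3]))
  expect_equal(unname(got[["dic"]]), dbar + (dbar - dhat), tolerance = 1e-9)
  expect_equal(unname(got[["p_d"]]), dbar - dhat, tolerance = 1e-9)
})

test_that("a perfect fit with huge precision keeps DIC finite and deviance negative", {
  x <- c(1, 3, 6, 10, 15, 21)
  y <- 0.02 * x + 0.05
  draws <- cbind(a = rep(0.02, 50), b = rep(0.05, 50), pi = rep(1e6, 50))
  got <- compute_dic(list(model = "linear", samples = draws, x = x, y = y))
  expect_true(is.finite(got[["dic"]]))
  expect_lt(got[["dic"]], -50)
  bad <- cbind(a = 0.02, b = 0.05, pi = -1)
  expect_error(compute_dic(list(model = "linear", samples = bad, x = x, y = y)),
               "precision")
})

test_that("DIC prefers the generating law and charges for extra parameters", {
  delays <- default_time_delays()
  pow_wins <- 0; pd_ok <- 0; n_seeds <- 5
  for (s in 1:n_seeds) {
    pow <- simulate_rating_data("power", list(a = 0.06, b = 0.5), delays,
                                pi = 400, seed = 100 + s)
    fp <- fit_rating_model(pow, "power", fast_mcmc(), seed = s)
    fl <- fit_rating_model(pow, "linear", fast_mcmc(), seed = s + 50)
    if (fp$dic < fl$dic) pow_wins <- pow_wins + 1
    lin <- simulate_rating_data("linear", list(a = 0.0045, b = 0.1), delays,
                                pi = 400, seed = 200 + s)
    gl <- fit_rating_model(lin, "linear", fast_mcmc(), seed = s + 100)
    gq <- fit_rating_model(lin, "quadratic", fast_mcmc(), seed = s + 150)
    if (gq$p_d >= gl$p_d) pd_ok <- pd_ok + 1
  }
  expect_gte(pow_wins, 4) # majority of seeds
  expect_gte(pd_ok, 4)
})

test_that("circle-size correction inverts the production law exactly", {
  # identity circle law: the correction is a no-op
  sess <- simulate_rating_data("power", list(a = 0.05, b = 0.5),
                               default_time_delays(), pi = 400, seed = 3)
  ident <- list(model = "power", medians = c(a = 1, b = 1))
  expect_equal(correct_time_ratings(sess, ident)$diameter, sess$diameter,
               tolerance = 1e-12)
  # algebraic round-trip with known circle parameters
  m <- 0.3
  y <- 2 * m^0.8
  one <- data.frame(stimulus_kind = "delay", stimulus_value = 10, diameter = y)
  corr <- correct_time_ratings(one, list(model = "power", medians = c(a = 2, b = 0.8)))
  expect_equal(corr$diameter, 0.3, tolerance = 1e-10)
  expect_identical(corr$stimulus_kind, "corrected_delay")
  expect_error(correct_time_ratings(one, list(model = "power", medians = c(a = -1, b = 0.8))),
               "positive")
  expect_error(correct_time_ratings(one, list(model = "linear", medians = c(a = 1, b = 1))),
               "power")
})

test_that("composite noiseless pipeline round-trips through the correction", {
  # parameters chosen so even the longest delay stays inside the rating scale
  prof <- make_profile(a_time = 0.05, b_time = 0.5, a_circ = 1.05, b_circ = 0.75,
                       pi = Inf)
  ts <- simulate_time_session(prof, seed = 1)
  truth_fit <- list(model = "power", medians = c(a = prof$a_circ, b = prof$b_circ))
  corr <- correct_time_ratings(ts, truth_fit)
  expect_equal(corr$diameter, prof$a_time * corr$stimulus_value^prof$b_time,
               tolerance = 1e-8)
  refit <- fit_rating_model(corr, "power", fast_mcmc(), seed = 4)
  expect_lt(abs(refit$medians[["b"]] - prof$b_time), 0.02)
})

test_that("model-selection table sums, ranks, and breaks ties as specified", {
  grid <- expand.grid(id = c("p1", "p2"), group = c("HC", "PG"),
                      analysis = c("delay", "circle", "corrected_delay"),
                      model = c("linear", "quadratic", "power"),
                      stringsAsFactors = FALSE)
  grid$dic <- 100 + match(grid$model, c("power", "quadratic", "linear"))
  tab <- model_selection_table(grid)
  expect_identical(nrow(tab), 18L) # 3 models x 2 groups x 3 analyses
  expect_true(all(tab$model[tab$winner] == "power"))
  expect_equal(unique(tab$dic_sum[tab$winner]), 2 * 101)
  # ties break toward the simpler model, with a warning
  tie <- grid[grid$id == "p1" & grid$analysis == "delay" & grid$group == "HC", ]
  tie$dic <- 100
  expect_warning(ttab <- model_selection_table(tie), "simpler")
  expect_identical(ttab$model[ttab$winner], "linear")
  # a missing fit is an error
  expect_error(model_selection_table(grid[-1, ]), "missing fits")
})
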