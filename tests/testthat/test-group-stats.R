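test_that("internal-details sum averages within sub-category, then sums", {
  five_cues <- matrix(2, nrow = 5, ncol = 5,
                      dimnames = list(NULL, c("event", "place", "time",
                                              "perceptual", "emotion_thought")))
  expect_equal(internal_details_sum(list(details = five_cues)), 10)
  # two recorded cues only: averages over the available cues
  two_cues <- rbind(c(4, 2, 0, 1, 3), c(2, 0, 2, 1, 1))
  expect_equal(internal_details_sum(list(details = two_cues)),
               sum(colMeans(two_cues)))
  expect_equal(internal_details_sum(list(details = matrix(0, 3, 5))), 0)
  # semantic/external columns are excluded from the internal score
  with_sem <- cbind(five_cues, semantic = 9, external = 7)
  expect_equal(internal_details_sum(list(details = with_sem)), 10)
  expect_error(internal_details_sum(list(details = five_cues[0, , drop = FALSE])),
               "one recorded cue")
})

test_that("addiction severity averages full-sample z-scores", {
  kfg <- c(0, 2, 4, 28, 30, 32)
  sogs <- c(0, 1, 2, 9, 10, 11)
  sev <- addiction_severity(kfg, sogs)
  expect_equal(mean(sev), 0, tolerance = 1e-12)
  # a participant at the sample mean of both scores gets exactly 0
  kfg2 <- c(1, 2, 3); sogs2 <- c(5, 6, 7)
  expect_equal(addiction_severity(kfg2, sogs2)[2], 0, tolerance = 1e-12)
  # opposite unit z-scores cancel
  z1 <- (kfg - mean(kfg)) / sd(kfg); z2 <- (sogs - mean(sogs)) / sd(sogs)
  expect_equal(sev, (z1 + z2) / 2, tolerance = 1e-12)
  expect_error(addiction_severity(rep(1, 4), sogs[1:4]), "constant")
  # compound correlates with an outcome at least as well as the weaker part
  set.seed(1)
  latent <- rnorm(200)
  k3 <- latent + rnorm(200, 0, 0.5); s3 <- latent + rnorm(200, 0, 0.5)
  out <- latent + rnorm(200, 0, 0.8)
  r_comp <- cor(addiction_severity(k3, s3), out)
  expect_gte(r_comp, min(cor(k3, out), cor(s3, out)) - 1e-12)
})

test_that("Welch t-test matches the textbook formulas", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5, 6)
  got <- welch_t(x, y)
  # brute-force Welch/Satterthwaite computation
  vx <- var(x) / 3; vy <- var(y) / 6
  t_manual <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_manual <- (vx + vy)^2 / (vx^2 / 2 + vy^2 / 5)
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  sp <- sqrt((2 * var(x) + 5 * var(y)) / 7)
  expect_equal(got$t, t_manual, tolerance = 1e-10)
  expect_equal(got$df, df_manual, tolerance = 1e-10)
  expect_equal(got$p, p_manual, tolerance = 1e-10)
  expect_equal(got$cohens_d, (mean(x) - mean(y)) / sp, tolerance = 1e-10)
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  # equal variances and n: Satterthwaite df reduces to 2n - 2
  a <- c(1, 2, 3, 4); b <- c(11, 12, 13, 14)
  expect_equal(welch_t(a, b)$df, 6, tolerance = 1e-10)
})

test_that("Pearson correlation and its p-value behave", {
  x <- c(1, 4, 2, 8, 5)
  got <- pearson_r(x, 2 * x)
  expect_equal(got$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x + 10)$r, -1, tolerance = 1e-12)
  set.seed(2)
  u <- rnorm(500); v <- 0.9 * u + sqrt(1 - 0.81) * rnorm(500)
  expect_lt(abs(pearson_r(u, v)$r - 0.9), 0.05)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "n >= 3")
})

test_that("independent-correlation comparison matches the Fisher-z closed form", {
  same <- compare_independent_correlations(0.5, 30, 0.5, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  got <- compare_independent_correlations(0.9, 20, 0, 20)
  expect_equal(got$z, atanh(0.9) / sqrt(2 / 17), tolerance = 1e-10)
  expect_equal(got$z, 4.29, tolerance = 0.005)
  swapped <- compare_independent_correlations(0, 20, 0.9, 20)
  expect_equal(swapped$z, -got$z, tolerance = 1e-12)
  expect_error(compare_independent_correlations(1, 20, 0.5, 20), "< 1")
})

test_that("Cronbach's alpha spans perfect agreement to independence", {
  base_scores <- matrix(rnorm(3 * 20, mean = 10), nrow = 1)[rep(1, 3), ]
  expect_equal(cronbach_alpha(base_scores), 1, tolerance = 1e-12)
  set.seed(3)
  indep <- matrix(rnorm(2 * 60), nrow = 2)
  expect_lt(abs(cronbach_alpha(indep)), 0.15)
  # two raters with equal variances: alpha equals the Spearman-Brown formula
  set.seed(4)
  r1 <- as.numeric(scale(rnorm(40)))
  r2 <- as.numeric(scale(0.7 * r1 + rnorm(40)))
  r12 <- cor(r1, r2)
  expect_equal(cronbach_alpha(rbind(r1, r2)), 2 * r12 / (1 + r12),
               tolerance = 1e-10)
  expect_error(cronbach_alpha(matrix(1, 2, 10)), "degenerate")
})

test_that("regression on z-scored predictors recovers exact constructions", {
  set.seed(5)
  n <- 60
  preds <- data.frame(b_time = rnorm(n, 0.5, 0.1), audit = rnorm(n, 8, 4),
                      ftnd = rnorm(n, 4, 2), bdi = rnorm(n, 10, 6),
                      group = rep(c(0, 1), n / 2), eft = rnorm(n, 40, 10))
  dv <- 2 * as.numeric(scale(preds$bdi))
  fit <- suppressWarnings(regress_log_k(dv, preds))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "bdi"], 2, tolerance = 1e-8)
  others <- cf$estimate[!cf$term %in% c("(Intercept)", "bdi")]
  expect_true(all(abs(others) < 1e-8))
  expect_gt(fit$adj_r_squared, 0.999)
  expect_true(all(cf$ci_lower <= cf$estimate & cf$estimate <= cf$ci_upper))
  # five-predictor variant drops EFT
  fit5 <- suppressWarnings(regress_log_k(dv, preds, include_eft = FALSE))
  expect_false("eft" %in% fit5$coefficients$term)
  expect_error(regress_log_k(dv, preds[, -1]), "missing predictor")
  preds_coll <- preds; preds_coll$eft <- preds_coll$bdi
  expect_error(regress_log_k(dv, preds_coll), "collinearity")
})

test_that("pure-noise outcomes give near-zero adjusted R-squared on average", {
  set.seed(6)
  n <- 40
  r2 <- vapply(1:100, function(i) {
    preds <- data.frame(b_time = rnorm(n), audit = rnorm(n), ftnd = rnorm(n),
                        bdi = rnorm(n), group = rep(c(0, 1), n / 2),
                        eft = rnorm(n))
    regress_log_k(rnorm(n), preds)$adj_r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2)), 0.05)
})

test_that("scale-invariant statistics ignore affine input changes", {
  set.seed(7)
  x <- rnorm(25, 10, 3); y <- rnorm(25, 12, 4)
  w1 <- welch_t(x, y); w2 <- welch_t(5 * x + 2, 5 * y + 2)
  expect_equal(w1$t, w2$t, tolerance = 1e-10)
  expect_equal(w1$df, w2$df, tolerance = 1e-10)
  expect_equal(w1$cohens_d, w2$cohens_d, tolerance = 1e-10)
  r1 <- pearson_r(x, y); r2 <- pearson_r(-3 * x + 1, y)
  expect_equal(r1$r, -r2$r, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})
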