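# Group-level statistical layer: AMI internal-detail sum scores, the compound
# addiction-severity score, Welch comparisons with effect sizes, correlations
# and their direct comparison, inter-rater reliability, and the multiple
# regression predicting log discount rates.

#' Internal-details sum score of one AMI record
#'
#' For one participant and condition (autobiographical memory or episodic
#' future thinking), averages each of the five internal sub-category counts
#' (event, place, time, perceptual, emotion/thought) across the recorded event
#' cues, then sums the five sub-category means. Semantic and external details
#' are excluded by definition. Participants with fewer than five recorded cues
#' (e.g. lost recordings) are averaged over the cues available.
#'
#' @param record list or data frame row with element `details`: a cues x 5
#'   matrix (or data frame) of internal sub-category counts, one row per
#'   recorded cue; extra columns named `semantic` or `external` are ignored.
#' @return scalar sum score.
#' @export
internal_details_sum <- function(record) {
  det <- record$details
  if (is.null(det)) det <- record
  det <- as.matrix(as.data.frame(det)[, !(colnames(as.data.frame(det)) %in%
                                            c("semantic", "external")), drop = FALSE])
  if (nrow(det) < 1) stop("at least one recorded cue is required")
  if (ncol(det) != 5) stop("expected exactly five internal sub-categories")
  if (any(det < 0)) stop("detail counts must be >= 0")
  sum(colMeans(det))
}

#' Compound addiction-severity score
#'
#' z-transforms each gambling questionnaire over the full sample (both groups
#' pooled) and averages the two z-scores per participant. Used whenever the
#' two gambling measures are strongly correlated and a single severity index
#' is preferable.
#'
#' @param kfg,sogs numeric questionnaire scores, one value per participant.
#' @return numeric vector of compound scores (sample mean 0 by construction).
#' @export
addiction_severity <- function(kfg, sogs) {
  if (length(kfg) != length(sogs)) stop("kfg and sogs must be the same length")
  (zscore(kfg) + zscore(sogs)) / 2
}

#' Welch two-sample t-test with Cohen's d
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom (the
#' default comparison throughout this pipeline) plus Cohen's d computed with
#' the pooled SD. The sign convention is `x - y`; calling with (HC, PG) gives
#' negative d when the clinical group scores higher.
#'
#' @param x,y numeric samples, each n >= 2 with non-zero variance.
#' @return list with `t`, `df`, `p`, `cohens_d`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("degenerate variance in both samples")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  d <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, cohens_d = d, mean_x = mean(x), mean_y = mean(y))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, n >= 3, non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Compare two independent correlations (Fisher z)
#'
#' Tests whether two Pearson correlations from independent samples differ:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided normal
#' p-value. Swapping the correlations negates z.
#'
#' @param r1,r2 correlations with |r| < 1.
#' @param n1,n2 sample sizes (>= 4).
#' @return list with `z`, `p`.
#' @export
compare_independent_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cronbach's alpha across raters
#'
#' Internal-consistency reliability of a raters x items score matrix:
#' `alpha = k/(k-1) * (1 - sum(var_rater) / var_total)`, where `var_rater` are
#' the variances of each rater's scores across items and `var_total` is the
#' variance of the per-item rater sums. Used here for inter-rater reliability
#' of AMI detail scoring.
#'
#' @param scores numeric matrix, rows = raters, columns = items (>= 2 each).
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(scores) {
  scores <- as.matrix(scores)
  k <- nrow(scores)
  if (k < 2 || ncol(scores) < 2) stop("need >= 2 raters and >= 2 items")
  v_raters <- apply(scores, 1, stats::var)
  v_total <- stats::var(colSums(scores))
  if (v_total == 0) stop("degenerate variance: all item totals identical")
  k / (k - 1) * (1 - sum(v_raters) / v_total)
}

#' Multiple regression predicting log discount rates
#'
#' Ordinary least squares of log k on z-transformed predictors. The default
#' predictor set matches the full model: time-perception curvature exponent
#' `b`, AUDIT, FTND, BDI, group (coded 0/1 then z-scored), and EFT internal
#' details; `include_eft = FALSE` drops EFT for the five-predictor variant.
#' All predictors (and nothing else) are standardized before fitting, so
#' coefficients are per-SD effects on the log k scale.
#'
#' @param log_k numeric response.
#' @param predictors data frame with columns `b_time`, `audit`, `ftnd`, `bdi`,
#'   `group` (factor/character with two levels or 0/1 numeric), `eft`.
#' @param include_eft include the EFT predictor (default TRUE).
#' @param conf_level confidence level for the intervals.
#' @return object of class `td_regression`: data frame `coefficients`
#'   (term, estimate, se, ci_lower, ci_upper, p), plus `adj_r_squared`, `n`.
#' @export
regress_log_k <- function(log_k, predictors, include_eft = TRUE,
                          conf_level = 0.95) {
  need <- c("b_time", "audit", "ftnd", "bdi", "group")
  if (include_eft) need <- c(need, "eft")
  miss <- setdiff(need, names(predictors))
  if (length(miss)) stop("missing predictor(s): ", paste(miss, collapse = ", "))
  X <- predictors[, need, drop = FALSE]
  if (!is.numeric(X$group)) X$group <- as.numeric(factor(X$group)) - 1
  if (anyNA(X) || anyNA(log_k)) stop("complete cases required")
  if (nrow(X) <= length(need) + 2) stop("too few observations for the predictor count")
  Xz <- as.data.frame(lapply(X, zscore))
  qrX <- qr(as.matrix(cbind(1, Xz)))
  if (qrX$rank < ncol(Xz) + 1) stop("perfect collinearity among predictors")

  dat <- cbind(log_k = log_k, Xz)
  fit <- stats::lm(log_k ~ ., data = dat)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    se = sm$coefficients[, "Std. Error"],
    ci_lower = ci[, 1], ci_upper = ci[, 2],
    p = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, adj_r_squared = sm$adj.r.squared,
                 n = nrow(X), lm = fit),
            class = "td_regression")
}

#' @export
print.td_regression <- function(x, ...) {
  cat(sprintf("OLS on z-scored predictors (n = %d, adj. R^2 = %.3f)\n",
              x$n, x$adj_r_squared))
  print(transform(x$coefficients,
                  estimate = round(estimate, 3), se = round(se, 3),
                  ci_lower = round(ci_lower, 3), ci_upper = round(ci_upper, 3),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}
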