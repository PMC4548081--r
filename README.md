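# tdperception

Hierarchical Bayesian analysis of temporal discounting, time perception, and
episodic future thinking in clinical group comparisons.

## The problem

Pathological gambling — like substance addictions — is reliably associated with
steep *temporal discounting* (TD): delayed rewards lose subjective value
quickly. Two candidate mechanisms are (a) impaired *episodic future thinking*
(EFT; less vivid imagination of future events) and (b) a *non-linear
perception of time* (a delay of 180 days "feels" much less than 180 times a
single day). Testing these hypotheses requires a pipeline that estimates
per-participant discount rates from binary intertemporal choices, separates
time-perception non-linearity from response-scale non-linearity, scores cued
autobiographical interviews, and runs the group-level statistics — plus
simulated data with known ground truth to validate every step, since raw
behavioral data of such studies are rarely deposited.

`tdperception` implements that pipeline for studies comparing healthy controls
(HC) with pathological gamblers (PG):

* **Synthetic cohorts** with questionnaire covariates (BDI, FTND, AUDIT, KFG,
  SOGS) drawn from the published group moments, and latent behavioral
  parameters with configurable group effects.
* **Task simulation**: an adaptive staircase discounting task (20 EUR now vs a
  titrated amount at 7 delays), a 27-item fixed choice task, a circle-size
  time-perception task (18 delays, two symmetric presentation sets, a 90%
  anti-ceiling rule), and a circle-size calibration task.
* **Hierarchical Bayesian discounting inference** (Gibbs sampling via JAGS)
  with separate group-level distributions.
* **Time-perception model selection** among linear, quadratic, and power
  rating laws by the deviance information criterion (DIC), with the
  circle-size correction and corrected refit.
* **Group statistics**: Welch tests with Cohen's d, Pearson correlations and
  their Fisher-z comparison, Cronbach's alpha, AMI internal-detail sum scores,
  a compound addiction-severity z-score, and the multiple regression
  predicting log *k*.

## The models

**Discounting.** The subjective value of an amount *A* delayed by *D* days is
hyperbolic,

```
SV = A / (1 + k * D)
```

with participant-specific discount rate *k* (1/days). Choices between the
smaller-sooner and larger-later option follow a softmax rule with decision
noise (temperature) *β*,

```
p_LL = exp(SV_LL / β) / (exp(SV_LL / β) + exp(SV_SS / β))
```

Participant-level (log *k*, log *β*) are drawn from group-specific normal
distributions with weakly informative hyperpriors; the model is estimated by
MCMC, participants are summarized by the natural log of their posterior-median
*k*.

**Time perception.** Each rating session (circle diameter *y* as a fraction of
the screen scale, per delay or per target percentage *x*) is fit *per
participant* with three laws — linear `a*x + b`, quadratic `a*x² + b*x + c`,
power `a*x^b` — under Gaussian noise with precision π, and compared by DIC
(smaller is better), summed across participants per group. Time ratings are
then corrected for non-linear circle *production* by inverting the
participant's circle power law,

```
y_corrected = (y / a_circle)^(1 / b_circle)
```

and the model selection is repeated on the corrected ratings.

See `vignette("tdperception-methods")` for priors, parametrizations, numerical
choices, and known limitations.

## Worked example

```r
library(tdperception)

cohort <- generate_cohort(n_hc = 10, n_pg = 10, seed = 42)
cohort
#> Synthetic cohort: 20 participants ( HC=10, PG=10 )

tasks <- lapply(seq_len(20), function(i) {
  prof <- cohort$latent[i, ]
  list(adaptive = run_adaptive_task(prof, seed = 100 + i)$trials,
       fixed    = run_fixed_item_task(prof, seed = 200 + i))
})
adaptive <- do.call(rbind, lapply(tasks, `[[`, "adaptive"))
fixed    <- do.call(rbind, lapply(tasks, `[[`, "fixed"))
groups   <- setNames(cohort$latent$group, cohort$latent$id)

fit <- combine_and_refit(adaptive, fixed, groups, mcmc_config(chains = 2), seed = 7)
fit
#> Hierarchical discounting fit: 20 participants, 2 chains
#> converged: TRUE | max split-R-hat: 1.006
#>  group   mu_logk  sd_logk mu_logbeta sd_logbeta
#>     HC -4.371874 1.023720  0.6220385  0.5583786
#>     PG -3.837516 1.344511  0.3820259  0.6785189

logk <- summarize_log_k(fit)
head(logk, 3)
#>      id group    median_k     log_k
#> 1 hc001    HC 0.010522003 -4.554287
#> 2 hc002    HC 0.002235378 -6.103345
#> 3 hc003    HC 0.011063229 -4.504128

cor(cohort$latent$log_k, logk$log_k[match(cohort$latent$id, logk$id)])
#> 0.993

w <- welch_t(logk$log_k[logk$group == "HC"], logk$log_k[logk$group == "PG"])
#> Welch t(16.48) = -0.99, p = 0.336, Cohen d = -0.44
```

The group means of log *k* (`mu_logk`) sit higher for PG than HC — the
generated group effect — while the per-participant posterior medians track the
generative truth (recovery r = 0.99). The Welch comparison of the 10-per-group
summary values is non-significant at this sample size (d = −0.44; the sign
convention is HC − PG, so negative d means steeper discounting in PG), which is
why the pipeline's regression stage adjusts for covariates before interpreting
group status.

The one-call version of the full pipeline, including the time-perception
stages and group statistics:

```r
res <- run_pipeline(pipeline_config(n_hc = 10, n_pg = 10, seed = 42,
                                    output_dir = "out"))
res$rating$selection   # summed-DIC model-selection table (Table-2 layout)
recovery_report(res)   # recovery r / bias / RMSE per latent parameter
```

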