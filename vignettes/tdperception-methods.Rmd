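---
title: "Models and design choices in tdperception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in tdperception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tdperception` is a simulation-and-inference pipeline for behavioral studies
that compare temporal discounting, time perception, and episodic future
thinking between a clinical group (pathological gamblers, PG) and matched
healthy controls (HC). This vignette documents the models, the tunable
parameters and their defaults, the numerical decisions, and what the synthetic
data do and do not emulate.

## The discounting model

Each binary choice pits a fixed smaller-but-sooner reward (by default 20 EUR
immediately) against a larger-but-later reward of amount $A$ (EUR) delayed by
$D$ (days). Subjective value decays hyperbolically,

$$SV = \frac{A}{1 + k\,D},$$

with participant-specific discount rate $k$ (1/days), and choices follow a
softmax with decision noise $\beta$ (EUR):

$$p_{LL} = \frac{\exp(SV_{LL}/\beta)}{\exp(SV_{LL}/\beta) + \exp(SV_{SS}/\beta)}.$$

$\beta$ is a temperature *divisor*: larger $\beta$ means noisier choices
(probabilities approach 0.5), smaller $\beta$ approaches deterministic value
maximisation. This is stated explicitly because the opposite ("inverse
temperature") convention is equally common.

### Hierarchical estimation

Participant-level parameters are given group-specific population
distributions on the log scale,

$$\log k_s \sim \mathcal N(\mu_k^{(g)}, 1/\lambda_k^{(g)}), \qquad
  \log \beta_s \sim \mathcal N(\mu_\beta^{(g)}, 1/\lambda_\beta^{(g)}),$$

which enforces positivity and matches the strong right-skew of empirical $k$
distributions. Hyperpriors are weakly informative and exposed via
`hier_priors()`: $\mu_k \sim \mathcal N(-4, 2^2)$ (a prior median $k$ of about
0.018/day, spanning roughly 0.0003–1/day within two SD), $\mu_\beta \sim
\mathcal N(0, 2^2)$, and $\lambda \sim \text{Gamma}(1, 0.5)$. Sampling is
Gibbs/slice MCMC via JAGS; every chain is seeded deterministically from the
user's seed. Convergence is gated on split-$\hat R \le 1.05$ for every
monitored parameter (the fit errors by default, `on_nonconvergence = "warn"`
downgrades). Per-participant summaries are the natural log of the
posterior-median $k$, the scale on which all group statistics operate.

Numerical note: per-trial choice probabilities inside the sampler are squashed
into $[10^{-6}, 1-10^{-6}]$. Near-deterministic agents otherwise produce
probabilities that round to exactly 0 or 1 in double precision, making
observed choices lie off the model's support.

### The tasks

The adaptive task runs an independent bisection staircase per delay (defaults:
7 delays from 1 to 180 days, LL amounts bracketed in [20.5, 80] EUR, 6 trials,
step halving each trial): the midpoint of the current bracket is offered, an
LL choice lowers the upper bound, an SS choice raises the lower bound. For a
deterministic, consistent agent the final midpoint is within one final bracket
width of the closed-form indifference amount $20(1 + kD)$ whenever that value
lies inside the amount bounds; outside the bounds the staircase converges to
the nearer bound, which is all any procedure confined to the design's range
can do — tests therefore compare against the clamped closed form. The original
task's pacing rules (minimum waiting time, breaks) have no behavioral
consequence in this model and are not simulated.

The fixed-item task presents 27 smaller-now/larger-later items (the standard
monetary choice questionnaire design, bundled as plain CSV and fully
substitutable). Both tasks' trials concatenate per participant for the
combined refit, mirroring the practice of pooling tasks once their discount
rates prove highly reliable across tasks.

## The time-perception model

Participants express the subjective duration of a delay by producing a circle;
the produced *diameter* (as a fraction of the maximal scale) is the dependent
variable. Production composes two power laws — subjective time and circle
production —

$$\text{diameter} = a_c\,\bigl(a_t\,D^{\,b_t}\bigr)^{b_c} + \epsilon,
  \qquad \epsilon \sim \mathcal N(0, 1/\pi),$$

clipped to the scale $(0, 1]$. Delays (18 values, 1–190 days) are split into
two symmetric sets: odd-ranked delays are presented shortest-first, even-ranked
longest-first (the split rule is a package choice; only "two symmetric sets"
is constrained by the task design). Within a set, once a produced diameter
exceeds 90% of the scale, all *longer* delays of that set are dropped — the
anti-ceiling rule that keeps early large ratings from compressing the top of
the scale. The calibration task re-rates reference sizes (20, 40, 60, 80% of a
reference circle) plus every diameter produced in the time session.

### Rating-model fits and DIC

Each participant's session is fit separately (no pooling — per-participant
goodness of fit is the point) with three observation models, $\hat y = a x +
b$, $\hat y = a x^2 + b x + c$, and $\hat y = a x^b$, all with $y \sim
\mathcal N(\hat y, 1/\pi)$. Priors: coefficients $\mathcal N(0, 10^2)$ (power
parameters truncated positive), $\pi \sim \text{Gamma}(0.001, 0.001)$.
Predictors enter in days for delay ratings and as fraction-of-reference for
circle targets.

Model comparison uses the classic deviance information criterion,
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$ (deviance at
the posterior mean of the parameters, not the half-variance form), computed in
package code from the raw posterior draws, summed across participants within
(group × analysis), and won by the minimal sum; exact ties break toward the
model with fewer parameters, with a warning.

Two numerical choices matter here:

* **Power-law parametrization.** The $(a, b)$ posterior of $a x^b$ is
  banana-shaped; componentwise sampling mixes poorly and the arithmetic
  posterior mean lies off the ridge, corrupting $D(\bar\theta)$ (we observed
  wildly negative $p_D$). The sampler therefore works in the log-linear
  parametrization $\log \hat y = \alpha + b(\log x - \overline{\log x})$,
  where the posterior is near-Gaussian, and the DIC plug-in evaluates the
  scale parameter at $\exp(\overline{\log a})$ — the posterior mean on the
  estimation scale. $p_D$ is parametrization-dependent by construction; this
  choice is flagged here because alternatives exist.
* **Conjugate block sampling.** JAGS's `glm` module is loaded at package load
  so the linear and quadratic fits (whose polynomial predictors are strongly
  collinear on the raw delay scale) are block-updated rather than
  componentwise slice-sampled.

### The circle-size correction

Time ratings are corrected by inverting the participant's circle power law
with the posterior-median calibration parameters:

$$\hat y = (y / a_c)^{1/b_c}.$$

A participant with linear circle production ($a_c = b_c = 1$) passes through
unchanged. The correction is a deterministic point transform (posterior
uncertainty in $a_c, b_c$ is not propagated — the correction is defined as a
transform of ratings, and the corrected values are refit with all three laws
anyway). Composed with noiseless production and the true circle parameters the
round trip is exact to numerical precision, which the tests verify at 1e-8.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes, not the
behavioral content:

* **Covariates** are truncated normals with the published group means and SDs
  (BDI 4.6/16.5, FTND 3.5/4.45, AUDIT 7.15/10.3, KFG 1.75/30.15, SOGS
  0.45/9.65 for HC/PG). Because truncation at zero would inflate means (by ~1
  point for HC BDI, more for SOGS), the parent normal's location is solved so
  the *truncated* mean equals the configured value — configured moments are
  sampling moments.
* **Latent parameters**: the study reports no generative values, so defaults
  are field-typical conventions chosen once: $\log k \sim \mathcal N(-4.5, 1)$
  for HC and $\mathcal N(-3.8, 1)$ for PG (the direction matches the reported
  numerically-greater PG discounting; the offset is a convention, not a paper
  fact); $\log\beta \sim \mathcal N(0.5, 0.4)$ (about 1.65 EUR of decision
  noise); time law $a_t \approx 0.06$, $b_t \approx 0.5$; circle law $a_c
  \approx 1$, $b_c \approx 0.8$; rating precision $\pi$ log-normal around 400
  (rating SD ≈ 0.05 of the scale, "moderate noise"). Depression couples to
  discounting via `logk$bdi_slope` (default −0.35 per within-group SD of BDI)
  so directional regression checks have a defined truth.
* **AM/EFT detail scores** are correlated truncated Gaussians (default $\rho =
  0.9$), reproducing the strong memory–prospection coupling without modeling
  narratives or raters.
* **Seeding**: one master seed expands into per-participant, per-stage
  substreams, so adding or removing a participant never perturbs the draws of
  the others, and every pipeline output is bit-reproducible from (config,
  seed).

What the generator does **not** emulate: narrative content and rater behavior
(detail counts are drawn directly), reaction times, sequential dependencies
between trials beyond the staircase mechanics, item-order or fatigue effects,
and model misspecification (real raters are not exact power-law producers). A
green test suite on synthetic data therefore demonstrates that the inference
machinery recovers what the model family can express — not that the model
family is true of human raters.

For the directional acceptance simulation (group raises log $k$, depression
lowers it), effect sizes are set by a power analysis rather than the generator
defaults: offset 1.2 on log $k$, BDI slope −0.5, residual SD 0.8, giving
expected |z| of roughly 3.7 for both coefficients at $n = 40$, so the
recovered signs are near-certain per seed. These values are simulation
conditions for a sign check, not estimates of any real effect.

## Statistical layer

All group comparisons are Welch (unequal-variance) t-tests with Satterthwaite
degrees of freedom — the fractional dfs reported in the emulated study imply
exactly this correction — plus Cohen's d with the pooled SD and the sign
convention HC − PG. Correlations are Pearson with two-sided t-based p-values;
two independent correlations are compared by Fisher z. Inter-rater reliability
is Cronbach's alpha over the rater × item matrix. The AMI internal-details sum
score averages each of the five internal sub-categories (event, place, time,
perceptual, emotion/thought) across the recorded cues — participants with
fewer recorded cues are averaged over what exists — and sums the five means;
semantic and external details are excluded. Addiction severity averages the
full-sample z-scores of KFG and SOGS. The regression of log $k$ standardizes
all predictors (group coded 0/1 before z-scoring); the default predictor set
includes EFT details alongside time-perception curvature, AUDIT, FTND, BDI,
and group, with `include_eft = FALSE` for the five-predictor variant — the
emulated study's figure and text disagree on whether EFT entered, so both are
available and the fuller model is the default.

## Problem sizes and runtime choices

Tests and the acceptance script run at sizes chosen to exercise the full
machinery while staying desk-scale: cohorts of 40 (20 per group) for
hierarchical recovery (~70 combined trials each; 2 chains, 1000 retained draws
per chain), cohorts of 20 over 20 seeded replicates per law for DIC model
selection (2 chains, 600 draws — the summed-DIC decision is insensitive to
chain length at these data sizes), 500 replicates for regression CI coverage,
and 100 seeds for directional sign checks.

## Known limitations

* Per-participant shrinkage dominance — the hierarchical posterior landing
  closer to the group mean than the unpooled MLE for *every* weak participant
  — does not hold uniformly here: with decision noise around 1.65 EUR against
  item value differences up to ~50 EUR, a participant with few trials is often
  perfectly choice-consistent, so their unpooled likelihood is maximized on a
  flat ridge and "the MLE" is a tie-break convention that can land near the
  group mean by chance. Shrinkage holds clearly in aggregate; the strict
  per-participant comparison fails in a minority of near-tie cases.
* Recovery of the time-law exponent $b_t$ from corrected refits is attenuated
  relative to discount-rate recovery: estimation error in the circle
  parameters propagates through the correction, and the between-participant SD
  of $b_t$ (0.08) is small relative to that error at 18 ratings per session.
* DIC with the plug-in $p_D$ is known to mis-rank under strong posterior
  skew; the log-linear power parametrization mitigates but does not eliminate
  this. Ratings clipped at the scale boundary additionally distort all three
  laws; the generator's defaults keep productions in-scale, and the task's
  anti-ceiling rule plays the same role for the simulated sessions.
* `beta = 0` (deterministic agents) is supported in simulation as the
  analytic limit, but not in inference, where $\log\beta$ must be finite.
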