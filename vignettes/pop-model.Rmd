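---
title: "Joint modelling of learning curves and cognitive-impairment risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of learning curves and cognitive-impairment risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poplearn)
```

## The modelling problem

Measurement-burst studies assess cognition intensively — here, a 16-day
burst of brief daily response-time sessions in adults aged 70+ — and
separately adjudicate a clinical outcome, mild cognitive impairment
(MCI), in the clinic. Repeated testing produces practice effects: daily
mean response times fall along a learning curve. The scientifically
interesting individual differences are not the raw response times but the
*parameters* of that curve, and the question is whether those latent
markers carry predictive information about MCI beyond ordinary
demographics.

poplearn implements a *partially observable predictor* (POP) model: a
single Bayesian hierarchical model in which latent markers extracted from
the behavioral data and manifest covariates jointly predict the binary
outcome, with all uncertainty propagated in one pass.

## The model

**Process model.** For participant $i$ with daily mean response time
$y_{ti}$ (seconds) observed $M_{ti}$ days after their first assessment,

$$y_{ti} \sim N\!\left(a_i + g_i e^{-r_i M_{ti}},\ \varepsilon_i^2\right),$$

with person-level markers: asymptote $a_i$ (peak performance approached
with practice; larger = slower), gain $g_i$ (total practice-related
improvement), learning rate $r_i$ (per-day steepness) and
intra-individual variability $\varepsilon_i$ (day-to-day inconsistency).

**Structural model.** MCI status is Bernoulli with risk

$$\pi_i = \mathrm{logistic}\big(\beta_0 + \beta_a a_i + \beta_g g_i +
\beta_r r_i + \beta_\varepsilon \varepsilon_i + \beta_{age}\,
\mathrm{Age}_i + \beta_{sex}\,\mathrm{Sex}_i + \beta_{edu}\,
\mathrm{Edu}_i + \beta_{rac}\,\mathrm{Rac}_i + \beta_{eth}\,
\mathrm{Eth}_i\big),$$

where age and education are standardized and sex (1 = male), race
(1 = Black) and ethnicity (1 = Hispanic) are dummies. The latent markers
enter on their raw scale: this is what makes the group-level means and
SDs directly usable for counterfactual profiles, and it is required to
reproduce the worked risk chain below from the published point estimates.

**Priors.** Person-level markers are pooled through Gaussian group-level
distributions, e.g. $a_i \sim N(\mu_a, \sigma_a^2)$; hypermeans get
$N(0,1)$, group SDs positive half-normal $N_+(0,1)$, and every
regression coefficient $N(0,1)$ (appropriate because covariates are
standardized or dummy-coded).

Two support conventions deserve note.

* $\varepsilon_i$ must be positive for the Gaussian likelihood to exist.
  It is constrained by truncation at zero while keeping the
  $N(\mu_\varepsilon, \sigma_\varepsilon^2)$ prior density *without* its
  truncation normalization constant — the same convention a Stan program
  with a lower-bounded declaration and an unadjusted normal prior uses.
  The omitted constant depends on $(\mu_\varepsilon, \sigma_\varepsilon)$,
  so those two hyperparameters are interpreted under this convention;
  in practice it shifts $\sigma_\varepsilon$ slightly below the SD a
  fully normalized truncated model would report.
* $a_i$, $g_i$ and $r_i$ are left unconstrained when fitting (a negative
  $r_i$ legitimately models worsening performance). The synthetic
  generator, by contrast, draws $r_i$ and $\varepsilon_i$ by rejection
  until positive so that every simulated curve is an improving one.

## Interpreting the fit: the counterfactual risk chain

With the package's default coefficient and group-level values (posterior
means from a 316-person burst cohort with 29% MCI prevalence),
`mci_risk_chain()` evaluates the model-implied risk of a baseline
profile — latent markers at their group means, covariates at the
zero/reference coding — and then cumulative shifts:

```{r}
round(mci_risk_chain(), 3)
```

An average participant has a risk near 0.25; one group-SD slower peak
performance raises it to about 0.37; setting the race dummy raises it to
about 0.49; additionally learning one group-SD more slowly raises it to
about 0.60. (Plugging point estimates into the logistic is a plug-in
profile, not a posterior mean of the risk; averaging the logistic over a
posterior instead pulls values slightly towards one half, which is why
the last figure is sometimes quoted a hundredth lower.)

## The sampler

The joint posterior is sampled with an adaptive Metropolis-within-Gibbs
scheme written for this model's structure:

* Person-level markers are conditionally independent given the global
  parameters, so each of the four marker columns is updated for **all
  persons at once** with vectorized random-walk proposals and per-person
  acceptance, each person carrying its own adapted step size
  (Robbins–Monro adaptation towards 0.44 acceptance during warmup).
* Group means $\mu$ have conjugate Gibbs updates; group SDs $\sigma$ use
  random walks on the log scale.
* Two ensemble moves fix the classic slow modes of hierarchical models:
  a *translation* move shifting a whole marker column together with its
  group mean, and a *scale* move rescaling a column about its mean
  together with its group SD (Jacobian-corrected).
* The ten structural coefficients are strongly cross-correlated because
  the latent predictors are uncentred, so besides component-wise updates
  they receive a joint block proposal whose covariance is estimated
  during warmup (adaptive Metropolis).

`pop_fit(chains, warmup, draws, thin, seed)` counts `warmup` and `draws`
in retained (post-thinning) sweeps; `thin = 8` by default, chosen so
that the effective sample size of the slowest parameters (typically
$\sigma_r$) is adequate even at small draw budgets. Chains are
deterministic functions of `seed`. Initial values come from crude
per-person curve summaries (tail mean for $a$, first-day excess for $g$)
jittered per chain.

Non-convergence is never silent: `convergence_check()` computes split
R-hat (threshold 1.03 by default, the conventional burst-study standard)
and Geyer initial-monotone-sequence effective sample sizes (warn below
300), and flags offending parameters.

## Synthetic cohorts and what they do (not) show

`pop_simulate()` generates cohorts with known ground truth. Defaults are
the study conditions the model's default estimates describe: 316
participants, 16 daily assessments, age 77.54 (SD 4.98) years
standardized within-sample, 67% female, education 15.09 (SD 3.55) years,
43% Black, 13% Hispanic, latent markers from the default group-level
values, outcomes from the default coefficients (≈29% prevalence).
Generation composes covariates → latents → outcomes → time series and is
a deterministic function of the configuration seed.

Deliberate simplifications: generation starts at the *daily-mean* level
the model consumes (no six-sessions-per-day nesting, no trial-level
data); there are no missed sessions; the MCI label is a clean Bernoulli
draw, with none of the adjudication noise real cohorts show; race and
ethnicity are the two collapsed dummies the structural model consumes,
not full category sets. Recovery and ordering results on these cohorts
therefore validate the *estimation machinery*, not robustness to the
messiness of field data.

Values simulated at the support boundary ($r_i, \varepsilon_i \le 0$,
response times $\le 0$) are redrawn and the rejection counts logged on
the returned objects.

## Evaluation protocol

Cross-validation mirrors the intended clinical use: `cv_risk()` assigns
participants to stratified folds (single round-robin pass over
class-sorted, shuffled participants — fold sizes differ by at most one,
fold prevalence by at most one participant), then refits the model once
per fold with the held-out participants' MCI status set to missing.
Their response-time data stays in the model, so their latent markers are
still estimated; only their Bernoulli term is dropped. The held-out
prediction is the posterior mean of $\mathrm{logistic}(\eta_i)$ over the
refitted draws — the mean of the transform, not the transform of the
mean — so latent-marker uncertainty propagates into the prediction.

Three variants share folds and seeds: `full_pop` (learning-curve process
model), `latent_descriptors` (process model replaced by a per-person
mean/SD description, $y_{ti} \sim N(m_i, s_i^2)$ with the analogous
hierarchy), and `manifest_only` (Bayesian logistic regression on the
demographics alone, same priors).

Discrimination is summarized by the Mann–Whitney AUC (ties get half
credit; identical to the trapezoidal ROC area, which `roc_points()`
reproduces exactly), with a stratified percentile bootstrap interval
(2000 replicates by default, resampling within class with fixed class
sizes).

The process-model fit statistic `variance_explained()` is
$1 - SS_{res}/SS_{tot}$ with fitted values equal to posterior-mean
curves per person-day and $SS_{tot}$ about the grand mean pooled over
all person-days — one specific choice among the several quantities
"akin to an $R^2$".

## Numerical choices

* Credible intervals are empirical 2.5/97.5 percentiles (R's type-7
  quantile rule).
* Directional probabilities use strict inequalities; draws exactly at
  zero count in neither direction.
* Bernoulli log-likelihoods are computed on the log-odds scale with the
  `log1p(exp(·))` guard, so extreme linear predictors do not overflow.
* Degenerate inputs fail loudly: non-positive $\varepsilon$ or
  $\sigma$ are invalid-parameter errors ( `-Inf` density inside the
  sampler), single-class label vectors are AUC errors, zero total
  variance makes $R^2$ an error, and a single chain makes R-hat `NA`
  with a warning rather than a fabricated value.

## Test-scale choices

The test suite validates recovery at 150 participants × 16 days with the
default generating values, five seeds, and a reduced budget of 2 chains
× 500 warmup + 500 retained draws (about 40 s per fit): the 95%
intervals of the 18 structural and group-level parameters cover the
generating values for well over 85% of parameter–seed pairs, and all
split R-hats stay below 1.05. The predictive-ordering check runs the
full 316 × 16 design with ten folds and a 2 × 300/300 per-fold budget;
the process-model variant beats the manifest-only variant decisively
while the descriptor variant lands inside the process variant's
bootstrap interval — the qualitative pattern expected when the data
really are generated by the learning-curve process.

Two caveats found while validating are worth knowing. First, with 150
participants a $N(0,1)$ prior noticeably shrinks an intercept whose
generating value is $-2.8$, so $\beta_0$ is the parameter most likely to
miss its interval — a prior-data conflict, not a sampler defect (an
independent JAGS implementation of the same model reproduces the same
posterior). Second, because the generator draws $r_i$ and
$\varepsilon_i$ by rejection while the model treats them as
(effectively) unnormalized truncations, the generated population SDs
are a few percent smaller than the nominal ones, which makes
$\sigma_r$ and $\sigma_\varepsilon$ intervals land low now and then.

## Limitations

The exponential curve is one process model among many; the structural
layer only consumes a vector of person-level markers, so a different
process model can be swapped in by analogy with the built-in
`descriptive` variant. The sampler is a random-walk scheme tuned to this
model's dimensionality (hundreds of latent parameters); for much larger
cohorts a gradient-based sampler would scale better. Concurrent-outcome
prediction only is implemented; predicting *incident* outcomes from a
baseline burst requires a longitudinal extension.
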