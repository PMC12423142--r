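# poplearn

Joint Bayesian modelling of practice effects and cognitive-impairment
risk from measurement-burst data.

## What problem this solves

Intensive repeated cognitive testing (e.g. a 16-day burst of brief daily
response-time sessions in older adults) produces learning curves whose
*parameters* — not the raw scores — carry the interesting individual
differences. poplearn implements a **partially observable predictor
(POP) model**: a single hierarchical Bayesian model in which latent
markers extracted from the behavioral data combine with manifest
demographic covariates to predict a binary clinical outcome (mild
cognitive impairment, MCI), with uncertainty propagated end to end. It
is aimed at cognitive and aging researchers who want to test whether
model-based markers predict clinical outcomes instead of merely
correlating with them.

The model, for participant *i* on day *M_ti*:

```
y_ti ~ N(a_i + g_i * exp(-r_i * M_ti), eps_i^2)            (process model)

pi_i = logistic(b0 + b_a*a_i + b_g*g_i + b_r*r_i + b_eps*eps_i
                + b_age*Age_i + b_sex*Sex_i + b_edu*Edu_i
                + b_rac*Rac_i + b_eth*Eth_i)               (structural model)
MCI_i ~ Bernoulli(pi_i)
```

with Gaussian group-level pooling `a_i ~ N(mu_a, sigma_a^2)` (likewise
g, r, eps), `N(0,1)` priors on means and coefficients and half-normal
`N+(0,1)` priors on group SDs. `a` is asymptotic (peak) response time,
`g` the practice gain, `r` the learning rate, `eps` intra-individual
variability. Estimation is by an adaptive Metropolis-within-Gibbs
sampler built for this structure (vectorized person-level updates,
conjugate group means, ensemble translation/scale moves, adaptive block
proposals for the coefficients).

## Worked example

```r
library(poplearn)

## counterfactual risk profile under the default (cohort-calibrated)
## estimates: baseline, +1 SD asymptote, race dummy set, -1 SD learning
round(mci_risk_chain(), 3)
#>          baseline     asymptote+1sd      race_black=1 learning_rate-1sd
#>             0.250             0.372             0.490             0.596

## simulate a 60-person burst cohort with known truth and refit it
sim <- pop_simulate(pop_sim_config(n_participants = 60, seed = 11))
fit <- pop_fit(sim$data, chains = 2, warmup = 400, draws = 400,
               thin = 4, seed = 1)
summary(fit)
#>  parameter    mean ci_lower ci_upper p_negative p_positive   rhat      ess
#>      beta0 -0.6913  -2.5638   1.0225     0.7925     0.2075 1.0044 134.2541
#>     beta_a  0.2179  -0.4041   0.9261     0.2612     0.7388 1.0006 130.9618
#>  ...
#>       mu_a  2.9678   2.7323   3.1822     0.0000     1.0000 1.0047 384.7088
#>    sigma_a  0.8749   0.7156   1.0696     0.0000     1.0000 1.0177 228.8358
#>  ...
variance_explained(fit)
#> [1] 0.595
```

The first block says: an average participant carries a ~25% model-implied
MCI risk; being one group-SD slower at peak performance raises it to
~37%, and so on — the latent markers move risk on a clinically relevant
scale. In the refit, the recovered group-level rows sit on top of the
generating values (`mu_a` 2.97 vs 2.95 generating, `sigma_a` 0.87 vs
0.91), directional probabilities give graded sign evidence per
coefficient, and split R-hat / effective-sample-size columns certify the
draws. `variance_explained()` is the proportion of response-time
variance captured by the posterior-mean learning curves.

Cross-validated prediction with the three model variants:

```r
sim   <- pop_simulate(pop_sim_config(seed = 7))      # 316 x 16 cohort
preds <- cv_risk(sim$data, k = 10, chains = 2, warmup = 300,
                 draws = 300, thin = 3, seed = 7)
cv_metrics(preds, n_boot = 2000, seed = 7)
#>              variant       auc  ci_lower  ci_upper n_boot
#> 1           full_pop 0.7564053 0.6943893 0.8128433   2000
#> 2 latent_descriptors 0.7154503 0.6503251 0.7750886   2000
#> 3      manifest_only 0.5687597 0.4993146 0.6371409   2000
```

Demographics alone are barely better than chance; adding behavioral
data lifts AUC by ~0.19, and the interpretable process model costs
nothing relative to the atheoretical mean/SD description.

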