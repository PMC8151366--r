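# bombusoccu

Bayesian analysis of bumble bee (*Bombus*) queen surveys in apple orchards
under imperfect detection, together with the orchard-management covariates
those surveys revolve around: landscape enhancements (hedgerows, windbreaks,
flower strips, intercropping) and a toxicity-weighted index of pesticide
use. The package is written for pollinator ecologists analysing
repeated-visit detection/non-detection data at a modest number of sites,
and for anyone who wants a transparent, dependency-light reference
implementation of the hierarchical community occupancy model that dominates
this literature.

## The model

Queens of eight (morpho-)species are recorded as detected or not at each
orchard x season sampling unit over repeated visits. For species *i*, unit
*j*, visit *k*:

    z_ij ~ Bernoulli(psi_ij),   y_ijk | z_ij ~ Bernoulli(z_ij * p_ijk)

    logit(psi_ij) = phi_i + beta_Season,i Season_j + beta_Mgmt,i Enhancement_j
                    + beta_Int,i Pesticide_j + alpha_site(j)
    logit(p_ijk)  = eta_i + beta_Air,i Air_jk + beta_Time,i Time_jk

Species-level parameters are drawn from community normal distributions
(e.g. `phi_i ~ N(mu_phi, sigma_phi)`), sharing strength across species; a
site random effect ties units from the same orchard across seasons. Priors
are the field's vague conventions: N(0, 1000) (variance scale) on community
means, Uniform(0, 50) on community sds, Uniform(0, 150) on the site sd.
Fitting is by a purpose-built collapsed Metropolis-within-Gibbs sampler
(latent states summed out analytically; adaptive random-walk proposals;
hierarchical group moves), described in the methods vignette
(`vignettes/community-occupancy-methods.Rmd`).

Around the model sit:

* `build_detection_history()` — capture records to detection arrays, with
  morpho-species grouping (`map_morphospecies()`);
* `compute_intensity()` / `classify_intensity()` — the pesticide-use index
  `sum(toxicity x applications)` and its low/high split at 48.5;
* `rhat()`, `mcmc_error_ratio()`, `posterior_predictive_check()`,
  `compute_auc()` — convergence and fit diagnostics;
* `richness_contrast()` — posterior species richness differences between
  spring/fall, enhanced/plain, low/high-pesticide conditions;
* `fit_apple_glmm()` — Bayesian GLMMs for apple weight, diameter, sugar
  (normal) and seed count (Poisson) with an orchard random intercept;
* `generate_community_dataset()` / `generate_apple_dataset()` — synthetic
  data at the survey's design scale with known ground truth;
* `run_pipeline()` — reproducible simulate - fit - diagnose - summarize runs
  with a hash-carrying manifest.

## Worked example

Simulate a survey at the design scale (8 species, 12 orchards x 5 seasons,
3 visits), fit the community model at desk scale and summarize:

```r
library(bombusoccu)

map_morphospecies(c("Bombus fervidus", "Bombus perplexus", "Bombus impatiens"))
#> [1] "B. borealis group" "B. vagans group"   "B. impatiens"

compute_effort(visits = 3, teams = 2, observers_per_team = 2, hours_per_observer = 1)
#> [1] 12   # person-hours per orchard per season

sim <- generate_community_dataset(community_truth(), seed = 1)
sim$data
#> <detection_dataset> 8 species x 60 units (12 sites x 5 seasons) x up to 3 visits
#>   naive detection rate: 0.200; flags: 0

fit <- fit_community_model(sim$data, mcmc = mcmc_config(3, 6000, 3000, 3, seed = 2))
richness_contrast(fit, "enhancement")
#> <richness_summary> enhancement - no_enhancement = 1.52 (95% CRI: [0.90, 2.17]) *

compute_auc(fit, ndraws = 1000)
#> <auc_result> AUC = 0.785 (95% CRI: [0.771, 0.796]), 1000 draws

set.seed(3)
posterior_predictive_check(fit, ndraws = 1000)
#> <ppc_result> chisq_rows = 51.46 (p = 0.557); chisq_cols = 7.67 (p = 0.457)
```

The richness contrast says orchards with landscape enhancements hold on
average 1.5 more queen species than orchards without them (the `*` marks a
95% interval excluding zero); the AUC near 0.8 says the fitted occupancy
and detection probabilities discriminate detections from non-detections
well; the posterior predictive p-values near 0.5 say the model reproduces
its own data's row and column detection totals. On real data the same calls
apply to a `detection_dataset` built by `build_detection_history()` from
capture CSVs.

The full survey-scale configuration used for publication-quality inference
is `mcmc_config(5, 500000, 250000, 10)`; the desk-scale default above is
for iteration and testing.

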