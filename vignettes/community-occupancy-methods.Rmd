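---
title: "Methods: hierarchical community occupancy for bumble bee queens in orchards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical community occupancy for bumble bee queens in orchards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Repeated-visit surveys of bumble bee (*Bombus*) queens in apple orchards
record, for each of eight field-identifiable (morpho-)species, whether the
species was caught at an orchard on each of several one-hour visits. A
species present at an orchard is frequently missed on any single visit, so
raw counts confound occupancy with detectability. The package fits the
standard remedy: a Bayesian hierarchical multi-species occupancy model with
imperfect detection, from which species-specific covariate effects and
posterior species richness follow with full uncertainty.

The sampling unit is an orchard x season combination ("unit"): occupancy
status is assumed closed within a season (queens do not colonize or vacate
an orchard between the three visits of one season), while the same orchard
re-enters across seasons through a site-level random effect. With 12
orchards and 5 survey seasons (3 springs, 2 falls) the design has 60 units.

## Model

For species $i$, unit $j$ and visit $k$:

$$z_{ij} \sim \mathrm{Bernoulli}(\psi_{ij}), \qquad
y_{ijk} \mid z_{ij} \sim \mathrm{Bernoulli}(z_{ij}\, p_{ijk})$$

$$\mathrm{logit}(\psi_{ij}) = \varphi_i + \beta_{\mathrm{Season},i}\,
\mathrm{Season}_j + \beta_{\mathrm{Mgmt},i}\, \mathrm{Enhancement}_j +
\beta_{\mathrm{Int},i}\, \mathrm{Pesticide}_j + \alpha_{site(j)}$$

$$\mathrm{logit}(p_{ijk}) = \eta_i + \beta_{\mathrm{Air},i}\,
\mathrm{Air}_{jk} + \beta_{\mathrm{Time},i}\, \mathrm{Time}_{jk}$$

Season is coded spring = 0 (reference), fall = 1, so the season slope is a
fall effect; enhancement and pesticide are 0/1 site indicators. Each
species-level parameter is drawn from a community distribution, e.g.
$\varphi_i \sim N(\mu_\varphi, \sigma_\varphi)$ and likewise for every
slope, which shares strength across the eight species. The site effect is
$\alpha_s \sim N(0, \sigma_{site})$.

Priors are deliberately vague and follow the convention of the hierarchical
occupancy literature: $N(0, 1000)$ (variance scale, i.e. sd $\approx 31.6$)
on all community means, $\mathrm{Uniform}(0, 50)$ on all community standard
deviations, and $\mathrm{Uniform}(0, 150)$ on $\sigma_{site}$. The `N(0,
1000)` is interpreted as a variance (precision $0.001$), matching the
common BUGS/JAGS convention; it is configurable via
`community_model_spec(v_beta = )`.

Air temperature and time of day are standardized (z-scored over all
observed visits) before entering the detection model; the constants are
stored for back-transformation. This choice is flagged in the fitted
object's provenance: standardization stabilizes the sampler and makes slope
magnitudes comparable, and with a linear link it is a reparametrization,
not a change of model.

### The pesticide covariate

Orchard pesticide pressure is summarized by the intensity-of-use index
$\sum_i T_i A_i$, the number of applications $A_i$ of each product weighted
by its toxicity to bees $T_i \in \{1,2,3\}$, computed by
`compute_intensity()` from a pre-scored registry (toxicity scoring of named
products from regulatory sources is out of scope). The index is
dichotomized at 48.5 — "low" $\le 48.5$ — which splits the twelve reference
orchards (`orchard_design()`) into balanced classes of six. The threshold
is a configurable argument; the published analysis chose it to balance the
design, and whether it is a median split is not documented.

## Sampler

`fit_community_model()` runs a purpose-built, collapsed
Metropolis-within-Gibbs sampler, in vectorized pure R:

* **Collapsing.** All parameter updates evaluate the *z-marginalized*
  likelihood: a unit with a detection contributes $\log\psi_{ij} + \sum_k
  \log\mathrm{Bern}(y_{ijk}\mid p_{ijk})$, one without contributes
  $\log(\psi_{ij}\prod_k(1-p_{ijk}) + 1 - \psi_{ij})$. We first implemented
  the textbook data-augmented kernel (Gibbs on $z$, Metropolis on the
  rest); it has a *practically absorbing* region: once a species' $\psi$
  approaches 1, every $z_{ij}$ is imputed 1, which in turn supports an even
  larger intercept, and escape requires a jointly improbable set of $z$
  flips. The drift is reproducible in independent BUGS-family samplers of
  the same augmented model and inflates community means and sds by an
  order of magnitude. Summing $z$ out analytically removes the pathology;
  latent states are then drawn from their exact conditional
  $\Pr(z=1\mid\cdot) = \psi q / (\psi q + 1 - \psi)$, $q = \prod_k
  (1-p_{ijk})$, for every retained draw, so richness summaries still have
  full posterior uncertainty.
* **Block vectorization.** Species are conditionally independent given the
  hyperparameters and site effects, and sites given the rest, so
  component-wise random-walk proposals are made for all species (or sites)
  at once with element-wise accept/reject — mathematically identical to a
  component-wise scan, but without R-level loops.
* **Adaptation.** Proposal step sizes follow a Robbins-Monro recursion
  toward 0.44 acceptance during burn-in only; the post-burn-in kernel is
  fixed, so the retained draws come from a valid Markov chain.
* **Funnel (group) moves.** Vague hierarchical priors on a logit scale
  produce a funnel: when a community sd is small the species effects pin
  its mean, and mixing between the small-sd and large-sd regimes is slow.
  Two standard interchain moves fix this at negligible cost: a joint
  translation of a community mean together with all its species effects,
  and a joint rescaling $\sigma' = c\sigma$, $\beta_i' = \mu + c(\beta_i -
  \mu)$ with $c = e^\varepsilon$, whose prior ratio $-n\varepsilon$ and
  Jacobian $(n+1)\varepsilon$ combine to $+\varepsilon$ in the MH ratio.
  They are applied to the occupancy slope blocks and the site-effect block,
  where the funnel is consequential.
* **Community means** have conjugate normal full conditionals and are
  Gibbs-updated; community sds use random-walk Metropolis on the sd scale
  so the uniform priors apply directly.
* **Initialization** is at naive logit occupancy/detection rates (jittered
  per chain), slopes at 0, sds at 1; per-chain seeds derive
  deterministically from the master seed, and every stochastic output
  carries its seeds in the returned object.

A point worth knowing when interpreting hyperparameters: $N(0,1000)$ on a
logit-scale mean is *not* innocuous. It places most of its mass where
$\psi$ is numerically 0 or 1, so when the data admit quasi-separation (a
species seen at every enhanced site, say), the posterior of that species'
slope — and of the community sd above it — has a genuinely heavy upper
tail. The sampler explores it (the group moves exist for that reason), but
credible intervals for community means can be very wide. This mirrors the
behaviour of the same model in general-purpose Bayesian engines; it is a
property of the prior/model, not of the implementation.

## Diagnostics and derived quantities

* `rhat()` is the split-chain potential scale reduction factor (each chain
  halved, a stricter variant than the unsplit statistic), with the
  convention that zero total variance returns 1. The informal convergence
  threshold used in this literature is 1.06.
* `mcmc_error_ratio()` is the batch-means Monte Carlo standard error of the
  posterior mean divided by the posterior sd; chains are conventionally
  long enough below 0.02.
* `posterior_predictive_check()` simulates a replicate detection array per
  retained draw and compares Pearson $\chi^2$ discrepancies of observed
  and replicated detection totals aggregated over rows (units) and columns
  (species), with expectations $\sum \psi_{ij} p_{ijk}$ under the same
  draw. A stabilizer $c = 10^{-4}$ in each denominator guards empty
  expected cells; exact ties between observed and replicated discrepancies
  count one half, so the p-value of a model confronted with its own
  replicate is exactly 0.5.
* `compute_auc()` scores every observed species x unit x visit cell by
  $\psi_{ij} p_{ijk}$ and computes one Mann-Whitney (midrank-tie) AUC per
  draw against the observed binary outcomes, summarized by posterior mean
  and 95% credible interval — one AUC per draw because a single predictive
  ability with an uncertainty band is wanted.
* `richness_contrast()`: per draw, unit richness $\sum_i z_{ij}$ is
  averaged over the units of each condition (spring vs fall, enhancement vs
  none, low vs high pesticide) and differenced. Averaging over units is the
  aggregation consistent with contrasts on a 0-8 species scale; the choice
  is recorded here and in the output object. Richness can never fall below
  the number of species actually detected at a unit, because those latent
  states are forced.

## Apple quality GLMMs

`fit_apple_glmm()` models apple weight (g), diameter (mm) and sugar
(degrees Brix) as normal with identity link, and seed count as Poisson with
log link; fixed effects are landscape enhancement and high pesticide
intensity, with a random orchard intercept. Priors are $N(0,1000)$
(variance) on fixed effects and $\mathrm{Uniform}(0,100)$ on both standard
deviations. Year is not a model term (no between-year differences were
found in preliminary analysis of the motivating data); a `year` column is
accepted and ignored. The sampler is the same adaptive Metropolis machinery
(fixed effects component-wise, orchard effects as an independent vectorized
block, sds on the sd scale). `apple_fit_check()` provides the posterior
predictive Pearson $\chi^2$ p-value (same tie convention) and per-record
Pearson residuals at posterior means — standardized by the residual sd for
normal models and by $\sqrt{\mu}$ for the Poisson model.

## Synthetic data

Because the field data are not yet public, `generate_community_dataset()`
and `generate_apple_dataset()` generate data with exactly the statistical
structure the models assume, at the survey's design scale, returning the
full ground truth for recovery studies.

Defaults are fixed once as the package's study conditions:

* Design: 8 species; 12 sites, 6 with enhancements and 6 with high
  pesticide use assigned in a crossed, near-orthogonal pattern (period-2
  and period-4 alternation) so the two site covariates are not confounded;
  5 seasons (3 spring, 2 fall); 3 visits per unit; 30 apples per orchard.
* Community hyperparameters: $\mu_\varphi = 0$, $\sigma_\varphi = 1$; fall
  effect $\mu_\beta = -1$ (occupancy clearly lower in fall, as queens are
  scarce outside bloom), enhancement effect $+0.75$, high-pesticide effect
  $-0.4$, all slope sds $0.75$ — so that a typical draw shows strong
  positive enhancement effects for a few species and a negative pesticide
  effect for about one, qualitatively echoing the field findings;
  $\sigma_{site} = 0.75$; detection intercept mean $-0.5$ (per-visit
  detection around 0.4), time-of-day effect $+0.5$ (queens easier to find
  later in the survey window), air-temperature effect 0 (no effect, as in
  the field analysis).
* Visit covariates: air temperature $N(15, 4^2)$ degrees C in spring,
  $N(12, 4^2)$ in fall; time of day uniform on a 12 h window. These exist
  for realism only — both are standardized before fitting.
* Apple responses: weight $150$ g intercept, enhancement $+7.81$,
  high-pesticide $+29.24$, orchard sd 15, residual sd 30; diameter 75 mm
  ($-0.68$, $+3.98$; 3; 6); sugar 13 Brix ($-0.04$, $+0.60$; 0.5; 1.2);
  seeds $\log 8$ log-intercept, enhancement $-0.20$, pesticide $+0.03$,
  orchard sd 0.15.

What the generator does *not* emulate: spatial structure among orchards
(regions, distances), year effects, temporal autocorrelation of covariates
within a day, observer heterogeneity, abundance-dependent detection, or
misidentification between morpho-species. Passing recovery tests therefore
demonstrates that the estimation machinery is correct under the model's own
assumptions — not that the model is adequate for any particular field
dataset; the posterior predictive checks are the in-package tool for the
latter question.

## Numerical choices

* Probabilities from the logit link are clipped to $(10^{-12}, 1 -
  10^{-12})$; all likelihood terms are computed from linear predictors via
  stable `log1p(exp(.))` forms, so saturated parameters never produce
  non-finite log-likelihoods.
* The marginal empty-history term uses a two-term log-sum-exp.
* R-hat returns 1 for zero total variance and `Inf` for constant unequal
  chains; the batch-means error ratio is undefined (NA) for a zero-sd
  chain.
* Ties: AUC uses midranks; posterior predictive p-values count exact ties
  as one half.
* Morpho-species: *B. griseocollis* is morphologically compatible with two
  groups; the default map assigns it to the *B. bimaculatus* group. The map
  is an explicit argument, so alternative groupings are one line away.
* Desk-scale MCMC defaults (3 chains x 6,000 iterations, 3,000 burn-in,
  thinning 3) are the package's test-and-demonstration configuration; the
  publication-scale configuration (5 x 500,000 / 250,000 / 10 for the
  community model, 5 x 250,000 / 125,000 / 10 for the apple models) is one
  `mcmc_config()` call. Simulation studies in the test suite use 20
  replicates at the full design scale (8 x 60 x 3) with the desk-scale
  sampler; the 1-species oracle comparison uses 3 x 20,000 iterations
  against a dense-grid posterior computed under the model's exact marginal
  prior.

## Known limitations

* Hyperparameter posteriors under the prescribed vague priors are heavy
  tailed whenever the detection histories admit quasi-separation; community
  mean estimates should be read together with their (wide) intervals, and
  species-level conclusions drawn from the species effects and richness
  contrasts, which are well identified.
* No data augmentation for never-detected species: the community consists
  of the eight observed taxa, so richness is bounded by 8 and the model
  makes no statement about wholly undetected species.
* Abundance is out of scope (recapture rates in the motivating survey were
  too low for individual-level modelling); the model is
  detection/non-detection only.
* The pipeline is plain sequential execution with a manifest — no caching
  or workflow-engine integration.
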