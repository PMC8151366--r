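#' Specification of the hierarchical community occupancy model
#'
#' Occupancy of species i at unit j (an orchard x season combination) follows
#' `logit(psi_ij) = phi_i + beta_season_i * Season_j + beta_enhancement_i *
#' Enhancement_j + beta_pesticide_i * Pesticide_j + alpha_site(j)`, and
#' detection on visit k follows `logit(p_ijk) = eta_i + beta_air_i * Air_jk +
#' beta_time_i * Time_jk`, with species-level parameters drawn from community
#' normal distributions (e.g. `phi_i ~ N(mu_phi, sigma_phi)`), a site random
#' effect `alpha ~ N(0, sigma_site)`, vague `N(0, v_beta)` priors (variance
#' scale, default 1000) on the community means, and uniform priors on all
#' standard deviations.
#'
#' @param occ_covariates Occupancy covariates to include, subset of
#'   `c("season", "enhancement", "pesticide")`.
#' @param det_covariates Detection covariates, subset of `c("air", "time")`.
#' @param site_effect Include the orchard-level random intercept tying
#'   units from the same site across seasons?
#' @param v_beta Prior variance of the community-mean (and species-mean)
#'   normal priors.
#' @param sd_upper Upper bound of the Uniform(0, sd_upper) priors on the
#'   community standard deviations.
#' @param sd_upper_site Upper bound for the site random-effect standard
#'   deviation prior.
#' @return Object of class `community_model_spec`.
#' @export
community_model_spec <- function(occ_covariates = c("season", "enhancement", "pesticide"),
                                 det_covariates = c("air", "time"),
                                 site_effect = TRUE,
                                 v_beta = 1000,
                                 sd_upper = 50,
                                 sd_upper_site = 150) {
  occ_covariates <- as.character(occ_covariates)
  det_covariates <- as.character(det_covariates)
  if (!all(occ_covariates %in% c("season", "enhancement", "pesticide")))
    stop_input("unknown occupancy covariate")
  if (!all(det_covariates %in% c("air", "time")))
    stop_input("unknown detection covariate")
  v_beta <- assert_number(v_beta, "v_beta")
  if (v_beta <= 0) stop_input("'v_beta' must be positive")
  if (assert_number(sd_upper, "sd_upper") <= 0 ||
      assert_number(sd_upper_site, "sd_upper_site") <= 0)
    stop_input("uniform prior upper bounds must be positive")
  structure(list(occ_covariates = occ_covariates,
                 det_covariates = as.character(det_covariates),
                 site_effect = assert_flag(site_effect, "site_effect"),
                 v_beta = v_beta, sd_upper = sd_upper,
                 sd_upper_site = sd_upper_site),
            class = "community_model_spec")
}

#' MCMC configuration
#'
#' Defaults are a desk-scale configuration (3 chains x 6,000 iterations,
#' 3,000 burn-in, thinning 3) suitable for simulation studies and tests; the
#' full-scale analysis configuration used for publication-quality inference
#' is 5 chains x 500,000 iterations with 250,000 burn-in and thinning 10
#' (`mcmc_config(5, 500000, 250000, 10)`).
#'
#' @param chains Number of chains (>= 2, so R-hat is defined).
#' @param iterations Iterations per chain.
#' @param burn_in Burn-in iterations discarded from each chain; proposal
#'   step sizes adapt only during burn-in.
#' @param thin Thinning interval applied after burn-in.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @param target_accept Target acceptance rate of the component-wise adaptive
#'   random-walk Metropolis updates.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, iterations = 6000, burn_in = 3000,
                        thin = 3, seed = 1, target_accept = 0.44) {
  chains <- assert_count(chains, "chains", min = 2)
  iterations <- assert_count(iterations, "iterations", min = 2)
  burn_in <- assert_count(burn_in, "burn_in", min = 0)
  thin <- assert_count(thin, "thin", min = 1)
  seed <- assert_count(seed, "seed", min = 0)
  if (burn_in >= iterations) stop_input("'burn_in' must be smaller than 'iterations'")
  ta <- assert_number(target_accept, "target_accept")
  if (ta <= 0 || ta >= 1) stop_input("'target_accept' must be in (0, 1)")
  structure(list(chains = chains, iterations = iterations, burn_in = burn_in,
                 thin = thin, seed = seed, target_accept = ta),
            class = "mcmc_config")
}
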