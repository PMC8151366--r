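## Synthetic-data generators mirroring the survey design: 12 orchards
## surveyed over five seasons (three springs, two falls) with three visits
## per orchard-season for the community model, and 30 apples per orchard for
## the quality GLMMs. Ground truth is returned alongside the data for
## parameter-recovery studies.

#' Ground truth settings for the community occupancy generator
#'
#' Hyperparameter and design settings from which a synthetic detection
#' dataset is generated. Defaults mirror the motivating survey: 8 species,
#' 12 sites (half with landscape enhancements, half with high pesticide use,
#' assigned in a crossed, near-orthogonal pattern), 5 seasons (3 spring,
#' 2 fall), 3 visits per unit. Community-mean defaults qualitatively echo
#' the field findings: occupancy lower in fall, higher with enhancements,
#' slightly lower under high pesticide use; detection improving with time
#' since sunrise and indifferent to air temperature.
#'
#' @param n_species,n_sites,n_spring,n_fall,visits Design dimensions.
#' @param enhancement_split,pesticide_split Number of sites with
#'   enhancements / with high pesticide use.
#' @param mu_phi,sigma_phi Community mean and sd of occupancy intercepts.
#' @param mu_beta_season,mu_beta_enhancement,mu_beta_pesticide Community
#'   means of the occupancy slopes (fall, enhancement and high-pesticide
#'   effects on the logit scale).
#' @param sigma_beta Community sd shared by all slope distributions.
#' @param sigma_site Sd of the site random effect.
#' @param mu_eta,sigma_eta Community mean and sd of detection intercepts.
#' @param mu_beta_air,mu_beta_time Community means of the detection slopes
#'   (per sd of standardized covariate).
#' @return Object of class `community_truth`.
#' @export
community_truth <- function(n_species = 8, n_sites = 12, n_spring = 3, n_fall = 2,
                            visits = 3, enhancement_split = n_sites %/% 2,
                            pesticide_split = n_sites %/% 2,
                            mu_phi = 0, sigma_phi = 1,
                            mu_beta_season = -1, mu_beta_enhancement = 0.75,
                            mu_beta_pesticide = -0.4, sigma_beta = 0.75,
                            sigma_site = 0.75,
                            mu_eta = -0.5, sigma_eta = 0.75,
                            mu_beta_air = 0, mu_beta_time = 0.5) {
  n_species <- assert_count(n_species, "n_species")
  n_sites <- assert_count(n_sites, "n_sites")
  n_spring <- assert_count(n_spring, "n_spring", min = 0)
  n_fall <- assert_count(n_fall, "n_fall", min = 0)
  if (n_spring + n_fall < 1) stop_input("need at least one season")
  visits <- assert_count(visits, "visits")
  enhancement_split <- assert_count(enhancement_split, "enhancement_split", min = 0)
  pesticide_split <- assert_count(pesticide_split, "pesticide_split", min = 0)
  if (enhancement_split > n_sites || pesticide_split > n_sites)
    stop_input("site splits cannot exceed n_sites")
  for (s in c(sigma_phi, sigma_beta, sigma_site, sigma_eta))
    if (assert_number(s, "sigma") <= 0) stop_input("all sigmas must be positive")
  structure(as.list(environment()), class = "community_truth")
}

# Crossed low-collinearity 0/1 site assignments: enhancement alternates with
# period 2, pesticide with period 4, then tail entries are flipped to honour
# the requested split counts exactly.
.site_assignments <- function(n_sites, enh_split, pest_split) {
  s <- seq_len(n_sites) - 1L
  enh <- s %% 2L
  pest <- (s %/% 2L) %% 2L
  fix <- function(v, want) {
    excess <- sum(v) - want
    if (excess > 0) v[rev(which(v == 1))[seq_len(excess)]] <- 0L
    if (excess < 0) v[rev(which(v == 0))[seq_len(-excess)]] <- 1L
    v
  }
  list(enhancement = fix(enh, enh_split), pesticide = fix(pest, pest_split))
}

#' Generate a synthetic community detection dataset with known truth
#'
#' Draws species-level parameters from the community distributions, site
#' effects, visit covariates (air temperature cooler in fall than spring;
#' time of day uniform over a 12-hour survey window), latent occupancy
#' states and detections, exactly following the model the package fits.
#'
#' @param truth A [community_truth()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with `data` (a [detection_dataset()]) and `truth` (the input
#'   settings plus the realized species parameters, site effects, latent
#'   states and cell probabilities).
#' @export
generate_community_dataset <- function(truth = community_truth(), seed = 1) {
  if (!inherits(truth, "community_truth")) stop_input("'truth' must be a community_truth")
  seed <- assert_count(seed, "seed", min = 0)
  set.seed(seed)
  n <- truth$n_species
  S <- truth$n_sites
  seasons <- c(paste0("spring-", seq_len(truth$n_spring)),
               paste0("fall-", seq_len(truth$n_fall)))
  fall <- c(rep(0L, truth$n_spring), rep(1L, truth$n_fall))
  J <- S * length(seasons)
  K <- truth$visits

  asg <- .site_assignments(S, truth$enhancement_split, truth$pesticide_split)
  units <- data.frame(
    site_id = rep(seq_len(S), times = length(seasons)),
    season_id = rep(seasons, each = S),
    season_fall = rep(fall, each = S),
    enhancement = rep(asg$enhancement, times = length(seasons)),
    pesticide_high = rep(asg$pesticide, times = length(seasons))
  )

  sp <- list(
    phi = stats::rnorm(n, truth$mu_phi, truth$sigma_phi),
    beta_season = stats::rnorm(n, truth$mu_beta_season, truth$sigma_beta),
    beta_enhancement = stats::rnorm(n, truth$mu_beta_enhancement, truth$sigma_beta),
    beta_pesticide = stats::rnorm(n, truth$mu_beta_pesticide, truth$sigma_beta),
    eta = stats::rnorm(n, truth$mu_eta, truth$sigma_eta),
    beta_air = stats::rnorm(n, truth$mu_beta_air, truth$sigma_beta),
    beta_time = stats::rnorm(n, truth$mu_beta_time, truth$sigma_beta)
  )
  alpha <- stats::rnorm(S, 0, truth$sigma_site)

  air_mean <- ifelse(rep(fall, each = S) == 1, 12, 15)
  air <- matrix(stats::rnorm(J * K, air_mean, 4), J, K)
  tod <- matrix(stats::runif(J * K, 0, 12), J, K)
  air_s <- (air - mean(air)) / stats::sd(air)
  tod_s <- (tod - mean(tod)) / stats::sd(tod)

  lpsi <- outer(sp$phi, rep(1, J)) +
    outer(sp$beta_season, units$season_fall) +
    outer(sp$beta_enhancement, units$enhancement) +
    outer(sp$beta_pesticide, units$pesticide_high) +
    matrix(alpha[units$site_id], n, J, byrow = TRUE)
  psi <- inv_logit(lpsi)
  z <- matrix(stats::rbinom(n * J, 1, psi), n, J)

  p <- array(NA_real_, c(n, J, K))
  for (i in seq_len(n))
    p[i, , ] <- inv_logit(sp$eta[i] + sp$beta_air[i] * air_s + sp$beta_time[i] * tod_s)
  y <- array(stats::rbinom(n * J * K, 1, as.vector(p) * rep(as.vector(z), K)),
             c(n, J, K))

  species <- paste0("species-", seq_len(n))
  data <- detection_dataset(y, species, units, air, tod)
  list(data = data,
       truth = c(truth, list(species_params = sp, alpha = alpha, z = z,
                             psi = psi, p = p, seed = seed)))
}

#' Ground truth settings for the apple-quality generator
#'
#' Per-response fixed effects, orchard sd and residual sd (normal responses)
#' or log-scale intercept (seed counts). Defaults put the responses on their
#' field scales (Cortland apples: weight around 150 g, diameter around 75
#' mm, sugar around 13 degrees Brix, about 8 seeds) with enhancement and
#' pesticide effects echoing the motivating analysis, e.g. a 29 g weight
#' increase under high pesticide use and a -0.20 log-scale enhancement
#' effect on seed count.
#'
#' @param n_orchards,apples_per_orchard Design dimensions.
#' @param enhancement_split,pesticide_split Orchards with enhancements / high
#'   pesticide use.
#' @param responses Named list of per-response settings; each element has
#'   `family` ("gaussian"/"poisson"), `intercept`, `beta_enhancement`,
#'   `beta_pesticide`, `sigma_orchard` and (gaussian only) `sigma_resid`.
#' @return Object of class `apple_truth`.
#' @export
apple_truth <- function(n_orchards = 12, apples_per_orchard = 30,
                        enhancement_split = n_orchards %/% 2,
                        pesticide_split = n_orchards %/% 2,
                        responses = list(
                          weight = list(family = "gaussian", intercept = 150,
                                        beta_enhancement = 7.81, beta_pesticide = 29.24,
                                        sigma_orchard = 15, sigma_resid = 30),
                          diameter = list(family = "gaussian", intercept = 75,
                                          beta_enhancement = -0.68, beta_pesticide = 3.98,
                                          sigma_orchard = 3, sigma_resid = 6),
                          sugar = list(family = "gaussian", intercept = 13,
                                       beta_enhancement = -0.04, beta_pesticide = 0.60,
                                       sigma_orchard = 0.5, sigma_resid = 1.2),
                          seeds = list(family = "poisson", intercept = log(8),
                                       beta_enhancement = -0.20, beta_pesticide = 0.03,
                                       sigma_orchard = 0.15))) {
  n_orchards <- assert_count(n_orchards, "n_orchards", min = 2)
  apples_per_orchard <- assert_count(apples_per_orchard, "apples_per_orchard")
  for (r in responses) {
    if (!r$family %in% c("gaussian", "poisson")) stop_input("unknown family")
    if (r$sigma_orchard <= 0) stop_input("sigma_orchard must be positive")
    if (r$family == "gaussian" && r$sigma_resid <= 0)
      stop_input("sigma_resid must be positive")
  }
  structure(list(n_orchards = n_orchards, apples_per_orchard = apples_per_orchard,
                 enhancement_split = enhancement_split,
                 pesticide_split = pesticide_split, responses = responses),
            class = "apple_truth")
}

#' Generate a synthetic apple-quality table with known truth
#'
#' @param truth An [apple_truth()].
#' @param seed Integer seed.
#' @param year Year label attached to every record (the models ignore it).
#' @return List with `records` (data frame: `orchard_id`, `year`,
#'   `enhancement`, `pesticide_high` and one column per response) and
#'   `truth` (settings plus realized orchard effects).
#' @export
generate_apple_dataset <- function(truth = apple_truth(), seed = 1, year = 2018) {
  if (!inherits(truth, "apple_truth")) stop_input("'truth' must be an apple_truth")
  seed <- assert_count(seed, "seed", min = 0)
  set.seed(seed)
  nO <- truth$n_orchards; nA <- truth$apples_per_orchard
  asg <- .site_assignments(nO, truth$enhancement_split, truth$pesticide_split)
  orch <- rep(seq_len(nO), each = nA)
  rec <- data.frame(orchard_id = orch, year = year,
                    enhancement = asg$enhancement[orch],
                    pesticide_high = asg$pesticide[orch])
  effects <- list()
  for (nm in names(truth$responses)) {
    r <- truth$responses[[nm]]
    u <- stats::rnorm(nO, 0, r$sigma_orchard)
    mu <- r$intercept + r$beta_enhancement * rec$enhancement +
      r$beta_pesticide * rec$pesticide_high + u[orch]
    rec[[nm]] <- if (r$family == "gaussian") stats::rnorm(nrow(rec), mu, r$sigma_resid)
                 else stats::rpois(nrow(rec), exp(mu))
    effects[[nm]] <- u
  }
  list(records = rec, truth = c(truth, list(orchard_effects = effects, seed = seed)))
}
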