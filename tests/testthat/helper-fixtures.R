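# Small in-code fixtures and independent oracles shared across tests.

# A tiny detection dataset with arbitrary (seeded) binary histories and
# covariates; all visits observed.
make_tiny_dataset <- function(n_species = 2, n_sites = 3, n_seasons = 2, K = 3,
                              seed = 1, p_detect = 0.4) {
  set.seed(seed)
  J <- n_sites * n_seasons
  y <- array(rbinom(n_species * J * K, 1, p_detect), c(n_species, J, K))
  units <- data.frame(
    site_id = rep(seq_len(n_sites), n_seasons),
    season_id = rep(c(paste0("spring-", seq_len(ceiling(n_seasons / 2))),
                      paste0("fall-", seq_len(floor(n_seasons / 2))))[seq_len(n_seasons)],
                    each = n_sites),
    season_fall = rep(rep(0:1, length.out = n_seasons), each = n_sites),
    enhancement = rep(rep(0:1, length.out = n_sites), n_seasons),
    pesticide_high = rep(rep(c(1, 0), length.out = n_sites), n_seasons)
  )
  air <- matrix(rnorm(J * K, 14, 4), J, K)
  tod <- matrix(runif(J * K, 0, 12), J, K)
  detection_dataset(y, paste0("sp", seq_len(n_species)), units, air, tod)
}

# Random parameter list for the tiny dataset.
random_params <- function(n_species, n_sites, seed = 1) {
  set.seed(seed)
  list(phi = rnorm(n_species, 0, 1),
       beta_season = rnorm(n_species, 0, 0.7),
       beta_enhancement = rnorm(n_species, 0, 0.7),
       beta_pesticide = rnorm(n_species, 0, 0.7),
       eta = rnorm(n_species, -0.3, 0.7),
       beta_air = rnorm(n_species, 0, 0.4),
       beta_time = rnorm(n_species, 0, 0.4),
       alpha = rnorm(n_sites, 0, 0.5))
}

# Independent oracle: the z-marginalized likelihood by brute-force summation
# over every latent configuration z in {0,1}^(species x units).
enumerate_loglik <- function(params, data) {
  y <- data$y
  n <- dim(y)[1]; J <- dim(y)[2]
  psi <- occupancy_prob(params, data)
  p <- detection_prob(params, data)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(J)) {
      yij <- y[i, j, ]; pij <- p[i, j, ]
      ok <- !is.na(yij)
      # z = 1 term
      l1 <- psi[i, j] * prod(ifelse(yij[ok] == 1, pij[ok], 1 - pij[ok]))
      # z = 0 term: only possible if no detection
      l0 <- if (any(yij[ok] == 1)) 0 else (1 - psi[i, j])
      total <- total + log(l1 + l0)
    }
  }
  total
}

# Build a community_posterior whose draws put every species at fixed
# occupancy/detection linear-predictor values (for exact checks of the
# diagnostics on a controlled posterior).
rigged_posterior <- function(data, phi_value, eta_value, ndraws = 50) {
  fit <- fit_community_model(data, mcmc = mcmc_config(2, 60, 20, 2, seed = 1))
  dr <- fit$draws[rep(1, ndraws), , drop = FALSE]
  dr[, grep("^phi\\[", colnames(dr))] <- phi_value
  dr[, grep("^eta\\[", colnames(dr))] <- eta_value
  dr[, grep("^beta_", colnames(dr))] <- 0
  dr[, grep("^alpha\\[", colnames(dr))] <- 0
  fit$draws <- dr
  fit$z <- fit$z[rep(1, ndraws), , , drop = FALSE]
  fit
}
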