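test_that("configuration objects validate their inputs", {
  expect_error(mcmc_config(1), "chains")
  expect_error(mcmc_config(3, 1000, 1000), "burn_in")
  expect_error(mcmc_config(3, 1000, 500, 0), "thin")
  expect_error(community_model_spec(v_beta = -1), "positive")
  expect_error(community_model_spec(occ_covariates = "weather"), "unknown")
  cfg <- mcmc_config(3, 6000, 3000, 3)
  expect_equal((cfg$iterations - cfg$burn_in) %/% cfg$thin, 1000)
})

test_that("fitting requires non-degenerate data and returns aligned draws", {
  d <- make_tiny_dataset(seed = 2)
  d0 <- d; d0$y[] <- 0
  expect_error(fit_community_model(d0), "degenerate")
  fit <- fit_community_model(d, mcmc = mcmc_config(2, 300, 100, 2, seed = 4))
  expect_s3_class(fit, "community_posterior")
  expect_equal(nrow(fit$draws), 2 * 100)
  expect_equal(dim(fit$z), c(200, 2, 6))
  expect_true(all(is.finite(fit$draws)))
  # latent states are 1 wherever the species was detected
  det <- apply(d$y == 1, c(1, 2), any)
  for (dd in c(1, 50, 200))
    expect_true(all(fit$z[dd, , ][det] == 1))
  # sds respect their uniform prior bounds
  expect_true(all(fit$draws[, grep("^sigma_(phi|beta|eta)", colnames(fit$draws))] < 50))
  expect_true(all(fit$draws[, "sigma_site"] < 150))
})

test_that("refitting with the same master seed reproduces draws exactly", {
  d <- make_tiny_dataset(seed = 6)
  f1 <- fit_community_model(d, mcmc = mcmc_config(2, 300, 100, 2, seed = 11))
  f2 <- fit_community_model(d, mcmc = mcmc_config(2, 300, 100, 2, seed = 11))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$z, f2$z)
})

test_that("a fully detected community yields near-certain occupancy", {
  J <- 20
  units <- data.frame(site_id = seq_len(J), season_id = "spring-1", season_fall = 0,
                      enhancement = 0, pesticide_high = 0)
  y <- array(1, c(3, J, 3))
  d <- detection_dataset(y, paste0("sp", 1:3), units,
                         matrix(rnorm(J * 3, 15, 2), J, 3),
                         matrix(runif(J * 3, 0, 12), J, 3))
  spec <- community_model_spec(occ_covariates = character(0),
                               det_covariates = character(0), site_effect = FALSE)
  fit <- fit_community_model(d, spec, mcmc_config(2, 2000, 1000, 2, seed = 3))
  psi <- plogis(fit$draws[, grep("^phi", colnames(fit$draws))])
  expect_true(all(colMeans(psi) > 0.9))
})

test_that("with no units the sampler reproduces the prior", {
  units0 <- data.frame(site_id = integer(0), season_id = character(0),
                       season_fall = integer(0), enhancement = integer(0),
                       pesticide_high = integer(0))
  d0 <- detection_dataset(array(numeric(0), c(3, 0, 3)), paste0("s", 1:3), units0,
                          matrix(0, 0, 3), matrix(0, 0, 3))
  spec <- community_model_spec(site_effect = FALSE)
  fit <- fit_community_model(d0, spec, mcmc_config(2, 20000, 5000, 10, seed = 9))
  for (pp in c("mu_phi", "mu_beta_season", "mu_beta_enhancement")) {
    x <- fit$draws[, pp]
    expect_lt(abs(mean(x)), 6)                  # prior mean 0, sd sqrt(1000)
    expect_gt(stats::sd(x), 22)
    expect_lt(stats::sd(x), 44)
  }
  s <- fit$draws[, "sigma_beta_time"]           # Uniform(0, 50)
  expect_gt(mean(s), 17)
  expect_lt(mean(s), 33)
  expect_gt(max(s), 42)
  expect_lt(min(s), 8)
})

test_that("permuting unit order leaves the posterior unchanged within MC error", {
  d <- make_tiny_dataset(n_species = 3, n_sites = 4, n_seasons = 2, seed = 21,
                         p_detect = 0.45)
  perm <- c(5, 2, 7, 1, 8, 4, 3, 6)
  d2 <- d
  d2$y <- d$y[, perm, , drop = FALSE]
  d2$units <- d$units[perm, ]
  d2$units$site_index <- as.integer(factor(d2$units$site_id,
                                           levels = unique(d2$units$site_id)))
  d2$air <- d$air[perm, , drop = FALSE]
  d2$time <- d$time[perm, , drop = FALSE]
  d2$obs <- d$obs[perm, , drop = FALSE]
  cfg <- mcmc_config(3, 4000, 2000, 2, seed = 5)
  f1 <- fit_community_model(d, mcmc = cfg)
  f2 <- fit_community_model(d2, mcmc = cfg)
  for (pp in c("mu_phi", "mu_eta", "mu_beta_time")) {
    m1 <- mean(f1$draws[, pp]); m2 <- mean(f2$draws[, pp])
    mcse <- stats::sd(f1$draws[, pp]) *
      max(mcmc_error_ratio(f1$draws[, pp]), mcmc_error_ratio(f2$draws[, pp]))
    expect_lt(abs(m1 - m2), 6 * mcse + 0.05)
  }
})
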