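test_that("R-hat matches the within/between variance formula and conventions", {
  # explicit textbook oracle, written out independently
  psrf_oracle <- function(chains) {
    n <- nrow(chains)
    W <- mean(apply(chains, 2, var))
    B_over_n <- var(colMeans(chains))
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }
  set.seed(1)
  ch <- cbind(rnorm(400), rnorm(400), rnorm(400))
  expect_equal(rhat(ch, split = FALSE), psrf_oracle(ch), tolerance = 1e-12)

  expect_equal(rhat(cbind(rep(3, 50), rep(3, 50))), 1)      # zero total variance
  expect_gt(rhat(cbind(rep(0, 50), rep(10, 50))), 1.06)     # disjoint constants
  set.seed(2)
  expect_lt(rhat(cbind(rnorm(2000), rnorm(2000))), 1.05)    # same distribution
  expect_error(rhat(matrix(rnorm(10), ncol = 1), split = FALSE), "two chains")
  expect_error(rhat(list(1:5, 1:4)), "equal length")
  # concatenating two chains then splitting equals the unsplit two-chain value
  a <- rnorm(500); b <- rnorm(500, 0.3)
  expect_equal(rhat(matrix(c(a, b), ncol = 1), split = TRUE),
               rhat(cbind(a, b), split = FALSE), tolerance = 1e-9)
})

test_that("Monte Carlo error ratio matches i.i.d. and AR(1) theory", {
  set.seed(3)
  x <- rnorm(10000)
  expect_lt(abs(mcmc_error_ratio(x) / (1 / sqrt(10000)) - 1), 0.5)
  expect_true(is.na(mcmc_error_ratio(rep(2, 500))))
  expect_error(mcmc_error_ratio(rnorm(50)), "100 draws")
  # AR(1) with rho = 0.6: ESS deflation (1-rho)/(1+rho), so the ratio is
  # sqrt((1+rho)/(1-rho)) / sqrt(n)
  rho <- 0.6; n <- 40000
  ar <- as.numeric(stats::filter(rnorm(n), rho, method = "recursive"))
  expect_lt(abs(mcmc_error_ratio(ar) / (sqrt((1 + rho) / (1 - rho)) / sqrt(n)) - 1), 0.5)
})

test_that("Mann-Whitney AUC handles ties, separation and transforms", {
  expect_equal(auc_mann_whitney(rep(0.7, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc_mann_whitney(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_true(is.na(auc_mann_whitney(runif(5), rep(1, 5))))
  set.seed(4)
  s <- runif(200); y <- rbinom(200, 1, s)
  a1 <- auc_mann_whitney(s, y)
  expect_equal(auc_mann_whitney(qlogis(s), y), a1, tolerance = 1e-12)  # monotone map
  skip_if_not_installed("pROC")
  a2 <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("posterior AUC is exact on rigged posteriors", {
  d <- make_tiny_dataset(n_species = 2, n_sites = 3, n_seasons = 2, seed = 31)
  # constant scores across all cells -> AUC exactly 0.5 in every draw
  flat <- rigged_posterior(d, phi_value = 0.4, eta_value = -0.3)
  a <- compute_auc(flat)
  expect_true(all(a$draws == 0.5))
  expect_equal(a$mean, 0.5)
  # degenerate outcomes -> undefined
  d1 <- d; d1$y[] <- 1
  sat <- rigged_posterior(d1, phi_value = 5, eta_value = 5)
  expect_true(is.na(compute_auc(sat)$mean))
})

test_that("posterior predictive p-value is 0.5 under forced ties and small under misfit", {
  units <- data.frame(site_id = 1:6, season_id = "spring-1", season_fall = 0,
                      enhancement = rep(0:1, 3), pesticide_high = rep(c(1, 0), 3))
  y1 <- array(1, c(2, 6, 3))
  d1 <- detection_dataset(y1, c("a", "b"), units, matrix(15, 6, 3), matrix(6, 6, 3))
  # psi and p pinned at ~1: every replicate equals the all-ones observation
  tied <- rigged_posterior(d1, phi_value = 60, eta_value = 60)
  ppc <- posterior_predictive_check(tied)
  expect_equal(ppc$p_rows, 0.5)
  expect_equal(ppc$p_cols, 0.5)
  # all-ones data under a sparse model is gross misfit
  sparse <- rigged_posterior(d1, phi_value = -2, eta_value = -2)
  set.seed(8)
  ppc2 <- posterior_predictive_check(sparse)
  expect_lt(ppc2$p_rows, 0.05)
  expect_lt(ppc2$p_cols, 0.05)
})

test_that("effect summaries flag sign-consistent intervals", {
  set.seed(9)
  m <- cbind(sym = rnorm(4000), pos = rexp(4000) + 0.01, norm = rnorm(4000))
  s <- summarize_effects(m, level = 0.95)
  expect_false(s$excludes_zero[s$parameter == "sym"])
  expect_true(s$excludes_zero[s$parameter == "pos"])
  expect_equal(s$lower[s$parameter == "norm"], qnorm(0.025), tolerance = 0.12)
  expect_equal(s$upper[s$parameter == "norm"], qnorm(0.975), tolerance = 0.12)
  s90 <- summarize_effects(m, level = 0.90, parameters = "sym")
  expect_equal(nrow(s90), 1)
  expect_error(summarize_effects(m, level = 1.2), "level")
})
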