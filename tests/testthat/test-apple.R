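quick_mcmc <- function(seed = 1) mcmc_config(2, 3000, 1000, 2, seed = seed)

test_that("apple GLMM validates input and returns the expected draw layout", {
  g <- generate_apple_dataset(apple_truth(), seed = 1)
  expect_error(fit_apple_glmm(g$records[, -1], "weight"), "orchard_id")
  one <- g$records[g$records$orchard_id == 1, ]
  expect_error(fit_apple_glmm(one, "weight"), "two orchards")
  bad <- g$records; bad$seeds[1] <- 2.5
  expect_error(fit_apple_glmm(bad, "seeds"), "integers")
  fit <- fit_apple_glmm(g$records, "sugar", mcmc = mcmc_config(2, 400, 200, 2, seed = 2))
  expect_s3_class(fit, "apple_model_fit")
  expect_equal(fit$family, "gaussian")
  expect_equal(nrow(fit$draws), 2 * 100)
  expect_true(all(c("intercept", "beta_enhancement", "beta_pesticide",
                    "sigma_orchard", "sigma_resid") %in% colnames(fit$draws)))
  pois <- fit_apple_glmm(g$records, "seeds", mcmc = mcmc_config(2, 400, 200, 2, seed = 2))
  expect_equal(pois$family, "poisson")
  expect_false("sigma_resid" %in% colnames(pois$draws))
  expect_true(all(fit$draws[, "sigma_orchard"] < 100))
})

test_that("a constant response centres both covariate effects on zero", {
  g <- generate_apple_dataset(apple_truth(), seed = 5)
  rec <- g$records
  rec$sugar <- 13
  fit <- fit_apple_glmm(rec, "sugar", mcmc = quick_mcmc(3))
  s <- summarize_effects(fit, parameters = "^beta_")
  expect_false(any(s$excludes_zero))
  expect_lt(max(abs(s$mean)), 0.5)
})

test_that("normal-model effects are translation-equivariant up to MC error", {
  tr <- apple_truth(responses = list(
    sugar = list(family = "gaussian", intercept = 13, beta_enhancement = 0.8,
                 beta_pesticide = -0.5, sigma_orchard = 0.4, sigma_resid = 1.2)))
  rec <- generate_apple_dataset(tr, seed = 7)$records
  f1 <- fit_apple_glmm(rec, "sugar", mcmc = quick_mcmc(4))
  rec2 <- rec; rec2$sugar <- rec2$sugar + 100
  f2 <- fit_apple_glmm(rec2, "sugar", mcmc = quick_mcmc(4))
  expect_equal(mean(f2$draws[, "intercept"]) - mean(f1$draws[, "intercept"]), 100,
               tolerance = 0.02)
  for (b in c("beta_enhancement", "beta_pesticide"))
    expect_lt(abs(mean(f2$draws[, b]) - mean(f1$draws[, b])), 0.15)
})

test_that("with no orchard variation the fixed effects match OLS", {
  tr <- apple_truth(n_orchards = 20, apples_per_orchard = 30, responses = list(
    weight = list(family = "gaussian", intercept = 150, beta_enhancement = 8,
                  beta_pesticide = 25, sigma_orchard = 1e-8, sigma_resid = 30)))
  rec <- generate_apple_dataset(tr, seed = 11)$records
  fit <- fit_apple_glmm(rec, "weight", mcmc = quick_mcmc(5))
  ols <- coef(lm(weight ~ enhancement + pesticide_high, data = rec))
  for (k in 1:3) {
    dr <- fit$draws[, k]
    mcse <- sd(dr) * mcmc_error_ratio(dr)
    # 3 MC standard errors plus the small shrinkage the free random
    # intercept adds relative to plain OLS
    expect_lt(abs(mean(dr) - ols[k]), 3 * mcse + 0.02 * sd(rec$weight))
  }
})

test_that("Poisson rate ratios recover a simulated enhancement effect", {
  tr <- apple_truth(n_orchards = 20, apples_per_orchard = 30, responses = list(
    seeds = list(family = "poisson", intercept = log(8), beta_enhancement = -0.20,
                 beta_pesticide = 0, sigma_orchard = 0.15)))
  rec <- generate_apple_dataset(tr, seed = 21)$records
  fit <- fit_apple_glmm(rec, "seeds", mcmc = quick_mcmc(6))
  b <- fit$draws[, "beta_enhancement"]
  expect_lt(abs(mean(b) - (-0.20)), 0.15)
  expect_equal(mean(exp(b)), exp(-0.2), tolerance = 0.15)
  ci <- quantile(b, c(0.025, 0.975))
  expect_true(ci[1] <= -0.2 + 0.15)  # interval in the right region
})

test_that("fit checks compute Pearson residuals and tie-convention p-values", {
  g <- generate_apple_dataset(apple_truth(), seed = 9)
  fit <- fit_apple_glmm(g$records, "seeds", mcmc = mcmc_config(2, 600, 200, 2, seed = 2))
  chk <- apple_fit_check(fit, ndraws = 100)
  expect_true(chk$p_value >= 0 && chk$p_value <= 1)
  # residual formula at posterior means: (y - mu) / sqrt(mu)
  pm <- colMeans(fit$draws)
  mu_hat <- exp(as.vector(fit$X %*% pm[1:3]) + pm[3 + fit$orch])
  expect_equal(chk$residuals, (fit$y - mu_hat) / sqrt(mu_hat), tolerance = 1e-12)
  # Poisson residual arithmetic: observed 10 at fitted mean 4 gives 3
  expect_equal((10 - 4) / sqrt(4), 3)

  # forced ties: all-zero counts under a rate pinned near zero replicate exactly
  rec0 <- g$records
  rec0$seeds <- 0
  f0 <- fit_apple_glmm(rec0, "seeds", mcmc = mcmc_config(2, 100, 50, 2, seed = 3))
  f0$draws[, "intercept"] <- -40
  f0$draws[, c("beta_enhancement", "beta_pesticide")] <- 0
  f0$draws[, grep("^u\\[", colnames(f0$draws))] <- 0
  chk0 <- apple_fit_check(f0, ndraws = 50)
  expect_equal(chk0$p_value, 0.5)
})

test_that("a year column is ignored by the model", {
  g <- generate_apple_dataset(apple_truth(), seed = 15)
  f1 <- fit_apple_glmm(g$records, "diameter", mcmc = mcmc_config(2, 400, 200, 2, seed = 4))
  rec2 <- g$records; rec2$year <- rec2$year + 1
  f2 <- fit_apple_glmm(rec2, "diameter", mcmc = mcmc_config(2, 400, 200, 2, seed = 4))
  expect_identical(f1$draws, f2$draws)
})
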