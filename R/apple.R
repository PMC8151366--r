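## Bayesian GLMMs for apple quality: weight, diameter and sugar are modelled
## as normal with identity link, seed count as Poisson with log link, each
## with fixed effects of landscape enhancement and high pesticide intensity
## and a random orchard intercept. Same sampler machinery as the community
## model: adaptive random-walk Metropolis, with variance parameters updated
## on the sd scale so the Uniform(0, 100) priors apply directly.

.apple_family <- c(weight = "gaussian", diameter = "gaussian",
                   sugar = "gaussian", seeds = "poisson")

.run_apple_chain <- function(y, X, orch, family, mcmc, prior, chain_seed, n_keep) {
  set.seed(chain_seed)
  nrec <- length(y); P <- ncol(X); Norch <- max(orch)
  target <- mcmc$target_accept
  gaussian <- family == "gaussian"

  b <- numeric(P)
  b[1] <- if (gaussian) mean(y) else log(mean(y) + 0.1)
  u <- numeric(Norch)
  sig_orch <- 1
  sig_res <- if (gaussian) max(stats::sd(y), 1e-3) else NA_real_

  mu <- as.vector(X %*% b) + u[orch]
  ll_vec <- function(mu, sr) if (gaussian) stats::dnorm(y, mu, sr, log = TRUE)
                             else stats::dpois(y, exp(mu), log = TRUE)
  lv <- ll_vec(mu, sig_res)
  ll <- sum(lv)

  ls_b <- rep(log(0.5), P); ls_u <- rep(log(0.5), Norch); ls_s <- rep(log(0.3), 2)
  ls_g <- rep(log(0.5), P)
  X_orch <- X[match(seq_len(Norch), orch), , drop = FALSE]  # site-level covariates
  draws <- matrix(NA_real_, n_keep, P + Norch + 1L + (gaussian))
  acc_sum <- 0; acc_n <- 0
  keep <- 0L

  for (iter in seq_len(mcmc$iterations)) {
    adapting <- iter <= mcmc$burn_in
    gam <- min(0.3, 3 / sqrt(iter))

    ## fixed effects, component-wise
    for (cc in seq_len(P)) {
      prop <- b[cc] + exp(ls_b[cc]) * stats::rnorm(1)
      mu_p <- mu + (prop - b[cc]) * X[, cc]
      llp <- sum(ll_vec(mu_p, sig_res))
      logr <- (llp - ll) +
        stats::dnorm(prop, 0, sqrt(prior$v_beta), log = TRUE) -
        stats::dnorm(b[cc], 0, sqrt(prior$v_beta), log = TRUE)
      acc <- log(stats::runif(1)) < logr
      if (acc) { b[cc] <- prop; mu <- mu_p; ll <- llp }
      if (adapting) ls_b[cc] <- min(max(ls_b[cc] + gam * (acc - target), -8), 6)
      else { acc_sum <- acc_sum + acc; acc_n <- acc_n + 1 }
    }

    ## orchard effects, all orchards at once (independent given the rest)
    prop <- u + exp(ls_u) * stats::rnorm(Norch)
    mu_p <- mu + (prop - u)[orch]
    lv_p <- ll_vec(mu_p, sig_res)
    ll_cur_o <- rowsum(ll_vec(mu, sig_res), orch)[, 1]
    ll_prop_o <- rowsum(lv_p, orch)[, 1]
    logr <- (ll_prop_o - ll_cur_o) +
      stats::dnorm(prop, 0, sig_orch, log = TRUE) -
      stats::dnorm(u, 0, sig_orch, log = TRUE)
    acc <- log(stats::runif(Norch)) < logr
    if (any(acc)) {
      u[acc] <- prop[acc]
      sel <- acc[orch]
      mu[sel] <- mu_p[sel]
      ll <- sum(ll_vec(mu, sig_res))
    }
    if (adapting) ls_u <- pmin(pmax(ls_u + gam * (acc - target), -8), 6)
    else { acc_sum <- acc_sum + sum(acc); acc_n <- acc_n + Norch }

    ## translation along the unidentified fixed-effect / orchard-effect
    ## direction: the covariates are orchard-level, so shifting a fixed
    ## effect and compensating through the orchard intercepts leaves the
    ## likelihood untouched and only the priors arbitrate
    for (cc in seq_len(P)) {
      eps <- exp(ls_g[cc]) * stats::rnorm(1)
      u_p <- u - eps * X_orch[, cc]
      logr <- -0.5 * ((b[cc] + eps)^2 - b[cc]^2) / prior$v_beta -
        0.5 * (sum(u_p^2) - sum(u^2)) / sig_orch^2
      acc <- log(stats::runif(1)) < logr
      if (acc) { b[cc] <- b[cc] + eps; u <- u_p }
      if (adapting) ls_g[cc] <- min(max(ls_g[cc] + gam * (acc - target), -8), 6)
    }

    ## orchard sd
    prop <- sig_orch + exp(ls_s[1]) * stats::rnorm(1)
    acc <- FALSE
    if (prop > 0 && prop < prior$sd_upper) {
      logr <- sum(stats::dnorm(u, 0, prop, log = TRUE)) -
        sum(stats::dnorm(u, 0, sig_orch, log = TRUE))
      acc <- log(stats::runif(1)) < logr
      if (acc) sig_orch <- prop
    }
    if (adapting) ls_s[1] <- min(max(ls_s[1] + gam * (acc - target), -8), 6)

    ## residual sd (normal models)
    if (gaussian) {
      prop <- sig_res + exp(ls_s[2]) * stats::rnorm(1)
      acc <- FALSE
      if (prop > 0 && prop < prior$sd_upper) {
        llp <- sum(ll_vec(mu, prop))
        acc <- log(stats::runif(1)) < (llp - ll)
        if (acc) { sig_res <- prop; ll <- llp }
      }
      if (adapting) ls_s[2] <- min(max(ls_s[2] + gam * (acc - target), -8), 6)
    }

    if (iter > mcmc$burn_in && (iter - mcmc$burn_in) %% mcmc$thin == 0L) {
      keep <- keep + 1L
      draws[keep, ] <- c(b, u, sig_orch, if (gaussian) sig_res)
    }
  }
  list(draws = draws[seq_len(keep), , drop = FALSE],
       accept = if (acc_n > 0) acc_sum / acc_n else NA_real_)
}

#' Fit a Bayesian GLMM for one apple-quality response
#'
#' Weight (g), diameter (mm) and sugar (degrees Brix) are fitted with a
#' normal distribution and identity link; seed count with a Poisson
#' distribution and log link. Fixed effects are landscape enhancement and
#' high pesticide intensity; orchard identity enters as a random intercept.
#' Priors: `N(0, v_beta)` (variance scale) on the fixed effects and
#' `Uniform(0, 100)` on both standard deviations. Year is deliberately not a
#' model term; a `year` column, if present, is ignored.
#'
#' @param records Data frame with columns `orchard_id`, `enhancement` (0/1),
#'   `pesticide_high` (0/1) and the response column (`weight`, `diameter`,
#'   `sugar` or `seeds`).
#' @param response One of `"weight"`, `"diameter"`, `"sugar"`, `"seeds"`.
#' @param mcmc An [mcmc_config()]. The publication-scale configuration is
#'   `mcmc_config(5, 250000, 125000, 10)`; the default is desk scale.
#' @param v_beta Prior variance for fixed effects.
#' @param sd_upper Upper bound of the uniform priors on standard deviations.
#' @return Object of class `apple_model_fit` with a draws matrix (columns
#'   `intercept`, `beta_enhancement`, `beta_pesticide`, `u[...]`,
#'   `sigma_orchard` and, for normal models, `sigma_resid`).
#' @export
fit_apple_glmm <- function(records, response = c("weight", "diameter", "sugar", "seeds"),
                           mcmc = mcmc_config(), v_beta = 1000, sd_upper = 100) {
  response <- match.arg(response)
  for (col in c("orchard_id", "enhancement", "pesticide_high", response))
    if (is.null(records[[col]])) stop_input("records lack column '", col, "'")
  y <- records[[response]]
  if (anyNA(y)) stop_input("response '", response, "' has missing values")
  family <- .apple_family[[response]]
  if (family == "poisson" && any(y < 0 | y != round(y)))
    stop_input("seed counts must be non-negative integers")
  orch <- as.integer(factor(records$orchard_id, levels = unique(records$orchard_id)))
  if (max(orch) < 2L)
    stop_input("at least two orchards are required to identify the random effect")
  X <- cbind(1, records$enhancement, records$pesticide_high)
  prior <- list(v_beta = v_beta, sd_upper = sd_upper)
  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  seeds <- derive_seeds(mcmc$seed, mcmc$chains, salt = 7L)
  chains <- lapply(seq_len(mcmc$chains), function(ch)
    .run_apple_chain(y, X, orch, family, mcmc, prior, seeds[ch], n_keep))
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  orch_ids <- unique(records$orchard_id)
  colnames(draws) <- c("intercept", "beta_enhancement", "beta_pesticide",
                       paste0("u[", orch_ids, "]"), "sigma_orchard",
                       if (family == "gaussian") "sigma_resid")
  structure(list(
    draws = draws,
    chain = rep(seq_len(mcmc$chains), vapply(chains, function(x) nrow(x$draws), 0L)),
    response = response, family = family,
    y = y, X = X, orch = orch, orchard_ids = orch_ids,
    mcmc = mcmc, seeds = seeds,
    accept = mean(vapply(chains, `[[`, 0, "accept"), na.rm = TRUE)
  ), class = "apple_model_fit")
}

#' @export
print.apple_model_fit <- function(x, ...) {
  cat(sprintf("<apple_model_fit> response '%s' (%s), %d draws (%d chains), %d orchards\n",
              x$response, x$family, nrow(x$draws), x$mcmc$chains, length(x$orchard_ids)))
  print(summarize_effects(x, parameters = "^(intercept|beta_)"), ...)
  invisible(x)
}

#' Posterior predictive fit check and Pearson residuals for an apple GLMM
#'
#' For each retained draw a replicate response vector is simulated and the
#' Pearson chi-square discrepancy (residuals standardized by the residual sd
#' draw for normal models, by `sqrt(mu)` for the Poisson model) of replicate
#' and observed data are compared; the Bayesian p-value counts exact ties as
#' one half. Per-record Pearson residuals are evaluated at posterior means.
#'
#' @param fit An [fit_apple_glmm()] result.
#' @param ndraws Number of retained draws to use (default all).
#' @return List with `p_value`, per-draw discrepancies, and `residuals`.
#' @export
apple_fit_check <- function(fit, ndraws = NULL) {
  dr <- fit$draws
  total <- nrow(dr)
  use <- if (is.null(ndraws) || ndraws >= total) seq_len(total)
         else unique(round(seq(1, total, length.out = ndraws)))
  y <- fit$y; X <- fit$X; orch <- fit$orch
  nO <- length(fit$orchard_ids)
  gaussian <- fit$family == "gaussian"
  out <- matrix(NA_real_, length(use), 2, dimnames = list(NULL, c("obs", "rep")))
  for (t in seq_along(use)) {
    d <- dr[use[t], ]
    mu <- as.vector(X %*% d[1:3]) + d[3 + orch]
    if (gaussian) {
      sr <- d[["sigma_resid"]]
      yrep <- stats::rnorm(length(y), mu, sr)
      out[t, ] <- c(sum(((y - mu) / sr)^2), sum(((yrep - mu) / sr)^2))
    } else {
      lam <- exp(mu)
      yrep <- stats::rpois(length(y), lam)
      out[t, ] <- c(sum((y - lam)^2 / lam), sum((yrep - lam)^2 / lam))
    }
  }
  pm <- colMeans(dr)
  mu_hat <- as.vector(X %*% pm[1:3]) + pm[3 + orch]
  resid <- if (gaussian) (y - mu_hat) / pm[["sigma_resid"]]
           else (y - exp(mu_hat)) / sqrt(exp(mu_hat))
  list(p_value = mean((out[, "rep"] > out[, "obs"]) + 0.5 * (out[, "rep"] == out[, "obs"])),
       draws = as.data.frame(out),
       residuals = resid)
}
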