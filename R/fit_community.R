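## Metropolis-within-Gibbs sampler for the hierarchical community occupancy
## model. Latent occupancy states are updated by Gibbs; species-level
## coefficients, site effects and hyper-sds by component-wise adaptive
## random-walk Metropolis (Robbins-Monro adaptation during burn-in only);
## community means by their conjugate normal full conditionals.
##
## Species are conditionally independent given the hyperparameters and site
## effects, and sites given everything else, so proposals are made in
## vectorized blocks (all species / all sites at once) with element-wise
## accept/reject; this keeps the sampler exact while avoiding per-component
## R-level loops.

.occ_cov_column <- c(season = "season_fall", enhancement = "enhancement",
                     pesticide = "pesticide_high")

# Design matrices and index structures shared by all chains.
.community_design <- function(data, spec) {
  y <- data$y
  n <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  obs_idx <- which(as.vector(data$obs))            # column-major over J x K
  M <- length(obs_idx)
  unit_of_obs <- ((obs_idx - 1L) %% J) + 1L
  ymat <- matrix(y, n, J * K)
  Y <- ymat[, obs_idx, drop = FALSE]
  Xocc <- cbind(intercept = rep(1, J))
  for (cv in spec$occ_covariates)
    Xocc <- cbind(Xocc, data$units[[.occ_cov_column[[cv]]]])
  colnames(Xocc) <- c("intercept", spec$occ_covariates)
  Wdet <- cbind(intercept = rep(1, M))
  if ("air" %in% spec$det_covariates) Wdet <- cbind(Wdet, as.vector(data$air)[obs_idx])
  if ("time" %in% spec$det_covariates) Wdet <- cbind(Wdet, as.vector(data$time)[obs_idx])
  colnames(Wdet) <- c("intercept", spec$det_covariates)
  det_any <- matrix(FALSE, n, J)
  if (J > 0) det_any <- apply(y == 1, c(1, 2), any, na.rm = TRUE)
  U <- matrix(0, M, J)
  if (M > 0) U[cbind(seq_len(M), unit_of_obs)] <- 1
  site_index <- data$units$site_index
  S <- if (spec$site_effect && J > 0) max(site_index) else 0L
  Msite <- matrix(0, J, S)
  if (S > 0) Msite[cbind(seq_len(J), site_index)] <- 1
  list(n = n, J = J, K = K, M = M, Y = Y, Xocc = Xocc, Wdet = Wdet,
       det_any = det_any, U = U, unit_of_obs = unit_of_obs,
       site_index = site_index, S = S, Msite = Msite)
}

# Parameter vector layout and names.
.community_par_names <- function(ds, spec, species) {
  occ_lab <- c("phi", if (length(spec$occ_covariates))
    paste0("beta_", spec$occ_covariates))
  det_lab <- c("eta", if (length(spec$det_covariates))
    paste0("beta_", spec$det_covariates))
  nm <- c(
    unlist(lapply(occ_lab, function(l) paste0(l, "[", species, "]"))),
    unlist(lapply(det_lab, function(l) paste0(l, "[", species, "]"))),
    if (ds$S > 0) paste0("alpha[", seq_len(ds$S), "]"),
    paste0("mu_", occ_lab), paste0("sigma_", occ_lab),
    paste0("mu_", det_lab), paste0("sigma_", det_lab),
    if (ds$S > 0) "sigma_site"
  )
  list(names = nm, occ_lab = occ_lab, det_lab = det_lab)
}

.bern_ll <- function(z, lp) z * lp - log1pexp(lp)

.run_community_chain <- function(ds, spec, mcmc, chain_seed, n_keep) {
  set.seed(chain_seed)
  n <- ds$n; J <- ds$J; M <- ds$M; S <- ds$S
  Pocc <- ncol(ds$Xocc); Pdet <- ncol(ds$Wdet)
  v_beta <- spec$v_beta
  sd_up_occ <- rep(spec$sd_upper, Pocc)
  sd_up_det <- rep(spec$sd_upper, Pdet)
  target <- mcmc$target_accept
  det_any <- ds$det_any

  ## initialization: intercepts at naive logit rates (jittered), slopes at 0,
  ## sds at 1
  naive_occ <- if (J > 0) rowMeans(det_any) else rep(0.5, n)
  naive_det <- if (M > 0) rowMeans(ds$Y) else rep(0.3, n)
  C <- matrix(0, n, Pocc)
  C[, 1] <- logit(pmin(pmax(naive_occ, 0.1), 0.9)) + stats::rnorm(n, 0, 0.3)
  D <- matrix(0, n, Pdet)
  D[, 1] <- logit(pmin(pmax(naive_det, 0.05), 0.9)) + stats::rnorm(n, 0, 0.3)
  alpha <- numeric(S)
  mu_occ <- c(mean(C[, 1]), numeric(Pocc - 1))
  sig_occ <- rep(1, Pocc)
  mu_det <- c(mean(D[, 1]), numeric(Pdet - 1))
  sig_det <- rep(1, Pdet)
  sig_site <- 1

  ## caches: Lpsi/Lp linear predictors; per-(species, unit) detection-history
  ## log-likelihood sums D1 (used when the species was detected there) and
  ## all-miss sums S1 (used in the z-marginalized empty-history term); Tmat
  ## holds the per-cell marginal log-likelihood terms.
  Lpsi <- C %*% t(ds$Xocc)
  if (S > 0) Lpsi <- Lpsi + matrix(alpha[ds$site_index], n, J, byrow = TRUE)
  Lp <- D %*% t(ds$Wdet)
  # per-unit sums over visits: cheap slice-adds when every unit has the full
  # visit complement, matrix product with the indicator otherwise
  uniformK <- (M == J * ds$K) && J > 0
  sumU <- if (uniformK) function(Amat) {
    out <- Amat[, seq_len(J), drop = FALSE]
    for (k in seq_len(ds$K - 1))
      out <- out + Amat[, k * J + seq_len(J), drop = FALSE]
    out
  } else function(Amat) Amat %*% ds$U
  A <- .bern_ll(ds$Y, Lp)
  D1 <- sumU(A)
  S1 <- sumU(-log1pexp(Lp))
  det_idx <- which(det_any)
  cellT <- function(Lpsi, D1, S1) {
    lse <- log1pexp(Lpsi)
    a <- Lpsi - lse + S1                    # log(psi * prod(1-p))
    b <- -lse                               # log(1 - psi)
    Tm <- pmax(a, b) + log1p(exp(-abs(a - b)))  # log(psi*prod(1-p) + 1-psi)
    Tm[det_idx] <- Lpsi[det_idx] - lse[det_idx] + D1[det_idx]
    Tm
  }
  Tmat <- cellT(Lpsi, D1, S1)
  ll <- rowSums(Tmat)
  if (!all(is.finite(ll)))
    stop("non-finite log-likelihood at initialization")

  ## adaptive step sizes (log scale)
  ls_occ <- matrix(log(0.5), n, Pocc)
  ls_det <- matrix(log(0.5), n, Pdet)
  ls_alpha <- rep(log(0.5), S)
  ls_sig <- rep(log(0.3), Pocc + Pdet + (S > 0))  # occ sds, det sds, site sd
  ls_gshift <- rep(log(0.3), Pocc + Pdet)         # group translation moves
  ls_gscale <- rep(log(0.3), Pocc + Pdet + 1L)    # group scale moves (+ site)

  pn <- .community_par_names(ds, spec, seq_len(n))
  npar <- length(pn$names)
  draws <- matrix(NA_real_, n_keep, npar)
  zdraws <- array(NA_integer_, c(n_keep, n, J))
  acc_sum <- c(occ = 0, alpha = 0, det = 0, sig = 0, grp = 0)
  acc_n <- c(occ = 0, alpha = 0, det = 0, sig = 0, grp = 0)

  ## hyperparameter updates (defined once; read the loop's current
  ## `adapting`/`gam` at call time)
  adapting <- TRUE; gam <- 0; sig_i <- 0L
  upd_sig <- function(values, mu, sig, upper) {
    sig_i <<- sig_i + 1L
    prop <- sig + exp(ls_sig[sig_i]) * stats::rnorm(1)
    acc <- FALSE
    if (prop > 0 && prop < upper) {
      ss <- sum((values - mu)^2)
      logr <- -length(values) * (log(prop) - log(sig)) -
        0.5 * ss * (1 / prop^2 - 1 / sig^2)
      acc <- log(stats::runif(1)) < logr
      if (acc) sig <- prop
    }
    if (adapting) ls_sig[sig_i] <<- min(max(ls_sig[sig_i] + gam * (acc - target), -8), 5)
    else { acc_sum["sig"] <<- acc_sum["sig"] + acc; acc_n["sig"] <<- acc_n["sig"] + 1 }
    sig
  }
  upd_mu <- function(values, sig) {
    prec <- length(values) / sig^2 + 1 / v_beta
    stats::rnorm(1, sum(values) / sig^2 / prec, sqrt(1 / prec))
  }

  keep <- 0L
  for (iter in seq_len(mcmc$iterations)) {
    adapting <- iter <= mcmc$burn_in
    gam <- min(0.3, 3 / sqrt(iter))

    ## -- species-level occupancy coefficients, one covariate block at a time
    for (cc in seq_len(Pocc)) {
      step <- exp(ls_occ[, cc])
      prop <- C[, cc] + step * stats::rnorm(n)
      Lpsi_p <- Lpsi + outer(prop - C[, cc], ds$Xocc[, cc])
      Tp <- cellT(Lpsi_p, D1, S1)
      llp <- rowSums(Tp)
      logr <- (llp - ll) -
        0.5 * ((prop - mu_occ[cc])^2 - (C[, cc] - mu_occ[cc])^2) / sig_occ[cc]^2
      acc <- log(stats::runif(n)) < logr
      if (any(acc)) {
        C[acc, cc] <- prop[acc]
        Lpsi[acc, ] <- Lpsi_p[acc, , drop = FALSE]
        Tmat[acc, ] <- Tp[acc, , drop = FALSE]
        ll[acc] <- llp[acc]
      }
      if (adapting) ls_occ[, cc] <- pmin(pmax(ls_occ[, cc] + gam * (acc - target), -8), 4)
      else { acc_sum["occ"] <- acc_sum["occ"] + sum(acc); acc_n["occ"] <- acc_n["occ"] + n }
    }

    ## -- site random effects, all sites at once
    if (S > 0) {
      step <- exp(ls_alpha)
      prop <- alpha + step * stats::rnorm(S)
      dvec <- (prop - alpha)[ds$site_index]
      Lpsi_p <- Lpsi + matrix(dvec, n, J, byrow = TRUE)
      Tp <- cellT(Lpsi_p, D1, S1)
      site_cur <- as.vector(crossprod(ds$Msite, colSums(Tmat)))
      site_prop <- as.vector(crossprod(ds$Msite, colSums(Tp)))
      logr <- (site_prop - site_cur) - 0.5 * (prop^2 - alpha^2) / sig_site^2
      acc <- log(stats::runif(S)) < logr
      if (any(acc)) {
        alpha[acc] <- prop[acc]
        ua <- ds$site_index %in% which(acc)
        Lpsi[, ua] <- Lpsi_p[, ua, drop = FALSE]
        Tmat[, ua] <- Tp[, ua, drop = FALSE]
        ll <- rowSums(Tmat)
      }
      if (adapting) ls_alpha <- pmin(pmax(ls_alpha + gam * (acc - target), -8), 4)
      else { acc_sum["alpha"] <- acc_sum["alpha"] + sum(acc); acc_n["alpha"] <- acc_n["alpha"] + S }
    }

    ## -- species-level detection coefficients (marginal likelihood, so the
    ## detection-history sums D1/S1 are re-derived under each proposal)
    for (cc in seq_len(Pdet)) {
      step <- exp(ls_det[, cc])
      prop <- D[, cc] + step * stats::rnorm(n)
      Lp_p <- Lp + outer(prop - D[, cc], ds$Wdet[, cc])
      A_p <- .bern_ll(ds$Y, Lp_p)
      D1_p <- sumU(A_p)
      S1_p <- sumU(-log1pexp(Lp_p))
      Tp <- cellT(Lpsi, D1_p, S1_p)
      llp <- rowSums(Tp)
      logr <- (llp - ll) -
        0.5 * ((prop - mu_det[cc])^2 - (D[, cc] - mu_det[cc])^2) / sig_det[cc]^2
      acc <- log(stats::runif(n)) < logr
      if (any(acc)) {
        D[acc, cc] <- prop[acc]
        Lp[acc, ] <- Lp_p[acc, , drop = FALSE]
        D1[acc, ] <- D1_p[acc, , drop = FALSE]
        S1[acc, ] <- S1_p[acc, , drop = FALSE]
        Tmat[acc, ] <- Tp[acc, , drop = FALSE]
        ll[acc] <- llp[acc]
      }
      if (adapting) ls_det[, cc] <- pmin(pmax(ls_det[, cc] + gam * (acc - target), -8), 4)
      else { acc_sum["det"] <- acc_sum["det"] + sum(acc); acc_n["det"] <- acc_n["det"] + n }
    }

    ## -- group moves traversing the hierarchical funnel: a joint shift of a
    ## community mean with all its species effects, and a joint rescaling of
    ## a community sd with its centred species effects (exact MH; for the
    ## scale map the prior ratio -n*eps and Jacobian (n+1)*eps net to +eps)
    for (cc in seq_len(Pocc)[-1]) {
      gi <- cc
      eps <- exp(ls_gshift[gi]) * stats::rnorm(1)
      Lpsi_p <- Lpsi + matrix(eps * ds$Xocc[, cc], n, J, byrow = TRUE)
      Tp <- cellT(Lpsi_p, D1, S1)
      llp <- rowSums(Tp)
      logr <- sum(llp - ll) -
        0.5 * ((mu_occ[cc] + eps)^2 - mu_occ[cc]^2) / v_beta
      acc <- log(stats::runif(1)) < logr
      if (acc) {
        C[, cc] <- C[, cc] + eps; mu_occ[cc] <- mu_occ[cc] + eps
        Lpsi <- Lpsi_p; Tmat <- Tp; ll <- llp
      }
      if (adapting) ls_gshift[gi] <- min(max(ls_gshift[gi] + gam * (acc - target), -8), 4)
      else { acc_sum["grp"] <- acc_sum["grp"] + acc; acc_n["grp"] <- acc_n["grp"] + 1 }

      eps <- exp(ls_gscale[gi]) * stats::rnorm(1)
      sig_p <- exp(eps) * sig_occ[cc]
      acc <- FALSE
      if (sig_p < sd_up_occ[cc]) {
        Cp <- mu_occ[cc] + exp(eps) * (C[, cc] - mu_occ[cc])
        Lpsi_p <- Lpsi + outer(Cp - C[, cc], ds$Xocc[, cc])
        Tp <- cellT(Lpsi_p, D1, S1)
        llp <- rowSums(Tp)
        acc <- log(stats::runif(1)) < sum(llp - ll) + eps
        if (acc) {
          C[, cc] <- Cp; sig_occ[cc] <- sig_p
          Lpsi <- Lpsi_p; Tmat <- Tp; ll <- llp
        }
      }
      if (adapting) ls_gscale[gi] <- min(max(ls_gscale[gi] + gam * (acc - target), -8), 4)
      else { acc_sum["grp"] <- acc_sum["grp"] + acc; acc_n["grp"] <- acc_n["grp"] + 1 }
    }
    if (S > 0) {
      gi <- Pocc + Pdet + 1L
      eps <- exp(ls_gscale[gi]) * stats::rnorm(1)
      sig_p <- exp(eps) * sig_site
      acc <- FALSE
      if (sig_p < spec$sd_upper_site) {
        alpha_p <- exp(eps) * alpha
        Lpsi_p <- Lpsi + matrix((alpha_p - alpha)[ds$site_index], n, J, byrow = TRUE)
        Tp <- cellT(Lpsi_p, D1, S1)
        llp <- rowSums(Tp)
        acc <- log(stats::runif(1)) < sum(llp - ll) + eps
        if (acc) {
          alpha <- alpha_p; sig_site <- sig_p
          Lpsi <- Lpsi_p; Tmat <- Tp; ll <- llp
        }
      }
      if (adapting) ls_gscale[gi] <- min(max(ls_gscale[gi] + gam * (acc - target), -8), 4)
      else { acc_sum["grp"] <- acc_sum["grp"] + acc; acc_n["grp"] <- acc_n["grp"] + 1 }
    }

    ## -- hyperparameters
    sig_i <- 0L
    for (cc in seq_len(Pocc)) {
      mu_occ[cc] <- upd_mu(C[, cc], sig_occ[cc])
      sig_occ[cc] <- upd_sig(C[, cc], mu_occ[cc], sig_occ[cc], sd_up_occ[cc])
    }
    for (cc in seq_len(Pdet)) {
      mu_det[cc] <- upd_mu(D[, cc], sig_det[cc])
      sig_det[cc] <- upd_sig(D[, cc], mu_det[cc], sig_det[cc], sd_up_det[cc])
    }
    if (S > 0) sig_site <- upd_sig(alpha, 0, sig_site, spec$sd_upper_site)

    ## -- store, drawing the latent states from their exact conditional
    if (iter > mcmc$burn_in && (iter - mcmc$burn_in) %% mcmc$thin == 0L) {
      keep <- keep + 1L
      draws[keep, ] <- c(as.vector(C), as.vector(D),
                         if (S > 0) alpha,
                         mu_occ, sig_occ, mu_det, sig_det,
                         if (S > 0) sig_site)
      if (J > 0) {
        lse <- log1pexp(Lpsi)
        a <- Lpsi - lse + S1
        m <- pmax(a, -lse)
        condz <- exp(a - (m + log(exp(a - m) + exp(-lse - m))))
        z <- det_any | (stats::runif(n * J) < condz)
        zdraws[keep, , ] <- as.integer(z)
      }
    }
  }
  colnames(draws) <- pn$names
  list(draws = draws[seq_len(keep), , drop = FALSE],
       z = zdraws[seq_len(keep), , , drop = FALSE],
       accept = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_))
}

#' Fit the hierarchical community occupancy model by MCMC
#'
#' Runs several independent chains of a collapsed Metropolis-within-Gibbs
#' sampler: species coefficients, site effects and standard deviations are
#' updated by vectorized component-wise adaptive random-walk Metropolis on
#' the z-marginalized likelihood (the latent presence states are summed out
#' analytically, which removes the near-absorbing high-occupancy region that
#' plagues data-augmented kernels for this model), community means by their
#' conjugate normal full conditionals, and the latent states are drawn from
#' their exact conditional for every retained draw (for richness summaries).
#' Step sizes adapt toward the target acceptance rate during burn-in only,
#' so the retained draws come from a fixed Markov kernel.
#'
#' @param data A [detection_dataset()] with at least one detection.
#' @param spec A [community_model_spec()].
#' @param mcmc An [mcmc_config()]; per-chain seeds derive deterministically
#'   from its master seed.
#' @return Object of class `community_posterior`: retained draws (matrix with
#'   one named column per parameter), per-draw latent states, chain ids,
#'   post-burn-in acceptance rates and provenance (spec, config, seeds).
#' @export
#' @examples
#' sim <- generate_community_dataset(community_truth(n_sites = 4, n_spring = 1,
#'                                                    n_fall = 1), seed = 1)
#' fit <- fit_community_model(sim$data, mcmc = mcmc_config(2, 400, 200, 2, seed = 1))
#' summarize_effects(fit, parameters = "mu_phi")
fit_community_model <- function(data, spec = community_model_spec(),
                                mcmc = mcmc_config()) {
  if (!inherits(data, "detection_dataset")) stop_input("'data' must be a detection_dataset")
  if (!inherits(spec, "community_model_spec")) stop_input("'spec' must be a community_model_spec")
  if (!inherits(mcmc, "mcmc_config")) stop_input("'mcmc' must be an mcmc_config")
  if (dim(data$y)[2] > 0 && sum(data$y, na.rm = TRUE) < 1)
    stop_input("data are degenerate: no detections at all")

  ds <- .community_design(data, spec)
  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  seeds <- derive_seeds(mcmc$seed, mcmc$chains)
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    res <- NULL
    for (attempt in 1:5) {
      res <- tryCatch(.run_community_chain(ds, spec, mcmc, seeds[ch] + attempt - 1, n_keep),
                      error = function(e)
                        if (grepl("initialization", conditionMessage(e))) NULL else stop(e))
      if (!is.null(res)) break
    }
    if (is.null(res)) stop_input("sampler failed to initialize after 5 attempts")
    chains[[ch]] <- res
  }

  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(mcmc$chains), vapply(chains, function(x) nrow(x$draws), 0L))
  zall <- array(NA_integer_, c(nrow(draws), ds$n, ds$J))
  off <- 0L
  for (ch in seq_along(chains)) {
    nk <- nrow(chains[[ch]]$draws)
    if (nk > 0) zall[off + seq_len(nk), , ] <- chains[[ch]]$z
    off <- off + nk
  }
  pn <- .community_par_names(ds, spec, data$species)
  colnames(draws) <- pn$names
  structure(list(
    draws = draws, chain = chain_id, z = zall,
    data = data, spec = spec, mcmc = mcmc, seeds = seeds,
    accept = rowMeans(do.call(cbind, lapply(chains, `[[`, "accept")), na.rm = TRUE),
    design = ds, par_labels = pn
  ), class = "community_posterior")
}

#' @export
print.community_posterior <- function(x, ...) {
  cat(sprintf("<community_posterior> %d draws (%d chains) x %d parameters; %d species, %d units\n",
              nrow(x$draws), x$mcmc$chains, ncol(x$draws),
              dim(x$z)[2], dim(x$z)[3]))
  acc <- paste(sprintf("%s %.2f", names(x$accept), x$accept), collapse = ", ")
  cat("  post-burn-in acceptance:", acc, "\n")
  invisible(x)
}

# Parameter list (as consumed by occupancy_prob()/detection_prob()) for one
# retained draw.
posterior_params <- function(post, d) {
  dr <- post$draws[d, ]
  n <- dim(post$z)[2]
  grab <- function(lab) {
    nm <- paste0(lab, "[", post$data$species, "]")
    if (all(nm %in% names(dr))) unname(dr[nm]) else numeric(n)
  }
  out <- list(phi = grab("phi"), beta_season = grab("beta_season"),
              beta_enhancement = grab("beta_enhancement"),
              beta_pesticide = grab("beta_pesticide"),
              eta = grab("eta"), beta_air = grab("beta_air"),
              beta_time = grab("beta_time"))
  if (post$design$S > 0)
    out$alpha <- unname(dr[paste0("alpha[", seq_len(post$design$S), "]")])
  out
}
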