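## Occupancy / detection probabilities and the z-marginalized likelihood.
## These are the model's elementary quantities; the sampler works with the
## complete-data (z-augmented) form, and marginal_loglik() provides the
## z-marginalized likelihood used for cross-checks against brute-force
## enumeration.

# Coerce a parameter list into per-species vectors of length n, defaulting
# absent components to 0.
.par_vec <- function(params, name, n) {
  v <- params[[name]]
  if (is.null(v)) return(numeric(n))
  if (length(v) == 1L) rep(as.numeric(v), n) else as.numeric(v)
}

# Occupancy linear predictor, species x units.
occ_linpred <- function(params, data) {
  n <- dim(data$y)[1]; J <- dim(data$y)[2]
  u <- data$units
  lp <- outer(.par_vec(params, "phi", n), rep(1, J)) +
    outer(.par_vec(params, "beta_season", n), u$season_fall) +
    outer(.par_vec(params, "beta_enhancement", n), u$enhancement) +
    outer(.par_vec(params, "beta_pesticide", n), u$pesticide_high)
  alpha <- params$alpha
  if (!is.null(alpha)) {
    a <- if (length(alpha) == J) as.numeric(alpha) else as.numeric(alpha)[u$site_index]
    lp <- lp + matrix(a, n, J, byrow = TRUE)
  }
  lp
}

# Detection linear predictor, species x units x visits (NA at missing visits).
det_linpred <- function(params, data) {
  n <- dim(data$y)[1]; J <- dim(data$y)[2]; K <- dim(data$y)[3]
  eta <- .par_vec(params, "eta", n)
  ba <- .par_vec(params, "beta_air", n)
  bt <- .par_vec(params, "beta_time", n)
  lp <- array(NA_real_, c(n, J, K))
  for (i in seq_len(n))
    lp[i, , ] <- eta[i] + ba[i] * data$air + bt[i] * data$time
  lp
}

#' Occupancy probability under the community model
#'
#' Inverse-logit of the occupancy linear predictor. Parameters absent from
#' `params` default to zero, so minimal parameter lists can be evaluated.
#'
#' @param params List with any of `phi`, `beta_season`, `beta_enhancement`,
#'   `beta_pesticide` (scalar or per-species vectors) and `alpha` (per-site,
#'   indexed through `units$site_index`, or per-unit).
#' @param data A [detection_dataset()].
#' @param i,j Optional species / unit indices; if both given, a single
#'   probability is returned, otherwise the full species x unit matrix.
#' @return Probability in (0, 1) (clipped away from exact 0/1 by a machine
#'   epsilon so logs stay finite).
#' @export
occupancy_prob <- function(params, data, i = NULL, j = NULL) {
  psi <- inv_logit(occ_linpred(params, data))
  if (!is.null(i) && !is.null(j)) psi[i, j] else psi
}

#' Detection probability under the community model
#'
#' Inverse-logit of `eta_i + beta_air_i * Air_jk + beta_time_i * Time_jk`,
#' with the standardized visit covariates stored in the dataset.
#'
#' @inheritParams occupancy_prob
#' @param k Optional visit index.
#' @return Single probability when `i`, `j`, `k` are given, else the full
#'   species x unit x visit array (`NA` at visits that did not occur).
#' @export
detection_prob <- function(params, data, i = NULL, j = NULL, k = NULL) {
  p <- inv_logit(det_linpred(params, data))
  p[is.na(data$y)] <- NA
  if (!is.null(i) && !is.null(j) && !is.null(k)) p[i, j, k] else p
}

#' Marginal log-likelihood of a detection dataset
#'
#' The occupancy latent state is summed out analytically per species x unit:
#' a unit with at least one detection contributes `log(psi) + sum_k Bern(y |
#' p)`, a unit with none contributes `log(psi * prod_k (1 - p) + 1 - psi)`.
#'
#' @inheritParams occupancy_prob
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(params, data) {
  y <- data$y
  yv <- y[!is.na(y)]
  if (!all(yv %in% c(0, 1))) stop_input("'y' must be binary")
  n <- dim(y)[1]; J <- dim(y)[2]
  if (J == 0L) return(0)
  lpsi <- occ_linpred(params, data)
  lpd <- det_linpred(params, data)
  logp <- log_invlogit(lpd); log1mp <- log1m_invlogit(lpd)
  ll_det <- apply(ifelse(is.na(y), 0, y * logp + (1 - y) * log1mp), c(1, 2), sum)
  sum1mp <- apply(ifelse(is.na(y), 0, log1mp), c(1, 2), sum)
  det_any <- apply(y == 1, c(1, 2), any, na.rm = TRUE)
  logpsi <- log_invlogit(lpsi); log1mpsi <- log1m_invlogit(lpsi)
  occ_term <- logpsi + ll_det
  # log(psi * prod(1-p) + (1 - psi)) computed stably via log-sum-exp
  m <- pmax(logpsi + sum1mp, log1mpsi)
  empty_term <- m + log(exp(logpsi + sum1mp - m) + exp(log1mpsi - m))
  sum(ifelse(det_any, occ_term, empty_term))
}

#' Gibbs draw of the latent occupancy states
#'
#' Species x unit presence indicators `z` given parameters and data: forced
#' to 1 wherever the species was detected, otherwise Bernoulli with the
#' conditional probability `psi * prod_k(1-p) / (psi * prod_k(1-p) + 1 -
#' psi)`.
#'
#' @inheritParams occupancy_prob
#' @return Binary species x unit matrix.
#' @export
update_latent <- function(params, data) {
  y <- data$y
  n <- dim(y)[1]; J <- dim(y)[2]
  psi <- inv_logit(occ_linpred(params, data))
  lpd <- det_linpred(params, data)
  sum1mp <- apply(ifelse(is.na(y), 0, log1m_invlogit(lpd)), c(1, 2), sum)
  det_any <- apply(y == 1, c(1, 2), any, na.rm = TRUE)
  q <- exp(sum1mp)
  cond <- psi * q / (psi * q + 1 - psi)
  z <- matrix(as.numeric(det_any | (stats::runif(n * J) < cond)), n, J)
  z
}
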