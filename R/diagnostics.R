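#' Split-chain potential scale reduction factor (R-hat)
#'
#' Brooks-Gelman-Rubin convergence statistic. Each chain is split in half
#' (a stricter variant that also detects non-stationarity within chains)
#' before comparing within- to between-chain variance. Values near 1
#' indicate convergence; an informal threshold of 1.06 is often used for
#' occupancy models of this kind.
#'
#' @param chains Matrix (iterations x chains) or list of equal-length numeric
#'   vectors, one per chain, for a single scalar parameter. At least two
#'   chains are required; with `split = TRUE` a single chain is admissible
#'   since its halves form the two sequences.
#' @param split Halve each chain before computing the statistic?
#' @return R-hat (>= 1 up to numerical tolerance); 1 when the total variance
#'   is zero, `Inf` when chains are constant but unequal.
#' @export
#' @examples
#' rhat(cbind(rnorm(1000), rnorm(1000)))
rhat <- function(chains, split = TRUE) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L)
      stop_input("all chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (nrow(chains) < 2L) stop_input("chains must have length >= 2")
  if (split) {
    half <- nrow(chains) %/% 2L
    chains <- cbind(chains[seq_len(half), , drop = FALSE],
                    chains[nrow(chains) - half + seq_len(half), , drop = FALSE])
  }
  if (ncol(chains) < 2L) stop_input("at least two chains are required")
  n <- nrow(chains); m <- ncol(chains)
  if (n < 2L) stop_input("chains too short to split")
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, stats::var))
  B_over_n <- stats::var(means)
  var_hat <- (n - 1) / n * W + B_over_n
  if (var_hat <= .Machine$double.eps) return(1)
  if (W <= .Machine$double.eps) return(Inf)
  sqrt(var_hat / W)
}

#' Monte Carlo error relative to the posterior standard deviation
#'
#' Batch-means Monte Carlo standard error of the posterior mean, divided by
#' the posterior standard deviation. A chain is conventionally "long enough"
#' when this ratio is below 0.02 (MCMC error < 2% of the posterior sd).
#'
#' @param draws Numeric vector of at least 100 draws of one scalar.
#' @return The ratio; `NA` (undefined) when the posterior sd is zero.
#' @export
mcmc_error_ratio <- function(draws) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 100L) stop_input("need at least 100 draws")
  s <- stats::sd(draws)
  if (s <= .Machine$double.eps) return(NA_real_)
  nb <- floor(sqrt(n))
  b <- n %/% nb
  bm <- colMeans(matrix(draws[seq_len(nb * b)], b, nb))
  mcse <- stats::sd(bm) / sqrt(nb)
  mcse / s
}

# Linear predictors (occupancy psi, detection p over observed cells) for one
# retained draw, using the stored design matrices.
.draw_prob <- function(post, d) {
  ds <- post$design
  n <- ds$n
  Pocc <- ncol(ds$Xocc); Pdet <- ncol(ds$Wdet)
  dr <- post$draws[d, ]
  C <- matrix(dr[seq_len(n * Pocc)], n, Pocc)
  D <- matrix(dr[n * Pocc + seq_len(n * Pdet)], n, Pdet)
  Lpsi <- C %*% t(ds$Xocc)
  if (ds$S > 0) {
    alpha <- dr[n * (Pocc + Pdet) + seq_len(ds$S)]
    Lpsi <- Lpsi + matrix(alpha[ds$site_index], n, ds$J, byrow = TRUE)
  }
  list(psi = inv_logit(Lpsi), p = inv_logit(D %*% t(ds$Wdet)))
}

#' Posterior predictive check with a Pearson chi-square discrepancy
#'
#' For each retained draw, a replicate detection array is simulated from the
#' draw's occupancy and detection probabilities; observed and replicated
#' detection totals are aggregated over rows (units; totals over species and
#' visits) and over columns (species; totals over units and visits) and
#' compared to their expectations with a Pearson chi-square,
#' `sum((agg - expected)^2 / (expected + c))`. The Bayesian p-value is the
#' fraction of draws whose replicated discrepancy exceeds the observed one,
#' with exact ties counting one half, so a model confronted with its own
#' replicate data scores exactly 0.5.
#'
#' @param post A fitted [fit_community_model()] posterior.
#' @param ndraws Number of retained draws to use (defaults to all; draws are
#'   taken evenly across the retained sample).
#' @param stabilizer Small constant `c` added to expected counts.
#' @return Object of class `ppc_result` with per-draw discrepancies and
#'   Bayesian p-values `p_rows`, `p_cols`, plus the posterior mean observed
#'   discrepancies `chisq_rows`, `chisq_cols`.
#' @export
posterior_predictive_check <- function(post, ndraws = NULL, stabilizer = 1e-4) {
  ds <- post$design
  n <- ds$n; J <- ds$J; M <- ds$M
  total <- nrow(post$draws)
  use <- if (is.null(ndraws) || ndraws >= total) seq_len(total)
         else unique(round(seq(1, total, length.out = ndraws)))
  nd <- length(use)
  Yrow <- as.vector(colSums(ds$Y) %*% ds$U)      # per-unit observed totals
  Ycol <- rowSums(ds$Y)                          # per-species observed totals
  chisq <- function(agg, expc) sum((agg - expc)^2 / (expc + stabilizer))
  out <- matrix(NA_real_, nd, 4,
                dimnames = list(NULL, c("obs_rows", "rep_rows", "obs_cols", "rep_cols")))
  for (t in seq_len(nd)) {
    pr <- .draw_prob(post, use[t])
    psi_obs <- pr$psi[, ds$unit_of_obs, drop = FALSE]  # n x M
    Ecell <- psi_obs * pr$p                            # marginal expected detection
    exp_row <- as.vector(colSums(Ecell) %*% ds$U)
    exp_col <- rowSums(Ecell)
    zrep <- matrix(stats::rbinom(n * J, 1, pr$psi), n, J)
    yrep <- matrix(stats::rbinom(n * M, 1,
                                 zrep[, ds$unit_of_obs, drop = FALSE] * pr$p), n, M)
    rep_row <- as.vector(colSums(yrep) %*% ds$U)
    rep_col <- rowSums(yrep)
    out[t, ] <- c(chisq(Yrow, exp_row), chisq(rep_row, exp_row),
                  chisq(Ycol, exp_col), chisq(rep_col, exp_col))
  }
  pval <- function(obs, rep) mean((rep > obs) + 0.5 * (rep == obs))
  structure(list(
    draws = as.data.frame(out),
    p_rows = pval(out[, "obs_rows"], out[, "rep_rows"]),
    p_cols = pval(out[, "obs_cols"], out[, "rep_cols"]),
    chisq_rows = mean(out[, "obs_rows"]),
    chisq_cols = mean(out[, "obs_cols"]),
    stabilizer = stabilizer
  ), class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("<ppc_result> chisq_rows = %.2f (p = %.3f); chisq_cols = %.2f (p = %.3f)\n",
              x$chisq_rows, x$p_rows, x$chisq_cols, x$p_cols))
  invisible(x)
}

#' Mann-Whitney AUC of a score vector against binary outcomes
#'
#' Area under the ROC curve via the rank-sum formulation with midrank
#' handling of ties; equals the probability that a randomly chosen positive
#' cell scores higher than a randomly chosen negative one (ties count one
#' half). Invariant under strictly increasing transformations of the scores.
#'
#' @param scores Numeric vector.
#' @param y Binary vector of the same length.
#' @return AUC in `[0, 1]`; `NA` when `y` is all 0 or all 1.
#' @export
auc_mann_whitney <- function(scores, y) {
  if (length(scores) != length(y)) stop_input("'scores' and 'y' lengths differ")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predictive ability of a fitted community model (posterior AUC)
#'
#' For each retained draw, every observed species x unit x visit cell is
#' scored by its unconditional detection probability `psi_ij * p_ijk` and the
#' AUC against the observed detections is computed; the per-draw AUCs are
#' summarized by their mean and 95% credible interval. 0.5 means the model
#' discriminates no better than random; 1 is perfect classification.
#'
#' @inheritParams posterior_predictive_check
#' @return Object of class `auc_result`: per-draw AUC, `mean`, `cri`.
#' @export
compute_auc <- function(post, ndraws = NULL) {
  ds <- post$design
  total <- nrow(post$draws)
  use <- if (is.null(ndraws) || ndraws >= total) seq_len(total)
         else unique(round(seq(1, total, length.out = ndraws)))
  yv <- as.vector(ds$Y)
  auc <- vapply(use, function(d) {
    pr <- .draw_prob(post, d)
    s <- pr$psi[, ds$unit_of_obs, drop = FALSE] * pr$p
    auc_mann_whitney(as.vector(s), yv)
  }, numeric(1))
  if (all(is.na(auc)))
    return(structure(list(draws = auc, mean = NA_real_, cri = c(NA_real_, NA_real_)),
                     class = "auc_result"))
  structure(list(draws = auc, mean = mean(auc), cri = cri(auc, 0.95)),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC = %.3f (95%% CRI: [%.3f, %.3f]), %d draws\n",
              x$mean, x$cri[1], x$cri[2], length(x$draws)))
  invisible(x)
}

#' Posterior summaries with equal-tailed credible intervals
#'
#' Mean, credible-interval bounds and an excludes-zero flag (both bounds on
#' the same side of 0, the usual Bayesian criterion for "the effect differs
#' from 0") for each parameter column of a posterior.
#'
#' @param post A `community_posterior`, an `apple_model_fit`, or a draws
#'   matrix with named columns.
#' @param level Credibility level, e.g. 0.95 or 0.90.
#' @param parameters Optional regular expression selecting parameter names.
#' @return Data frame with `parameter`, `mean`, `lower`, `upper`,
#'   `excludes_zero`.
#' @export
summarize_effects <- function(post, level = 0.95, parameters = NULL) {
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop_input("'level' must be in (0, 1)")
  draws <- if (is.matrix(post)) post else post$draws
  if (is.data.frame(draws)) draws <- as.matrix(draws)
  if (!is.null(parameters))
    draws <- draws[, grepl(parameters, colnames(draws)), drop = FALSE]
  qs <- apply(draws, 2, cri, level = level)
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    lower = qs[1, ],
    upper = qs[2, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$excludes_zero <- out$lower * out$upper > 0
  out
}
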