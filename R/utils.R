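## Internal numerical helpers shared across modules.

# Probabilities from the logistic link are kept strictly inside (0, 1) so
# downstream logs never produce -Inf from floating-point saturation.
.PROB_EPS <- 1e-12

inv_logit <- function(x) {
  p <- 1 / (1 + exp(-x))
  pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)
}

# log(1 + e^x), stable over the whole real line.
log1pexp <- function(x) {
  ax <- abs(x)
  (x + ax) / 2 + log1p(exp(-ax))
}

# log(p) and log(1 - p) straight from the linear predictor; numerically stable
# for large |x| where inv_logit() would round.
log_invlogit <- function(x) x - log1pexp(x)
log1m_invlogit <- function(x) -log1pexp(x)

logit <- function(p) stats::qlogis(pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS))

#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)

assert_flag <- function(x, name) {
  if (!(is.logical(x) && length(x) == 1L && !is.na(x)))
    stop_input(sprintf("'%s' must be TRUE or FALSE", name))
  x
}

assert_count <- function(x, name, min = 1) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min))
    stop_input(sprintf("'%s' must be a single integer >= %s", name, min))
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min))
    stop_input(sprintf("'%s' must be a single finite number >= %s", name, min))
  as.numeric(x)
}

# Derive independent sub-stream seeds from one master seed, staying within
# 32-bit integer range for set.seed().
derive_seeds <- function(seed, n, salt = 0L) {
  seed <- assert_count(seed, "seed", min = 0)
  (as.numeric(seed) + 1000003 * (seq_len(n) + as.numeric(salt))) %% 2147483647
}

# Equal-tailed credible interval bounds.
cri <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), names = FALSE, type = 7)
}
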