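#' Inverse logit
#'
#' @param x numeric vector of log-odds.
#' @return probabilities in (0, 1).
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Logit
#'
#' @param p probabilities in (0, 1).
#' @return log-odds.
#' @export
logit <- function(p) log(p / (1 - p))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Stable log Bernoulli(y | inv_logit(eta)) = -log(1 + exp(-(2y-1) eta))
log_bernoulli_logit <- function(y, eta) {
  s <- (2 * y - 1) * eta
  ifelse(s > -30, -log1p(exp(-s)), s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

## Location/scale of a normal truncated at zero whose realized mean/sd equal
## the targets. Solved numerically; for targets many SDs above zero the
## adjustment is tiny but still applied so configured moments are exact in
## expectation.
truncnorm_match <- function(target_mean, target_sd) {
  stopifnot(target_sd > 0, target_mean >= 0)
  tn_moments <- function(mu, sigma) {
    a <- -mu / sigma                      # standardized truncation point
    lam <- exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    c(m, sqrt(pmax(v, 1e-12)))
  }
  obj <- function(par) {
    mo <- tn_moments(par[1], exp(par[2]))
    (mo[1] - target_mean)^2 + (mo[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

## Draw from N(mu, sigma) truncated at zero by inverse-cdf sampling.
rtruncnorm0 <- function(n, mu, sigma) {
  p0 <- pnorm(0, mu, sigma)
  u <- runif(n, p0, 1)
  qnorm(u, mu, sigma)
}

## Over-dispersed count draw matched to a mean/SD; Poisson fallback when the
## variance does not exceed the mean (with a one-time warning per call site).
rcount_match <- function(n, mean, sd, warn = TRUE) {
  if (mean <= 0) return(rep(0L, n))
  v <- sd^2
  if (v > mean * (1 + 1e-8)) {
    size <- mean^2 / (v - mean)
    rnbinom(n, size = size, mu = mean)
  } else {
    if (warn) warning(sprintf(
      "count variable with SD^2 <= mean (mean=%.3g, sd=%.3g): using Poisson",
      mean, sd), call. = FALSE)
    rpois(n, mean)
  }
}

## Empirical quantiles with linear interpolation (stats type 7).
ci_quantile <- function(x, probs = c(0.025, 0.975)) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

## Derive a stream seed from a base seed; kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}
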