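#' Fit a generalized Pareto distribution to tail exceedances
#'
#' Profile-likelihood estimator of the GPD shape/scale (Zhang–Stephens
#' style grid over the transformed scale with a weakly informative
#' shape regularization), applied to exceedances over a tail cut point.
#' Parameterization: `F(x) = 1 - (1 + k x / sigma)^(-1/k)`.
#'
#' @param x positive exceedances.
#' @param regularize apply the shape prior pulling small-sample estimates
#'   toward 0.5.
#' @return list with `k` (shape) and `sigma` (scale); `k = NA` when fewer
#'   than 5 exceedances are supplied (smoothing should be skipped).
#' @export
fit_gpd_tail <- function(x, regularize = TRUE) {
  x <- x[is.finite(x)]
  if (length(x) < 5 || max(x) <= 0)
    return(list(k = NA_real_, sigma = NA_real_))
  N <- length(x)
  x <- sort(x)
  prior_b <- 3; prior_k <- 10
  m <- 30L + floor(sqrt(N))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  if (xstar <= 0) xstar <- min(x[x > 0])
  theta <- 1 / x[N] + (1 - sqrt(m / (jj - 0.5))) / (prior_b * xstar)
  k_of <- vapply(theta, function(b) mean(log1p(-b * x)), numeric(1))
  l_theta <- N * (log(-theta / k_of) - k_of - 1)
  w <- exp(l_theta - logsumexp(l_theta))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  if (regularize) k <- (k * N + prior_k * 0.5) / (N + prior_k)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

#' Pareto-smooth a vector of importance weights
#'
#' Replaces the `M = min(ceil(0.2 S), ceil(3 sqrt(S)))` largest raw
#' weights by expected order statistics of a generalized Pareto
#' distribution fitted to their exceedances over the cut point, truncates
#' all weights at the raw maximum, and normalizes to sum one.
#'
#' @param log_raw_weights finite log importance weights.
#' @return list with `weights` (normalized, summing to 1) and `khat`
#'   (GPD shape diagnostic; `NA` when smoothing was skipped).
#' @export
psis_smooth <- function(log_raw_weights) {
  lw <- log_raw_weights
  if (any(!is.finite(lw))) stop("non-finite log-weights at indices: ",
                                paste(utils::head(which(!is.finite(lw)), 5),
                                      collapse = ", "))
  S <- length(lw)
  lw <- lw - max(lw)
  w <- exp(lw)
  if (S < 25) {
    warning("fewer than 25 weights; falling back to truncated importance sampling",
            call. = FALSE)
    cap <- mean(w) * sqrt(S)
    w <- pmin(w, cap)
    return(list(weights = w / sum(w), khat = NA_real_))
  }
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  ord <- order(w)
  tail_ids <- ord[(S - M + 1):S]
  cut <- w[ord[S - M]]
  exceed <- w[tail_ids] - cut
  if (max(exceed) <= sqrt(.Machine$double.eps) || M < 5) {
    ## (near-)equal weights in the tail: nothing to smooth
    return(list(weights = w / sum(w), khat = NA_real_))
  }
  fit <- fit_gpd_tail(exceed)
  if (is.na(fit$k)) return(list(weights = w / sum(w), khat = NA_real_))
  pp <- (seq_len(M) - 0.5) / M
  smoothed <- cut + qgpd(pp, fit$k, fit$sigma)
  w_max <- max(w)
  w[tail_ids[order(w[tail_ids])]] <- pmin(smoothed, w_max)
  list(weights = w / sum(w), khat = fit$k)
}

#' PSIS-LOO predictive evaluation
#'
#' Computes, per observation, the Pareto-smoothed importance-sampling
#' estimate of the leave-one-out predictive density (`elpd_loo_i`) and
#' the LOO predictive probability `P(y_i = 1 | data minus i)`, using raw
#' log-weights `-loglik[, i]`.
#'
#' @param loglik `S x N` pointwise log-likelihood matrix from
#'   [pointwise_loglik()].
#' @param pred_draws `S x N` matrix of per-draw predicted probabilities
#'   from [predictive_draws()].
#' @return object of class `sw_loo`: list with `pointwise` (data frame of
#'   `elpd`, `p_hat`, `khat`), totals `elpd`, `se`, and `n_high_k`
#'   (count of `khat > 0.7`).
#' @export
loo_predictive <- function(loglik, pred_draws) {
  if (!all(dim(loglik) == dim(pred_draws)))
    stop("loglik and pred_draws shapes disagree")
  bad <- which(!is.finite(loglik), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite log-likelihood entries, first at (draw, obs) = (",
         bad[1, 1], ", ", bad[1, 2], ")")
  N <- ncol(loglik)
  elpd <- p_hat <- khat <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-loglik[, i])
    wi <- sm$weights
    elpd[i] <- logsumexp(log(wi) + loglik[, i])
    p_hat[i] <- sum(wi * pred_draws[, i])
    khat[i] <- sm$khat
  }
  structure(list(
    pointwise = data.frame(elpd = elpd, p_hat = p_hat, khat = khat),
    elpd = sum(elpd),
    se = sqrt(N * stats::var(elpd)),
    n_high_k = sum(khat > 0.7, na.rm = TRUE)
  ), class = "sw_loo")
}

#' @export
print.sw_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO over %d observations\n", nrow(x$pointwise)))
  cat(sprintf("  elpd_loo: %.1f (SE %.1f)\n", x$elpd, x$se))
  cat(sprintf("  Pareto k > 0.7: %d observation(s)\n", x$n_high_k))
  invisible(x)
}
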