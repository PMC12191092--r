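## Gradient-based samplers shared by the logistic, piecewise and neural
## network models. `lp_grad(theta)` must return list(lp = scalar log
## posterior, grad = gradient vector); both samplers treat it as a black
## box over an unconstrained parameterization.

leapfrog <- function(lp_grad, theta, mom, eps, n_steps, inv_mass) {
  g <- lp_grad(theta)$grad
  for (s in seq_len(n_steps)) {
    mom <- mom + 0.5 * eps * g
    theta <- theta + eps * inv_mass * mom
    g <- lp_grad(theta)$grad
    if (any(!is.finite(g))) return(list(theta = theta, mom = mom, ok = FALSE))
    mom <- mom + 0.5 * eps * g
  }
  list(theta = theta, mom = mom, ok = TRUE)
}

hamiltonian <- function(lp, mom, inv_mass) -lp + 0.5 * sum(inv_mass * mom^2)

find_initial_eps <- function(lp_grad, theta, inv_mass) {
  eps <- 0.1
  d <- length(theta)
  mom <- rnorm(d) / sqrt(inv_mass)
  h0 <- hamiltonian(lp_grad(theta)$lp, mom, inv_mass)
  step <- leapfrog(lp_grad, theta, mom, eps, 1L, inv_mass)
  h1 <- if (step$ok) hamiltonian(lp_grad(step$theta)$lp, step$mom, inv_mass) else Inf
  a <- if (exp(h0 - h1) > 0.5) 1 else -1
  for (it in 1:30) {
    eps2 <- eps * 2^a
    step <- leapfrog(lp_grad, theta, mom, eps2, 1L, inv_mass)
    h1 <- if (step$ok) hamiltonian(lp_grad(step$theta)$lp, step$mom, inv_mass) else Inf
    if ((exp(h0 - h1) > 0.5) != (a > 0)) break
    eps <- eps2
  }
  eps
}

## One chain of adaptive HMC: dual-averaging step-size adaptation toward a
## target acceptance rate, with a diagonal mass matrix re-estimated from
## the middle of warmup. Trajectory length is jittered uniformly.
hmc_chain <- function(lp_grad, init, n_warmup, n_draws, target_accept = 0.8,
                      n_leapfrog = c(8L, 24L)) {
  d <- length(init)
  theta <- init
  inv_mass <- rep(1, d)
  eps <- find_initial_eps(lp_grad, theta, inv_mass)

  mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  adapt_count <- 0

  mass_window <- seq(max(1, floor(n_warmup * 0.4)), floor(n_warmup * 0.8))
  mass_buf <- matrix(NA_real_, length(mass_window), d)

  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, d)
  accept_sum <- 0; divergences <- 0L

  for (it in seq_len(total)) {
    mom <- rnorm(d) / sqrt(inv_mass)
    cur <- lp_grad(theta)
    h0 <- hamiltonian(cur$lp, mom, inv_mass)
    L <- sample(n_leapfrog[1]:n_leapfrog[2], 1L)
    prop <- leapfrog(lp_grad, theta, mom, eps, L, inv_mass)
    if (prop$ok) {
      lp1 <- lp_grad(prop$theta)$lp
      h1 <- hamiltonian(lp1, prop$mom, inv_mass)
      dh <- h0 - h1
      if (!is.finite(dh)) dh <- -Inf
      if (dh < -1000) divergences <- divergences + 1L
      a_prob <- min(1, exp(dh))
      if (runif(1) < a_prob) theta <- prop$theta
    } else {
      a_prob <- 0
      divergences <- divergences + 1L
    }

    if (it <= n_warmup) {
      adapt_count <- adapt_count + 1
      h_bar <- (1 - 1 / (adapt_count + t0)) * h_bar +
        (target_accept - a_prob) / (adapt_count + t0)
      log_eps <- mu - sqrt(adapt_count) / gamma * h_bar
      w <- adapt_count^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it %in% mass_window)
        mass_buf[it - mass_window[1] + 1, ] <- theta
      if (it == mass_window[length(mass_window)]) {
        v <- apply(mass_buf, 2, stats::var)
        v[!is.finite(v) | v <= 1e-10] <- 1e-10
        inv_mass <- v
        ## restart step-size adaptation under the new metric
        eps <- find_initial_eps(lp_grad, theta, inv_mass)
        mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0; adapt_count <- 0
      }
      if (it == n_warmup) eps <- exp(log_eps_bar)
    } else {
      draws[it - n_warmup, ] <- theta
      accept_sum <- accept_sum + a_prob
    }
  }
  list(draws = draws, accept_rate = accept_sum / n_draws,
       divergences = divergences, step_size = eps)
}

split_rhat <- function(chain_list) {
  ## split-R-hat per parameter over chains
  half <- lapply(chain_list, function(m) {
    n <- nrow(m)
    h <- floor(n / 2)
    list(m[seq_len(h), , drop = FALSE], m[(n - h + 1):n, , drop = FALSE])
  })
  parts <- do.call(c, half)
  means <- sapply(parts, colMeans)
  vars <- sapply(parts, function(m) apply(m, 2, stats::var))
  if (is.null(dim(means))) { means <- matrix(means, 1); vars <- matrix(vars, 1) }
  n <- nrow(parts[[1]])
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  sqrt((W * (n - 1) / n + B / n) / pmax(W, 1e-300))
}

#' Adaptive Hamiltonian Monte Carlo
#'
#' Generic HMC with dual-averaging step-size adaptation and diagonal mass
#' estimation, used as the default inference engine for all model
#' families in the package.
#'
#' @param lp_grad function of the parameter vector returning
#'   `list(lp, grad)`.
#' @param init initial parameter vector.
#' @param n_warmup,n_draws warmup and retained iterations per chain.
#' @param chains number of independent chains.
#' @param seed integer seed.
#' @param target_accept dual-averaging target acceptance rate.
#' @return list with `draws` (all chains stacked), `accept_rate`,
#'   `divergences`, `rhat` (per parameter, `NA` for a single chain) and a
#'   `flag` marking doubtful convergence.
#' @export
hmc_sample <- function(lp_grad, init, n_warmup = 500, n_draws = 1000,
                       chains = 2, seed = 1, target_accept = 0.8) {
  chain_out <- vector("list", chains)
  for (c in seq_len(chains)) {
    set.seed(derive_seed(seed, c))
    init_c <- init + rnorm(length(init), 0, 0.1)
    chain_out[[c]] <- hmc_chain(lp_grad, init_c, n_warmup, n_draws,
                                target_accept)
  }
  draws <- do.call(rbind, lapply(chain_out, `[[`, "draws"))
  rhat <- if (chains > 1) split_rhat(lapply(chain_out, `[[`, "draws"))
          else rep(NA_real_, length(init))
  accept <- mean(sapply(chain_out, `[[`, "accept_rate"))
  div <- sum(sapply(chain_out, `[[`, "divergences"))
  flag <- (accept < 0.5) || (chains > 1 && any(rhat > 1.1, na.rm = TRUE))
  if (flag)
    warning(sprintf(
      "sampler diagnostics doubtful (mean accept %.2f, max rhat %.3f)",
      accept, suppressWarnings(max(rhat, na.rm = TRUE))), call. = FALSE)
  list(draws = draws, accept_rate = accept, divergences = div,
       rhat = rhat, flag = flag)
}

#' Mean-field variational inference
#'
#' Maximizes the evidence lower bound of a fully factorized Gaussian
#' approximation with single-sample reparameterization gradients and Adam
#' updates, restarted from jittered initializations; the restart with the
#' best smoothed ELBO is kept.
#'
#' @inheritParams hmc_sample
#' @param n_iter gradient steps per restart.
#' @param n_restarts random restarts guarding against mode collapse.
#' @param n_draws draws sampled from the fitted approximation.
#' @param lr Adam learning rate.
#' @return list with `draws`, `elbo` (smoothed final ELBO), `mu`, `sd`,
#'   and `flag`.
#' @export
vi_fit <- function(lp_grad, init, n_iter = 3000, n_restarts = 5,
                   n_draws = 1000, lr = 0.05, seed = 1) {
  d <- length(init)
  run_one <- function(r) {
    set.seed(derive_seed(seed, 100 + r))
    mu <- init + rnorm(d, 0, 0.3 * (r > 1))
    omega <- rep(-2, d)
    m1 <- v1 <- m2 <- v2 <- rep(0, d)
    b1 <- 0.9; b2 <- 0.999; ee <- 1e-8
    elbo_trace <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      epsn <- rnorm(d)
      sd_q <- exp(omega)
      theta <- mu + sd_q * epsn
      lg <- lp_grad(theta)
      if (!all(is.finite(lg$grad)) || !is.finite(lg$lp)) {
        elbo_trace[it] <- if (it > 1) elbo_trace[it - 1] else -Inf
        next
      }
      g_mu <- lg$grad
      g_om <- lg$grad * epsn * sd_q + 1      # + entropy gradient
      m1 <- b1 * m1 + (1 - b1) * g_mu; v1 <- b2 * v1 + (1 - b2) * g_mu^2
      m2 <- b1 * m2 + (1 - b1) * g_om; v2 <- b2 * v2 + (1 - b2) * g_om^2
      corr <- sqrt(1 - b2^it) / (1 - b1^it)
      mu <- mu + lr * corr * m1 / (sqrt(v1) + ee)
      omega <- omega + lr * corr * m2 / (sqrt(v2) + ee)
      elbo_trace[it] <- lg$lp + sum(omega)
    }
    tail_n <- max(50, floor(n_iter * 0.1))
    list(mu = mu, omega = omega,
         elbo = mean(elbo_trace[(n_iter - tail_n + 1):n_iter]))
  }
  fits <- lapply(seq_len(n_restarts), run_one)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "elbo"))]]
  set.seed(derive_seed(seed, 999))
  sd_q <- exp(best$omega)
  draws <- matrix(rnorm(n_draws * d), n_draws, d)
  draws <- sweep(sweep(draws, 2, sd_q, "*"), 2, best$mu, "+")
  list(draws = draws, elbo = best$elbo, mu = best$mu, sd = sd_q,
       flag = !is.finite(best$elbo))
}
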