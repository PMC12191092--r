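#' Specification of the hierarchical logistic model
#'
#' The model is `y_it ~ Bernoulli(inv_logit(alpha + u_t + z_it' beta))`
#' over post-baseline person-years, with masked design cells replaced by
#' latent values `z_miss ~ Normal(mu_col, sigma_col)` that are sampled
#' jointly with the regression parameters, so missing covariates are
#' marginalized during inference rather than imputed once.
#'
#' Priors: `alpha ~ Normal(0, intercept_scale)`; coefficients share a
#' shrinkage scale, either fixed (`beta_j ~ Normal(0, coef_scale)`) or
#' learned (`beta_j ~ Normal(0, lambda)`, `lambda ~ half-Normal(0, 1)`).
#' The optional year-level random intercept has `u_t ~ Normal(0, tau)`,
#' `tau ~ half-Normal(0, 1)`. Imputation hyperparameters `mu_col`,
#' `sigma_col` carry `Normal(0, 1)` / `half-Normal(0, 1)` priors when
#' learned, and are pinned at (0, 1) otherwise.
#'
#' @param covariate_set which covariate classes the design was built with
#'   (metadata only; recorded in the fit).
#' @param intercept_scale prior SD of the intercept.
#' @param coef_scale fixed coefficient prior SD (used when
#'   `learn_shrinkage = FALSE`).
#' @param learn_shrinkage learn a shared coefficient scale.
#' @param year_effect include the year-level random intercept.
#' @param learn_imputation learn per-column imputation hyperparameters.
#' @param algorithm `"hmc"` (default) or `"vi"`.
#' @param draws retained posterior draws per chain.
#' @param warmup warmup iterations per chain (HMC) / optimization steps
#'   scale (VI uses `vi_iter`).
#' @param chains HMC chains.
#' @param vi_iter,vi_restarts variational settings.
#' @param seed integer seed.
#' @return object of class `logistic_spec`.
#' @export
logistic_spec <- function(covariate_set = "full",
                          intercept_scale = 2.5,
                          coef_scale = 1,
                          learn_shrinkage = TRUE,
                          year_effect = TRUE,
                          learn_imputation = TRUE,
                          algorithm = c("hmc", "vi"),
                          draws = 1000, warmup = 500, chains = 4,
                          vi_iter = 3000, vi_restarts = 5,
                          seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(intercept_scale > 0, coef_scale > 0, draws * chains >= 100)
  structure(list(covariate_set = covariate_set,
                 intercept_scale = intercept_scale, coef_scale = coef_scale,
                 learn_shrinkage = learn_shrinkage, year_effect = year_effect,
                 learn_imputation = learn_imputation, algorithm = algorithm,
                 draws = draws, warmup = warmup, chains = chains,
                 vi_iter = vi_iter, vi_restarts = vi_restarts,
                 seed = as.integer(seed)),
            class = "logistic_spec")
}

## Layout of the unconstrained parameter vector for the linear family.
logistic_layout <- function(design, spec) {
  p <- ncol(design$z)
  years <- sort(unique(design$year))
  cells <- which(design$mask, arr.ind = TRUE)
  miss_cols <- sort(unique(cells[, 2]))
  pm <- length(miss_cols)
  idx <- list(); at <- 0
  take <- function(n) { v <- at + seq_len(n); at <<- at + n; v }
  idx$alpha <- take(1)
  idx$beta <- take(p)
  if (spec$year_effect) { idx$u <- take(length(years)); idx$log_tau <- take(1) }
  if (spec$learn_shrinkage) idx$log_lambda <- take(1)
  if (nrow(cells)) {
    idx$zm <- take(nrow(cells))
    if (spec$learn_imputation) {
      idx$mu_m <- take(pm)
      idx$log_sig_m <- take(pm)
    }
  }
  list(idx = idx, n_par = at, p = p, years = years,
       cells = cells, miss_cols = miss_cols,
       cell_group = match(if (nrow(cells)) cells[, 2] else integer(0), miss_cols))
}

## Log posterior + gradient for the (piecewise-)logistic family. When
## `partition` is non-NULL it carries levels (n x D matrix), per-dimension
## level counts, and the deviation prior scale; deviations extend the
## parameter vector beyond the base layout.
logistic_lp_grad <- function(design, spec, layout, partition = NULL) {
  y <- design$y
  Z0 <- design$z
  Z0[design$mask] <- 0
  n <- nrow(Z0); p <- ncol(Z0)
  idx <- layout$idx
  cells <- layout$cells
  M <- nrow(cells)
  cell_ij <- if (M) cbind(cells[, 1], cells[, 2]) else NULL
  group <- layout$cell_group
  pm <- length(layout$miss_cols)
  year_id <- match(design$year, layout$years)
  Tn <- length(layout$years)
  s0 <- spec$intercept_scale

  part <- partition
  D <- if (is.null(part)) 0L else ncol(part$levels)

  function(theta) {
    alpha <- theta[idx$alpha]
    beta <- theta[idx$beta]
    lambda <- if (spec$learn_shrinkage) exp(theta[idx$log_lambda]) else spec$coef_scale
    Zf <- Z0
    if (M) {
      ## latent imputed values, non-centered: z = mu_col + sigma_col * raw
      zraw <- theta[idx$zm]
      if (spec$learn_imputation) {
        mu_m <- theta[idx$mu_m]
        sig_m <- exp(theta[idx$log_sig_m])
      } else {
        mu_m <- rep(0, pm); sig_m <- rep(1, pm)
      }
      mu_c <- mu_m[group]; sig_c <- sig_m[group]
      zm <- mu_c + sig_c * zraw
      Zf[cell_ij] <- zm
    }
    eta <- alpha + as.vector(Zf %*% beta)
    if (spec$year_effect) {
      u <- theta[idx$u]
      tau <- exp(theta[idx$log_tau])
      eta <- eta + u[year_id]
    }
    if (D) {
      for (d in seq_len(D)) {
        for (l in seq_len(part$n_levels[d])) {
          rows <- part$rows[[d]][[l]]
          if (!length(rows)) next
          a_dl <- theta[part$idx_a[[d]][l]]
          del <- theta[part$idx_delta[[d]][[l]]]
          eta[rows] <- eta[rows] + a_dl + as.vector(Zf[rows, , drop = FALSE] %*% del)
        }
      }
    }
    pr <- inv_logit(eta)
    r <- y - pr
    lp <- sum(log_bernoulli_logit(y, eta)) -
      0.5 * alpha^2 / s0^2 -
      p * log(lambda) - 0.5 * sum(beta^2) / lambda^2

    g <- numeric(length(theta))
    g[idx$alpha] <- sum(r) - alpha / s0^2
    g_beta <- as.vector(crossprod(Zf, r)) - beta / lambda^2
    g[idx$beta] <- g_beta
    if (spec$learn_shrinkage) {
      lp <- lp - 0.5 * lambda^2          # half-normal(0,1) on lambda
      g[idx$log_lambda] <- -p + sum(beta^2) / lambda^2 - lambda^2 + 1
      lp <- lp + theta[idx$log_lambda]   # Jacobian of log transform
    }
    if (spec$year_effect) {
      lp <- lp - Tn * log(tau) - 0.5 * sum(u^2) / tau^2 -
        0.5 * tau^2 + theta[idx$log_tau]
      g[idx$u] <- rowsum(r, year_id)[, 1] - u / tau^2
      g[idx$log_tau] <- -Tn + sum(u^2) / tau^2 - tau^2 + 1
    }
    if (M) {
      lp <- lp - 0.5 * sum(zraw^2)
      coef_cell <- beta[cells[, 2]]
      if (D) {
        for (d in seq_len(D)) {
          lev_cell <- part$levels[cells[, 1], d]
          for (l in seq_len(part$n_levels[d])) {
            sel <- lev_cell == l
            if (any(sel))
              coef_cell[sel] <- coef_cell[sel] +
                theta[part$idx_delta[[d]][[l]]][cells[sel, 2]]
          }
        }
      }
      pull <- coef_cell * r[cells[, 1]]      # d lp / d z_cell
      g[idx$zm] <- pull * sig_c - zraw
      if (spec$learn_imputation) {
        lp <- lp - 0.5 * sum(mu_m^2) - 0.5 * sum(sig_m^2) +
          sum(theta[idx$log_sig_m])
        g[idx$mu_m] <- rowsum(pull, group)[, 1] - mu_m
        g[idx$log_sig_m] <- rowsum(pull * sig_c * zraw, group)[, 1] -
          sig_m^2 + 1
      }
    }
    if (D) {
      sdev <- part$dev_scale
      for (d in seq_len(D)) {
        for (l in seq_len(part$n_levels[d])) {
          rows <- part$rows[[d]][[l]]
          ia <- part$idx_a[[d]][l]; idl <- part$idx_delta[[d]][[l]]
          a_dl <- theta[ia]; del <- theta[idl]
          lp <- lp - 0.5 * (a_dl^2 + sum(del^2)) / sdev^2
          if (length(rows)) {
            g[ia] <- sum(r[rows]) - a_dl / sdev^2
            g[idl] <- as.vector(crossprod(Zf[rows, , drop = FALSE], r[rows])) -
              del / sdev^2
          } else {
            g[ia] <- -a_dl / sdev^2
            g[idl] <- -del / sdev^2
          }
        }
      }
    }
    list(lp = lp, grad = g)
  }
}

run_inference <- function(lp_grad, init, spec) {
  if (spec$algorithm == "hmc") {
    out <- hmc_sample(lp_grad, init, n_warmup = spec$warmup,
                      n_draws = spec$draws, chains = spec$chains,
                      seed = spec$seed)
    list(draws = out$draws,
         diagnostics = list(algorithm = "hmc",
                            accept_rate = out$accept_rate,
                            divergences = out$divergences,
                            max_rhat = suppressWarnings(max(out$rhat, na.rm = TRUE)),
                            flag = out$flag))
  } else {
    out <- vi_fit(lp_grad, init, n_iter = spec$vi_iter,
                  n_restarts = spec$vi_restarts,
                  n_draws = spec$draws * spec$chains, seed = spec$seed)
    list(draws = out$draws,
         diagnostics = list(algorithm = "vi", elbo = out$elbo, flag = out$flag))
  }
}

#' Fit the Bayesian hierarchical logistic regression
#'
#' Samples the joint posterior over the intercept, standardized
#' coefficients, optional year-level random intercepts, imputation
#' hyperparameters, and one latent value per masked design cell.
#'
#' @param design an `sw_design` from [build_design()].
#' @param spec a [logistic_spec()].
#' @return an object of class `c("sw_logistic", "sw_fit")` carrying the
#'   draw matrix, parameter layout, design, and sampler diagnostics.
#' @examples
#' cfg <- cohort_config(n_participants = 120, seed = 2)
#' panel <- generate_cohort(cfg)
#' des <- build_design(panel, fit_standardizer(panel), "demo")
#' fit <- fit_logistic(des, logistic_spec(draws = 100, warmup = 100,
#'                                        chains = 1, seed = 3))
#' @export
fit_logistic <- function(design, spec = logistic_spec()) {
  stopifnot(inherits(design, "sw_design"))
  if (nrow(design$z) == 0 || ncol(design$z) == 0)
    stop("empty design")
  layout <- logistic_layout(design, spec)
  lp_grad <- logistic_lp_grad(design, spec, layout)
  init <- numeric(layout$n_par)
  init[layout$idx$alpha] <- logit(min(max(mean(design$y), 0.02), 0.98))
  if (!is.null(layout$idx$log_tau)) init[layout$idx$log_tau] <- -1
  res <- run_inference(lp_grad, init, spec)
  structure(list(draws = res$draws, layout = layout, design = design,
                 spec = spec, diagnostics = res$diagnostics,
                 type = "logistic"),
            class = c("sw_logistic", "sw_fit"))
}

## Linear predictor draws: N x S matrix. For a design other than the
## training one, masked cells are drawn per-posterior-draw from the
## learned imputation hyperparameters.
eta_draws <- function(fit, design, ...) UseMethod("eta_draws")

eta_draws_linear <- function(fit, design, delta_fun = NULL) {
  layout <- fit$layout; idx <- layout$idx
  B <- fit$draws[, idx$beta, drop = FALSE]
  S <- nrow(B)
  Z0 <- design$z; Z0[design$mask] <- 0
  eta <- Z0 %*% t(B)
  eta <- sweep(eta, 2, fit$draws[, idx$alpha], "+")
  if (fit$spec$year_effect) {
    U <- fit$draws[, idx$u, drop = FALSE]
    yid <- match(design$year, layout$years)
    if (anyNA(yid)) stop("design contains years unseen in the fit")
    eta <- eta + t(U)[yid, , drop = FALSE]
  }
  zm_draws <- latent_draws(fit, design)
  if (!is.null(zm_draws)) {
    cells <- which(design$mask, arr.ind = TRUE)
    for (m in seq_len(nrow(cells))) {
      coef <- B[, cells[m, 2]]
      if (!is.null(delta_fun)) coef <- coef + delta_fun(cells[m, 1], cells[m, 2])
      eta[cells[m, 1], ] <- eta[cells[m, 1], ] + zm_draws[, m] * coef
    }
  }
  eta
}

## S x M matrix of latent values for the masked cells of `design`, or NULL.
latent_draws <- function(fit, design) {
  layout <- fit$layout; idx <- layout$idx
  cells <- which(design$mask, arr.ind = TRUE)
  if (!nrow(cells)) return(NULL)
  same <- nrow(design$mask) == nrow(fit$design$mask) &&
    ncol(design$mask) == ncol(fit$design$mask) &&
    all(design$mask == fit$design$mask)
  if (same && !is.null(idx$zm)) {
    zraw <- fit$draws[, idx$zm, drop = FALSE]
    if (isTRUE(fit$spec$learn_imputation) && !is.null(idx$mu_m)) {
      g <- layout$cell_group
      mu <- fit$draws[, idx$mu_m, drop = FALSE]
      sg <- exp(fit$draws[, idx$log_sig_m, drop = FALSE])
      return(mu[, g, drop = FALSE] + sg[, g, drop = FALSE] * zraw)
    }
    return(zraw)
  }
  ## new masked cells: simulate from the imputation prior per draw
  S <- nrow(fit$draws)
  pm_cols <- layout$miss_cols
  bad <- setdiff(unique(cells[, 2]), pm_cols)
  if (length(bad) && !fit$spec$learn_imputation) bad <- integer(0)
  if (length(bad))
    stop("masked cells in columns without imputation hyperparameters: ",
         paste(colnames(design$z)[bad], collapse = ", "))
  if (fit$spec$learn_imputation && !is.null(idx$mu_m)) {
    mu <- fit$draws[, idx$mu_m, drop = FALSE]
    sg <- exp(fit$draws[, idx$log_sig_m, drop = FALSE])
    g <- match(cells[, 2], pm_cols)
    zm <- matrix(rnorm(S * nrow(cells)), S, nrow(cells))
    zm * sg[, g, drop = FALSE] + mu[, g, drop = FALSE]
  } else {
    matrix(rnorm(S * nrow(cells)), S, nrow(cells))
  }
}

#' @export
eta_draws.sw_logistic <- function(fit, design, ...) eta_draws_linear(fit, design)

#' Per-draw pointwise log-likelihood
#'
#' Entry `(s, i)` is `log Bernoulli(y_i | p_i^(s))` under draw `s`'s
#' parameters, using that draw's imputed values for row `i`'s masked
#' cells. All model families share this contract, which makes the
#' LOO-based evaluation model-agnostic.
#'
#' @param fit an `sw_fit`.
#' @param design the design to evaluate on (defaults to the training
#'   design).
#' @return `S x N` matrix.
#' @export
pointwise_loglik <- function(fit, design = fit$design) {
  stopifnot(inherits(fit, "sw_fit"))
  eta <- eta_draws(fit, design)
  t(log_bernoulli_logit(matrix(design$y, nrow(eta), ncol(eta)), eta))
}

#' Per-draw predicted probabilities
#'
#' @inheritParams pointwise_loglik
#' @return `S x N` matrix of probabilities.
#' @export
predictive_draws <- function(fit, design = fit$design) {
  t(inv_logit(eta_draws(fit, design)))
}

#' Posterior-mean predicted probability per row
#'
#' @inheritParams pointwise_loglik
#' @return numeric vector in (0, 1).
#' @export
predict_prob <- function(fit, design = fit$design) {
  rowMeans(inv_logit(eta_draws(fit, design)))
}

#' @export
predict.sw_fit <- function(object, design = object$design,
                           type = c("prob", "link"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_prob(object, design)
  else rowMeans(eta_draws(object, design))
}

#' Odds-ratio summaries
#'
#' Per design column: posterior mean of `exp(beta_j)` with central 95%
#' credible interval (linear-interpolation empirical quantiles), sorted by
#' the magnitude of the posterior mean log odds ratio for top-k reporting.
#'
#' @param fit an `sw_fit` of the linear family.
#' @param top optionally keep only the `top` largest-effect columns.
#' @return data frame of class `sw_or` with columns `name`, `class`,
#'   `kind`, `or_mean`, `or_lo`, `or_hi`, `log_or_mean`.
#' @export
odds_ratios <- function(fit, top = NULL) {
  stopifnot(inherits(fit, "sw_fit"))
  B <- fit$draws[, fit$layout$idx$beta, drop = FALSE]
  or <- exp(B)
  qs <- apply(or, 2, ci_quantile)
  out <- data.frame(name = colnames(fit$design$z),
                    class = fit$design$info$class,
                    kind = fit$design$info$kind,
                    or_mean = colMeans(or),
                    or_lo = qs[1, ], or_hi = qs[2, ],
                    log_or_mean = colMeans(B),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log_or_mean)), ]
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  class(out) <- c("sw_or", class(out))
  out
}

#' @export
coef.sw_fit <- function(object, ...) {
  b <- colMeans(object$draws[, object$layout$idx$beta, drop = FALSE])
  names(b) <- colnames(object$design$z)
  c(intercept = mean(object$draws[, object$layout$idx$alpha]), b)
}

#' @export
print.sw_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s model for steady work\n", x$type))
  cat(sprintf("  %d draws, %d parameters; design: %d rows x %d columns (%s)\n",
              nrow(x$draws), ncol(x$draws), nrow(x$design$z),
              ncol(x$design$z), x$spec$covariate_set %||% ""))
  dg <- x$diagnostics
  if (identical(dg$algorithm, "hmc"))
    cat(sprintf("  HMC: accept %.2f, divergences %d, max rhat %.3f%s\n",
                dg$accept_rate, dg$divergences, dg$max_rhat,
                if (isTRUE(dg$flag)) " [FLAGGED]" else ""))
  else
    cat(sprintf("  VI: ELBO %.1f%s\n", dg$elbo,
                if (isTRUE(dg$flag)) " [FLAGGED]" else ""))
  invisible(x)
}

#' @export
summary.sw_fit <- function(object, top = 10, ...) {
  print(object)
  cat("\nTop predictors (posterior mean odds ratio, 95% CrI):\n")
  or <- odds_ratios(object, top = top)
  print(data.frame(or[, c("name", "class", "kind")],
                   OR = round(or$or_mean, 3),
                   lo = round(or$or_lo, 3), hi = round(or$or_hi, 3)))
  invisible(or)
}

#' @export
print.sw_or <- function(x, ...) {
  cat("Odds ratios (standardized units), sorted by |log OR|\n")
  print.data.frame(utils::head(x, 20), digits = 3)
  invisible(x)
}
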