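#' Partition specification for the piecewise-linear GLM
#'
#' Defines the covariates whose (quantile-based) bins carve the data into
#' local regions. The region-specific coefficient is represented by
#' additive decomposition: `beta_cell = beta_global + sum_d
#' delta_{d, level_d(cell)}` with zero-mean shrinkage priors on every
#' deviation, so the model collapses onto the plain logistic regression as
#' the deviation scale shrinks to zero.
#'
#' @param columns design column names to partition on (default: baseline
#'   Communication & Cognition and baseline working status).
#' @param knot_probs quantile probabilities of the interior knots for
#'   continuous partition covariates (default terciles). Binary columns
#'   split on their two values.
#' @param dev_scale prior SD of the intercept/slope deviations.
#' @return object of class `partition_spec`.
#' @export
partition_spec <- function(columns = c("comm_cognition", "baseline_working"),
                           knot_probs = c(1/3, 2/3),
                           dev_scale = 0.5) {
  stopifnot(length(columns) >= 1, dev_scale > 0,
            all(knot_probs > 0 & knot_probs < 1))
  structure(list(columns = columns, knot_probs = knot_probs,
                 dev_scale = dev_scale),
            class = "partition_spec")
}

## Assign each design row a level per partition dimension; returns levels
## matrix, per-dimension breaks, and level counts. Levels with fewer than
## 2 rows are merged into the adjacent level with a warning.
assign_levels <- function(design, part, breaks = NULL) {
  D <- length(part$columns)
  n <- nrow(design$z)
  levels <- matrix(1L, n, D)
  out_breaks <- vector("list", D)
  for (d in seq_len(D)) {
    j <- match(part$columns[d], colnames(design$z))
    if (is.na(j)) stop("partition column '", part$columns[d],
                       "' not in the design")
    if (any(design$mask[, j]))
      stop("partition column '", part$columns[d],
           "' has masked cells; partition covariates must be fully observed")
    x <- design$z[, j]
    if (is.null(breaks)) {
      if (length(unique(x)) <= 2) {
        br <- if (length(unique(x)) == 2) mean(range(x)) else numeric(0)
      } else {
        br <- unique(stats::quantile(x, part$knot_probs, names = FALSE))
      }
    } else br <- breaks[[d]]
    lev <- findInterval(x, br) + 1L
    ## merge degenerate levels into a neighbor
    repeat {
      cnt <- tabulate(lev, max(lev, length(br) + 1L))
      small <- which(cnt < 2)
      if (!length(small) || length(br) == 0) break
      s <- small[1]
      drop_br <- min(max(s - 1, 1), length(br))
      warning(sprintf("partition level %d of '%s' has < 2 rows; merging",
                      s, part$columns[d]), call. = FALSE)
      br <- br[-drop_br]
      lev <- findInterval(x, br) + 1L
    }
    levels[, d] <- lev
    out_breaks[[d]] <- br
  }
  list(levels = levels, breaks = out_breaks,
       n_levels = vapply(out_breaks, function(b) length(b) + 1L, integer(1)))
}

build_partition <- function(design, part, layout, breaks = NULL) {
  al <- assign_levels(design, part, breaks)
  D <- length(part$columns)
  p <- ncol(design$z)
  at <- layout$n_par
  idx_a <- vector("list", D); idx_delta <- vector("list", D)
  rows <- vector("list", D)
  for (d in seq_len(D)) {
    nl <- al$n_levels[d]
    idx_a[[d]] <- integer(nl)
    idx_delta[[d]] <- vector("list", nl)
    rows[[d]] <- vector("list", nl)
    for (l in seq_len(nl)) {
      idx_a[[d]][l] <- at + 1L; at <- at + 1L
      idx_delta[[d]][[l]] <- at + seq_len(p); at <- at + p
      rows[[d]][[l]] <- which(al$levels[, d] == l)
    }
  }
  list(levels = al$levels, breaks = al$breaks, n_levels = al$n_levels,
       rows = rows, idx_a = idx_a, idx_delta = idx_delta,
       dev_scale = part$dev_scale, columns = part$columns,
       n_par = at, spec = part)
}

#' Fit the piecewise-linear Bayesian GLM
#'
#' A multilevel logistic regression with random intercepts and slopes over
#' the data regions induced by [partition_spec()], parameterized by
#' additive coefficient decomposition. The likelihood and the latent
#' imputation of masked non-partition cells are identical to
#' [fit_logistic()].
#'
#' @param design an `sw_design`.
#' @param part a [partition_spec()].
#' @param spec a [logistic_spec()] for the shared base model.
#' @return object of class `c("sw_piecewise", "sw_fit")`.
#' @export
fit_piecewise_glm <- function(design, part = partition_spec(),
                              spec = logistic_spec()) {
  stopifnot(inherits(design, "sw_design"), inherits(part, "partition_spec"))
  layout <- logistic_layout(design, spec)
  partition <- build_partition(design, part, layout)
  layout$n_par <- partition$n_par
  lp_grad <- logistic_lp_grad(design, spec, layout, partition)
  init <- numeric(layout$n_par)
  init[layout$idx$alpha] <- logit(min(max(mean(design$y), 0.02), 0.98))
  if (!is.null(layout$idx$log_tau)) init[layout$idx$log_tau] <- -1
  res <- run_inference(lp_grad, init, spec)
  structure(list(draws = res$draws, layout = layout, design = design,
                 spec = spec, partition = partition,
                 diagnostics = res$diagnostics, type = "piecewise"),
            class = c("sw_piecewise", "sw_fit"))
}

#' @export
eta_draws.sw_piecewise <- function(fit, design, ...) {
  part <- fit$partition
  D <- length(part$columns)
  same <- nrow(design$z) == nrow(fit$design$z) &&
    isTRUE(all.equal(design$z, fit$design$z))
  al <- if (same) part else assign_levels(design, part$spec, part$breaks)
  S <- nrow(fit$draws)
  delta_fun <- function(i, j) {
    out <- rep(0, S)
    for (d in seq_len(D)) {
      l <- al$levels[i, d]
      out <- out + fit$draws[, part$idx_delta[[d]][[l]][j]]
    }
    out
  }
  eta <- eta_draws_linear(fit, design, delta_fun = delta_fun)
  Z0 <- design$z; Z0[design$mask] <- 0
  for (d in seq_len(D)) {
    for (l in seq_len(part$n_levels[d])) {
      rows <- which(al$levels[, d] == l)
      if (!length(rows)) next
      A <- fit$draws[, part$idx_a[[d]][l]]
      Del <- fit$draws[, part$idx_delta[[d]][[l]], drop = FALSE]
      eta[rows, ] <- eta[rows, ] +
        matrix(A, length(rows), S, byrow = TRUE) +
        Z0[rows, , drop = FALSE] %*% t(Del)
    }
  }
  eta
}

#' Region-specific odds ratios from the additive decomposition
#'
#' For every cell of the partition, summarizes draws of
#' `exp(beta_global + sum_d delta_{d, level_d})` per design column.
#'
#' @param fit an `sw_piecewise` fit.
#' @return data frame with one block of odds-ratio rows per cell, the cell
#'   labelled by its per-dimension levels.
#' @export
effective_coefficients <- function(fit) {
  stopifnot(inherits(fit, "sw_piecewise"))
  part <- fit$partition
  D <- length(part$columns)
  grid <- expand.grid(lapply(part$n_levels, seq_len))
  names(grid) <- part$columns
  B <- fit$draws[, fit$layout$idx$beta, drop = FALSE]
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    eff <- B
    for (d in seq_len(D))
      eff <- eff + fit$draws[, part$idx_delta[[d]][[grid[g, d]]], drop = FALSE]
    or <- exp(eff)
    qs <- apply(or, 2, ci_quantile)
    out[[g]] <- data.frame(
      cell = paste(sprintf("%s=%d", part$columns, unlist(grid[g, ])),
                   collapse = ","),
      name = colnames(fit$design$z),
      or_mean = colMeans(or), or_lo = qs[1, ], or_hi = qs[2, ],
      log_or_mean = colMeans(eff),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specification of the shallow Bayesian neural network
#'
#' A single hidden layer of `hidden` tanh units feeding a logistic output:
#' `y ~ Bernoulli(inv_logit(w2' tanh(W1' z + b1) + b2))`, with independent
#' normal priors on all weights. Masked design cells are handled by the
#' same latent-imputation scheme as the logistic model.
#'
#' @param hidden hidden-layer width (default 12).
#' @param scan_range candidate widths for [width_scan()] (default 2..20).
#' @param weight_scale prior SD of the weights.
#' @param learn_imputation learn per-column imputation hyperparameters.
#' @param algorithm `"vi"` (default: mean-field variational with random
#'   restarts) or `"hmc"`.
#' @param draws posterior draws (per chain under HMC).
#' @param warmup,chains HMC settings.
#' @param vi_iter,vi_restarts variational settings.
#' @param seed integer seed.
#' @return object of class `bnn_spec`.
#' @export
bnn_spec <- function(hidden = 12, scan_range = 2:20, weight_scale = 1,
                     learn_imputation = TRUE,
                     algorithm = c("vi", "hmc"),
                     draws = 1000, warmup = 500, chains = 2,
                     vi_iter = 3000, vi_restarts = 5, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(hidden >= 1, length(scan_range) >= 1, weight_scale > 0)
  structure(list(hidden = as.integer(hidden), scan_range = scan_range,
                 weight_scale = weight_scale,
                 learn_imputation = learn_imputation, algorithm = algorithm,
                 draws = draws, warmup = warmup, chains = chains,
                 vi_iter = vi_iter, vi_restarts = vi_restarts,
                 seed = as.integer(seed), year_effect = FALSE),
            class = "bnn_spec")
}

bnn_layout <- function(design, spec) {
  p <- ncol(design$z); H <- spec$hidden
  cells <- which(design$mask, arr.ind = TRUE)
  miss_cols <- sort(unique(cells[, 2]))
  pm <- length(miss_cols)
  idx <- list(); at <- 0
  take <- function(n) { v <- at + seq_len(n); at <<- at + n; v }
  idx$W1 <- take(p * H); idx$b1 <- take(H)
  idx$w2 <- take(H); idx$b2 <- take(1)
  if (nrow(cells)) {
    idx$zm <- take(nrow(cells))
    if (spec$learn_imputation) { idx$mu_m <- take(pm); idx$log_sig_m <- take(pm) }
  }
  list(idx = idx, n_par = at, p = p, H = H, cells = cells,
       miss_cols = miss_cols,
       cell_group = match(if (nrow(cells)) cells[, 2] else integer(0), miss_cols))
}

bnn_lp_grad <- function(design, spec, layout) {
  y <- design$y
  Z0 <- design$z; Z0[design$mask] <- 0
  n <- nrow(Z0); p <- ncol(Z0); H <- layout$H
  idx <- layout$idx
  cells <- layout$cells; M <- nrow(cells)
  cell_ij <- if (M) cbind(cells[, 1], cells[, 2]) else NULL
  group <- layout$cell_group; pm <- length(layout$miss_cols)
  sw <- spec$weight_scale

  function(theta) {
    W1 <- matrix(theta[idx$W1], p, H)
    b1 <- theta[idx$b1]; w2 <- theta[idx$w2]; b2 <- theta[idx$b2]
    Zf <- Z0
    if (M) {
      zraw <- theta[idx$zm]
      if (spec$learn_imputation) {
        mu_m <- theta[idx$mu_m]; sig_m <- exp(theta[idx$log_sig_m])
      } else { mu_m <- rep(0, pm); sig_m <- rep(1, pm) }
      mu_c <- mu_m[group]; sig_c <- sig_m[group]
      Zf[cell_ij] <- mu_c + sig_c * zraw
    }
    A <- tanh(sweep(Zf %*% W1, 2, b1, "+"))
    eta <- as.vector(A %*% w2) + b2
    pr <- inv_logit(eta)
    r <- y - pr
    lp <- sum(log_bernoulli_logit(y, eta)) -
      0.5 * (sum(W1^2) + sum(b1^2) + sum(w2^2)) / sw^2 -
      0.5 * b2^2 / 2.5^2
    G <- (r %o% w2) * (1 - A^2)
    g <- numeric(length(theta))
    g[idx$W1] <- as.vector(crossprod(Zf, G)) - theta[idx$W1] / sw^2
    g[idx$b1] <- colSums(G) - b1 / sw^2
    g[idx$w2] <- as.vector(crossprod(A, r)) - w2 / sw^2
    g[idx$b2] <- sum(r) - b2 / 2.5^2
    if (M) {
      lp <- lp - 0.5 * sum(zraw^2)
      pull <- rowSums(G[cells[, 1], , drop = FALSE] *
                        W1[cells[, 2], , drop = FALSE])
      g[idx$zm] <- pull * sig_c - zraw
      if (spec$learn_imputation) {
        lp <- lp - 0.5 * sum(mu_m^2) - 0.5 * sum(sig_m^2) +
          sum(theta[idx$log_sig_m])
        g[idx$mu_m] <- rowsum(pull, group)[, 1] - mu_m
        g[idx$log_sig_m] <- rowsum(pull * sig_c * zraw, group)[, 1] -
          sig_m^2 + 1
      }
    }
    list(lp = lp, grad = g)
  }
}

#' Fit the shallow Bayesian neural network
#'
#' @param design an `sw_design`.
#' @param spec a [bnn_spec()].
#' @return object of class `c("sw_bnn", "sw_fit")`.
#' @export
fit_bnn <- function(design, spec = bnn_spec()) {
  stopifnot(inherits(design, "sw_design"))
  layout <- bnn_layout(design, spec)
  lp_grad <- bnn_lp_grad(design, spec, layout)
  set.seed(derive_seed(spec$seed, 7))
  init <- rnorm(layout$n_par, 0, 0.1)
  init[layout$idx$b2] <- logit(min(max(mean(design$y), 0.02), 0.98))
  if (!is.null(layout$idx$zm)) init[layout$idx$zm] <- 0
  res <- run_inference(lp_grad, init, spec)
  structure(list(draws = res$draws, layout = layout, design = design,
                 spec = spec, diagnostics = res$diagnostics, type = "bnn"),
            class = c("sw_bnn", "sw_fit"))
}

#' @export
eta_draws.sw_bnn <- function(fit, design, ...) {
  idx <- fit$layout$idx
  p <- fit$layout$p; H <- fit$layout$H
  S <- nrow(fit$draws)
  Z0 <- design$z; Z0[design$mask] <- 0
  cells <- which(design$mask, arr.ind = TRUE)
  zm_draws <- latent_draws(fit, design)
  eta <- matrix(NA_real_, nrow(Z0), S)
  for (s in seq_len(S)) {
    th <- fit$draws[s, ]
    Zf <- Z0
    if (!is.null(zm_draws)) Zf[cells] <- zm_draws[s, ]
    W1 <- matrix(th[idx$W1], p, H)
    A <- tanh(sweep(Zf %*% W1, 2, th[idx$b1], "+"))
    eta[, s] <- as.vector(A %*% th[idx$w2]) + th[idx$b2]
  }
  eta
}

#' Scan hidden-layer widths by LOO expected log predictive density
#'
#' Fits one network per candidate width and scores each by PSIS-LOO elpd.
#' The selected width is the smallest whose elpd is within one standard
#' error of the best (one-SE rule); widths whose fit fails are logged and
#' excluded.
#'
#' @param design an `sw_design`.
#' @param spec a [bnn_spec()]; `spec$scan_range` gives the widths.
#' @param widths optional override of the scan range.
#' @return list with `table` (width, elpd, se, n_high_k) and `selected`.
#' @export
width_scan <- function(design, spec = bnn_spec(), widths = spec$scan_range) {
  rows <- list()
  for (H in widths) {
    sp <- spec; sp$hidden <- as.integer(H)
    sp$seed <- derive_seed(spec$seed, H)
    res <- tryCatch({
      fit <- fit_bnn(design, sp)
      ll <- pointwise_loglik(fit, design)
      loo <- loo_predictive(ll, predictive_draws(fit, design))
      data.frame(hidden = H, elpd = loo$elpd, se = loo$se,
                 n_high_k = loo$n_high_k)
    }, error = function(e) {
      message(sprintf("width %d failed: %s", H, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("all widths failed")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$hidden), ]
  rownames(tab) <- NULL
  best <- which.max(tab$elpd)
  ok <- tab$elpd >= tab$elpd[best] - tab$se[best]
  list(table = tab, selected = min(tab$hidden[ok]))
}
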