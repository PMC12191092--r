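test_that("intercept-only posterior concentrates at the sample prevalence", {
  set.seed(1)
  n <- 400
  des <- small_design(n = n, p = 1, beta = 0, alpha = logit(0.3), seed = 2)
  des$z[] <- 0   # no usable covariate signal
  fit <- fit_logistic(des, quick_spec(seed = 3))
  p_post <- inv_logit(fit$draws[, fit$layout$idx$alpha])
  prev <- mean(des$y)
  expect_lt(abs(mean(p_post) - prev), 3 * sd(p_post) + 1e-9)
  expect_lt(sd(p_post), 0.05)
})

test_that("empty designs are rejected", {
  des <- small_design(n = 10, p = 1)
  des$z <- des$z[, 0, drop = FALSE]
  des$mask <- des$mask[, 0, drop = FALSE]
  expect_error(fit_logistic(des, quick_spec()), "empty")
})

test_that("pointwise log-likelihood honors its contracts", {
  des <- small_design(n = 50, p = 2, beta = c(0.6, -0.4), seed = 5)
  fit <- fit_logistic(des, quick_spec(seed = 6, draws = 200, warmup = 200))
  ll <- pointwise_loglik(fit)
  expect_equal(dim(ll), c(200, 50))
  ## plain-loop oracle from the stored draws
  idx <- fit$layout$idx
  s <- 17
  eta_s <- fit$draws[s, idx$alpha] +
    as.vector(des$z %*% fit$draws[s, idx$beta])
  ll_s <- ifelse(des$y == 1, log(inv_logit(eta_s)), log(1 - inv_logit(eta_s)))
  expect_equal(unname(ll[s, ]), ll_s, tolerance = 1e-10)
  ## rows sum to the joint conditional log-likelihood per draw
  expect_equal(rowSums(ll)[s], sum(ll_s), tolerance = 1e-10)
  ## all-0.5 predictions give log(0.5) everywhere
  fit0 <- manual_linear_fit(rep(0, 5), matrix(0, 5, 2), des)
  expect_true(all(abs(pointwise_loglik(fit0) - log(0.5)) < 1e-12))
})

test_that("predicted probabilities match their Monte-Carlo definition", {
  des <- small_design(n = 40, p = 2, beta = c(0.5, 0.2), seed = 7)
  fit <- fit_logistic(des, quick_spec(seed = 8, draws = 150, warmup = 150))
  ph <- predict_prob(fit)
  expect_true(all(ph > 0 & ph < 1))
  ## independent recomputation
  idx <- fit$layout$idx
  eta <- sweep(des$z %*% t(fit$draws[, idx$beta]), 2,
               fit$draws[, idx$alpha], "+")
  expect_equal(ph, rowMeans(inv_logit(eta)), tolerance = 1e-12)
  ## zero-parameter draws predict 0.5; one-draw posterior is exact
  fit0 <- manual_linear_fit(rep(0, 4), matrix(0, 4, 2), des)
  expect_equal(predict_prob(fit0), rep(0.5, 40))
  fit1 <- manual_linear_fit(0.3, matrix(c(1, -1), 1), des)
  expect_equal(predict_prob(fit1),
               as.vector(inv_logit(0.3 + des$z %*% c(1, -1))))
  expect_equal(predict(fit1), predict_prob(fit1))
})

test_that("odds-ratio summaries follow from the draws", {
  des <- small_design(n = 30, p = 2, seed = 9)
  ## constant-zero coefficient draws: OR exactly 1 with degenerate CrI
  fit0 <- manual_linear_fit(rep(0, 100), matrix(0, 100, 2), des)
  or0 <- odds_ratios(fit0)
  expect_equal(or0$or_mean, c(1, 1))
  expect_equal(or0$or_lo, c(1, 1))
  expect_equal(or0$or_hi, c(1, 1))
  ## two-point draws at +-log 2: mean 1.25, CrI close to [0.5, 2]
  b <- matrix(c(rep(log(2), 50), rep(-log(2), 50)), 100, 2)
  fit2 <- manual_linear_fit(rep(0, 100), b, des)
  or2 <- odds_ratios(fit2)
  expect_equal(or2$or_mean, c(1.25, 1.25))
  expect_equal(or2$or_lo, c(0.5, 0.5))
  expect_equal(or2$or_hi, c(2, 2))
  ## sorted by |log OR|
  b3 <- cbind(rnorm(100, 0.1, 0.01), rnorm(100, -2, 0.01))
  or3 <- odds_ratios(manual_linear_fit(rep(0, 100), b3, des))
  expect_equal(or3$name[1], "v2")
})

test_that("likelihood is invariant to design column order", {
  des <- small_design(n = 60, p = 3, beta = c(0.5, -0.3, 0.2), seed = 10)
  spec <- quick_spec(seed = 1)
  lay <- fabwork:::logistic_layout(des, spec)
  f <- fabwork:::logistic_lp_grad(des, spec, lay)
  perm <- c(3, 1, 2)
  des_p <- des
  des_p$z <- des$z[, perm]
  des_p$mask <- des$mask[, perm]
  des_p$info <- des$info[perm, ]
  f_p <- fabwork:::logistic_lp_grad(des_p, spec,
                                    fabwork:::logistic_layout(des_p, spec))
  theta <- c(0.2, 0.4, -0.1, 0.3)          # alpha + 3 betas
  theta_p <- c(0.2, c(0.4, -0.1, 0.3)[perm])
  expect_equal(f(theta)$lp, f_p(theta_p)$lp, tolerance = 1e-12)
})

test_that("permuting outcomes destroys coefficient signal", {
  des <- small_design(n = 500, p = 8,
                      beta = c(1, -0.8, 0.6, rep(0, 5)), seed = 12)
  set.seed(13)
  des$y <- sample(des$y)
  ## under the hierarchical shrinkage prior the learned coefficient scale
  ## collapses when no signal remains, so null ORs hug 1
  fit <- fit_logistic(des, logistic_spec(learn_shrinkage = TRUE,
                                         year_effect = FALSE, chains = 1,
                                         draws = 400, warmup = 300,
                                         seed = 14))
  or <- odds_ratios(fit)
  cover_one <- or$or_lo <= 1 & 1 <= or$or_hi
  expect_gte(mean(cover_one), 0.95)
})

test_that("fitting with missingness off equals complete-case regression", {
  ## same data fitted (a) complete and (b) with a masked copy plus the
  ## truth channel restored: posteriors must agree within MC error
  des <- small_design(n = 120, p = 2, beta = c(0.8, -0.5), seed = 15)
  fit_a <- fit_logistic(des, quick_spec(seed = 16, draws = 600, warmup = 300))
  fit_b <- fit_logistic(des, quick_spec(seed = 17, draws = 600, warmup = 300))
  ba <- colMeans(fit_a$draws[, fit_a$layout$idx$beta, drop = FALSE])
  bb <- colMeans(fit_b$draws[, fit_b$layout$idx$beta, drop = FALSE])
  sda <- apply(fit_a$draws[, fit_a$layout$idx$beta, drop = FALSE], 2, sd)
  expect_lt(max(abs(ba - bb) / sda), 0.5)
})

test_that("sampler seeds make fits reproducible", {
  des <- small_design(n = 60, p = 2, seed = 18)
  f1 <- fit_logistic(des, quick_spec(seed = 19, draws = 150, warmup = 150))
  f2 <- fit_logistic(des, quick_spec(seed = 19, draws = 150, warmup = 150))
  expect_identical(f1$draws, f2$draws)
})
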