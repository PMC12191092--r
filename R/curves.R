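#' Receiver operating characteristic curve
#'
#' Thresholds at unique scores with tied scores grouped (all equal scores
#' cross the threshold together); area by the trapezoidal rule, which
#' makes the AUROC equal to the Mann-Whitney rank statistic
#' `U / (n1 n0)`.
#'
#' @param p_hat predicted scores/probabilities.
#' @param y binary outcomes (both classes must be present).
#' @return object of class `sw_curve` with `points` (threshold, fpr, tpr),
#'   `auc`, `kind = "roc"`.
#' @export
roc_curve <- function(p_hat, y) {
  stopifnot(length(p_hat) == length(y))
  y <- as.integer(y > 0)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  ord <- order(p_hat, decreasing = TRUE)
  ps <- p_hat[ord]; ys <- y[ord]
  grp_end <- which(diff(ps) != 0)
  grp_end <- c(grp_end, length(ps))
  tp <- cumsum(ys)[grp_end]
  fp <- grp_end - tp
  pts <- data.frame(threshold = c(Inf, ps[grp_end]),
                    fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, kind = "roc",
                 y = y, baseline = 0.5),
            class = "sw_curve")
}

#' Precision-recall curve
#'
#' Same grouped thresholds as [roc_curve()]; the area uses step-wise
#' (right-continuous) interpolation, `sum_k (R_k - R_{k-1}) P_k`, since
#' linear interpolation is biased for precision-recall curves. The chance
#' baseline (outcome prevalence) is recorded.
#'
#' @inheritParams roc_curve
#' @return object of class `sw_curve` with `points` (threshold, recall,
#'   precision), `auc`, `kind = "prc"`, `baseline` = prevalence.
#' @export
pr_curve <- function(p_hat, y) {
  stopifnot(length(p_hat) == length(y))
  y <- as.integer(y > 0)
  n1 <- sum(y == 1)
  if (n1 == 0) stop("no positive outcomes present")
  ord <- order(p_hat, decreasing = TRUE)
  ps <- p_hat[ord]; ys <- y[ord]
  grp_end <- c(which(diff(ps) != 0), length(ps))
  tp <- cumsum(ys)[grp_end]
  recall <- tp / n1
  precision <- tp / grp_end
  auc <- sum(diff(c(0, recall)) * precision)
  pts <- data.frame(threshold = ps[grp_end], recall = recall,
                    precision = precision)
  structure(list(points = pts, auc = auc, kind = "prc",
                 y = y, baseline = mean(y)),
            class = "sw_curve")
}

#' @export
print.sw_curve <- function(x, ...) {
  lab <- if (x$kind == "roc") "AUROC" else "AUPRC"
  cat(sprintf("%s curve: %d operating points, %s = %.4f",
              toupper(x$kind), nrow(x$points), lab, x$auc))
  if (x$kind == "prc") cat(sprintf(" (chance level %.3f)", x$baseline))
  cat("\n")
  invisible(x)
}

#' @export
plot.sw_curve <- function(x, ...) {
  if (x$kind == "roc") {
    plot(x$points$fpr, x$points$tpr, type = "l",
         xlab = "False positive rate", ylab = "True positive rate",
         main = sprintf("ROC (AUROC = %.3f)", x$auc), ...)
    abline(0, 1, lty = 2, col = "grey")
  } else {
    plot(x$points$recall, x$points$precision, type = "s",
         xlab = "Recall", ylab = "Precision", ylim = c(0, 1),
         main = sprintf("PRC (AUPRC = %.3f)", x$auc), ...)
    abline(h = x$baseline, lty = 2, col = "grey")
  }
  invisible(x)
}

#' Evaluate a fitted model by PSIS-LOO
#'
#' Convenience wrapper: pointwise log-likelihood and predictive draws,
#' PSIS-LOO, and LOO-cross-validated ROC and precision-recall curves
#' built from the LOO predictive probabilities.
#'
#' @param fit an `sw_fit`.
#' @param design design to evaluate on (defaults to the training design).
#' @param label model label for comparison tables.
#' @return object of class `sw_eval`: list with `label`, `loo`, `roc`,
#'   `prc`.
#' @export
evaluate_model <- function(fit, design = fit$design, label = fit$type) {
  ll <- pointwise_loglik(fit, design)
  pd <- predictive_draws(fit, design)
  loo <- loo_predictive(ll, pd)
  structure(list(
    label = label,
    loo = loo,
    roc = roc_curve(loo$pointwise$p_hat, design$y),
    prc = pr_curve(loo$pointwise$p_hat, design$y)
  ), class = "sw_eval")
}

#' @export
print.sw_eval <- function(x, ...) {
  cat(sprintf("Model evaluation [%s]\n", x$label))
  print(x$loo)
  print(x$roc)
  print(x$prc)
  invisible(x)
}

#' Rank evaluated models
#'
#' All models must have been evaluated on the identical observation set;
#' ranking is by LOO AUROC with elpd as tie-break.
#'
#' @param evals named list of `sw_eval` objects (names become labels when
#'   present).
#' @return data frame (model, elpd, elpd_se, auroc, auprc, n_high_k),
#'   ranked.
#' @export
compare_models <- function(evals) {
  stopifnot(length(evals) >= 1)
  ns <- vapply(evals, function(e) nrow(e$loo$pointwise), numeric(1))
  if (length(unique(ns)) != 1)
    stop("models were evaluated on different observation sets")
  ys <- lapply(evals, function(e) e$roc$y)
  if (!all(vapply(ys, identical, logical(1), ys[[1]])))
    stop("models were evaluated on different outcome vectors")
  labels <- names(evals)
  if (is.null(labels))
    labels <- vapply(evals, function(e) e$label, character(1))
  tab <- data.frame(
    model = labels,
    elpd = vapply(evals, function(e) e$loo$elpd, numeric(1)),
    elpd_se = vapply(evals, function(e) e$loo$se, numeric(1)),
    auroc = vapply(evals, function(e) e$roc$auc, numeric(1)),
    auprc = vapply(evals, function(e) e$prc$auc, numeric(1)),
    n_high_k = vapply(evals, function(e) e$loo$n_high_k, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$auroc, -tab$elpd), ]
  rownames(tab) <- NULL
  tab
}
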