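# External-validation metrics (r2_pred, through-origin regressions, Roy's
# r2_m, RMSEP), the five-condition acceptability gate, and the robustness
# battery (y-randomization, bootstrap, repeated k-fold cross-validation).

#' External predictive coefficient r2_pred
#'
#' `1 - PRESS / SD`, where PRESS sums squared test-set residuals and SD sums
#' squared deviations of the observed test activities from the mean activity
#' of the *training* compounds.
#'
#' @param observed observed test-set activities.
#' @param predicted model-predicted test-set activities.
#' @param train_mean mean observed activity of the training set.
#' @return r2_pred.
#' @export
r2_pred <- function(observed, predicted, train_mean) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  sdsum <- sum((observed - train_mean)^2)
  if (sdsum == 0) stop("SD = 0: test activities all equal the training mean")
  1 - sum((observed - predicted)^2) / sdsum
}

#' Through-origin regressions of the test set
#'
#' Axis convention follows the acceptability gate's slope definition:
#' predicted on X, observed on Y, intercept 0, giving
#' `k = sum(y*yhat) / sum(yhat^2)` and the through-origin determination
#' coefficient `r2_o = 1 - sum((y - k*yhat)^2) / sum((y - mean(y))^2)`.
#' The primed variants swap the axes. `r2_test` is the ordinary squared
#' Pearson correlation.
#'
#' @param observed,predicted test-set activities.
#' @return list with `k`, `k_prime`, `r2_o`, `r2_o_prime`, `r2_test`.
#' @export
origin_regressions <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  if (all(predicted == 0)) stop("all predictions zero: slope undefined")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("degenerate (constant) activities")
  k <- sum(observed * predicted) / sum(predicted^2)
  kp <- sum(observed * predicted) / sum(observed^2)
  r2o <- 1 - sum((observed - k * predicted)^2) /
             sum((observed - mean(observed))^2)
  r2op <- 1 - sum((predicted - kp * observed)^2) /
              sum((predicted - mean(predicted))^2)
  list(k = k, k_prime = kp, r2_o = r2o, r2_o_prime = r2op,
       r2_test = cor(observed, predicted)^2)
}

#' Roy's r2_m metric
#'
#' `r2_m = r2_test * (1 - sqrt(r2_test - r2_o))`, penalizing the divergence
#' between the correlations with and without intercept.
#'
#' @param r2_test squared Pearson correlation on the test set.
#' @param r2_o through-origin determination coefficient (same axes as the
#'   gate's k).
#' @return r2_m.
#' @export
rm2 <- function(r2_test, r2_o) {
  if (r2_o > r2_test + 1e-12)
    stop("invalid pair: r2_o exceeds r2_test")
  r2_test * (1 - sqrt(max(0, r2_test - r2_o)))
}

#' Root-mean-squared error of prediction
#' @param observed,predicted paired activities.
#' @return RMSEP.
#' @export
rmsep <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  stopifnot(length(observed) >= 1L)
  sqrt(mean((observed - predicted)^2))
}

#' Five-condition acceptability gate
#'
#' An externally validated model is acceptable when all of:
#' (1) `r2_pred > 0.5`; (2) `r2_test > 0.6`;
#' (3) `(r2_test - r2_o)/r2_test < 0.1`; (4) `0.85 <= k <= 1.15`;
#' (5) `r2_m > 0.5`.
#'
#' @param r2_pred,r2_test,r2_o,k,r2_m the five inputs (see the metric
#'   functions).
#' @return list with `conditions` (named logical vector) and `verdict`
#'   (logical AND).
#' @export
tropsha_gate <- function(r2_pred, r2_test, r2_o, k, r2_m) {
  conditions <- c(
    r2_pred_gt_0.5 = r2_pred > 0.5,
    r2_test_gt_0.6 = r2_test > 0.6,
    origin_degradation_lt_0.1 = (r2_test - r2_o) / r2_test < 0.1,
    k_in_0.85_1.15 = k >= 0.85 && k <= 1.15,
    r2_m_gt_0.5 = r2_m > 0.5
  )
  list(conditions = conditions, verdict = all(conditions))
}

#' Full external-validation report
#'
#' Computes every test-set metric, both axis conventions of the
#' through-origin statistics, RMSEP and the acceptability gate in one call.
#'
#' @param observed,predicted test-set activities.
#' @param train_observed training-set observed activities (for the r2_pred
#'   reference mean).
#' @return `qsar_validation` list: `r2_pred`, `r2_test`, `r2_o`,
#'   `r2_o_prime`, `k`, `k_prime`, `degradation`, `r2_m`, `r2_m_prime`,
#'   `rmsep`, `n_test`, `gate`.
#' @export
validate_external <- function(observed, predicted, train_observed) {
  orr <- origin_regressions(observed, predicted)
  rp <- r2_pred(observed, predicted, mean(train_observed))
  r2m <- rm2(orr$r2_test, min(orr$r2_o, orr$r2_test))
  r2mp <- rm2(orr$r2_test, min(orr$r2_o_prime, orr$r2_test))
  structure(list(
    r2_pred = rp, r2_test = orr$r2_test, r2_o = orr$r2_o,
    r2_o_prime = orr$r2_o_prime, k = orr$k, k_prime = orr$k_prime,
    degradation = (orr$r2_test - orr$r2_o) / orr$r2_test,
    r2_m = r2m, r2_m_prime = r2mp,
    rmsep = rmsep(observed, predicted), n_test = length(observed),
    gate = tropsha_gate(rp, orr$r2_test, orr$r2_o, orr$k, r2m)
  ), class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  cat(sprintf(
    "External validation (n_test = %d)\n  r2_pred %.3f | r2_test %.3f | (r2_test-r2_o)/r2_test %.3f | k %.3f | r2_m %.3f | RMSEP %.3f\n  gate: %s\n",
    x$n_test, x$r2_pred, x$r2_test, x$degradation, x$k, x$r2_m, x$rmsep,
    if (x$gate$verdict) "acceptable" else
      paste("REJECTED:", paste(names(which(!x$gate$conditions)), collapse = ", "))))
  invisible(x)
}

#' y-randomization test
#'
#' Permutes the response `runs` times with a seeded generator, re-selects
#' the component count per permutation (conservative), and records the LOO
#' q2 of each scrambled model. A real model's q2 should exceed all of them.
#'
#' @param X,y training data.
#' @param runs number of permutations (published study setting: 50).
#' @param seed RNG seed.
#' @param max_comp component-scan bound passed to [select_components()].
#' @return list with `q2` (length `runs`), `range`, `seed`.
#' @export
y_randomization <- function(X, y, runs = 50L, seed = 1L, max_comp = NULL) {
  stopifnot(runs >= 0L)
  if (runs == 0L) return(list(q2 = numeric(), range = c(NA_real_, NA_real_),
                              seed = seed))
  set.seed(seed)
  perms <- replicate(runs, sample(length(y)), simplify = FALSE)
  q2s <- vapply(perms, function(p)
    select_components(X, y[p], max_comp = max_comp)$q2, numeric(1))
  list(q2 = q2s, range = range(q2s), seed = seed)
}

#' Bootstrap r2 and SEE
#'
#' Resamples compounds with replacement, refits at a fixed component count,
#' and averages the non-cross-validated r2 and SEE over the resamples.
#' Resamples with fewer than `ncomp + 2` distinct compounds are redrawn.
#'
#' @param X,y training data.
#' @param ncomp fixed component count (the selected model's).
#' @param runs number of resamples (published study setting: 100).
#' @param seed RNG seed.
#' @return list with `r2_bs`, `see_bs`, per-run vectors, `seed`.
#' @export
bootstrap_r2 <- function(X, y, ncomp, runs = 100L, seed = 1L) {
  stopifnot(runs >= 1L)
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  r2s <- numeric(runs); sees <- numeric(runs)
  for (b in seq_len(runs)) {
    repeat {
      idx <- sample(n, n, replace = TRUE)
      if (length(unique(idx)) >= ncomp + 2L) break
    }
    fit <- fit_pls(X[idx, , drop = FALSE], y[idx], ncomp)
    st <- final_stats(fit)
    r2s[b] <- st$r2_ncv; sees[b] <- st$see
  }
  list(r2_bs = mean(r2s), see_bs = mean(sees), r2 = r2s, see = sees,
       seed = seed)
}

#' Repeated k-fold cross-validation
#'
#' Grouped cross-validation: per repeat, compounds are randomly assigned to
#' `folds` balanced groups; each group is predicted by a model trained on the
#' rest, and the repeat's `r2_cv = 1 - PRESS / sum((y - mean(y))^2)`. With
#' `folds = n` this is exactly the LOO q2.
#'
#' @param X,y training data.
#' @param ncomp fixed component count.
#' @param folds number of groups (published study setting: 10).
#' @param repeats number of repeats (published study setting: 10).
#' @param seed RNG seed.
#' @return list with `r2_cv_mean`, per-repeat `r2_cv`, `seed`.
#' @export
repeated_kfold_q2 <- function(X, y, ncomp, folds = 10L, repeats = 10L,
                              seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds > n) stop("more folds than compounds")
  stopifnot(folds >= 2L, repeats >= 1L)
  ss <- sum((y - mean(y))^2)
  set.seed(seed)
  r2s <- numeric(repeats)
  for (r in seq_len(repeats)) {
    assignment <- sample(rep(seq_len(folds), length.out = n))
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      hold <- assignment == f
      fit <- fit_pls(X[!hold, , drop = FALSE], y[!hold], ncomp)
      pred[hold] <- predict(fit, X[hold, , drop = FALSE])
    }
    r2s[r] <- 1 - sum((y - pred)^2) / ss
  }
  list(r2_cv_mean = mean(r2s), r2_cv = r2s, seed = seed)
}
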