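# PLS1 regression by NIPALS, leave-one-out cross-validation, component
# selection and the SYBYL-style training statistics (q2/SEP, r2_ncv/SEE/F,
# per-field relative contributions, StDev*Coeff grids).

#' Fit a PLS regression model
#'
#' NIPALS partial least squares with a single response. X is column-centered
#' internally and y is centered, never scaled (field blocks arrive already
#' block-scaled from [assemble_block()]). The NIPALS inner loop uses
#' convergence 1e-10 with at most 500 iterations per component; for a single
#' response this converges immediately and the fit is fully deterministic.
#'
#' @param X predictor matrix (compounds x columns).
#' @param y numeric response (e.g. pIC50).
#' @param ncomp number of latent components.
#' @return `qsar_pls` object with weights/loadings/scores, a coefficient
#'   matrix `coefs` (column k = regression vector using k components),
#'   `coef`/`intercept` for the full model, and `fitted` values.
#' @export
fit_pls <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n < ncomp + 2L) stop("need at least ncomp + 2 rows")
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(n-1, ncol(X))")
  xmean <- colMeans(X); ymean <- mean(y)
  Xc <- sweep(X, 2, xmean); yc <- y - ymean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); qvec <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("component ", a, " exceeds the rank of X")
    w <- w / nw
    for (iter in seq_len(500L)) {          # NIPALS loop; PLS1 converges at once
      tt <- Xd %*% w
      q <- sum(yd * tt) / sum(tt * tt)
      u <- yd / q
      w_new <- crossprod(Xd, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < 1e-10) { w <- w_new; break }
      w <- w_new
    }
    tt <- Xd %*% w
    tt2 <- sum(tt * tt)
    pvec <- crossprod(Xd, tt) / tt2
    qvec[a] <- sum(yd * tt) / tt2
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- tt
    Xd <- Xd - tt %*% t(pvec)
    yd <- yd - tt * qvec[a]
  }
  # coefficients on the original (uncentered) columns, for every 1..ncomp
  R <- W %*% solve(t(P) %*% W)             # ncomp small: cheap
  coefs <- sapply(seq_len(ncomp), function(k)
    R[, seq_len(k), drop = FALSE] %*% qvec[seq_len(k)])
  coefs <- matrix(coefs, nrow = p)
  coef <- coefs[, ncomp]
  intercept <- ymean - sum(xmean * coef)
  fitted <- as.vector(X %*% coef) + intercept
  structure(list(ncomp = ncomp, weights = W, loadings = P, scores = Tm,
                 q = qvec, coefs = coefs, coef = coef, intercept = intercept,
                 xmean = xmean, ymean = ymean, fitted = fitted, y = y),
            class = "qsar_pls")
}

#' @export
print.qsar_pls <- function(x, ...) {
  cat(sprintf("<PLS model: %d components, %d columns, n = %d>\n",
              x$ncomp, length(x$coef), length(x$y)))
  invisible(x)
}

#' Predict from a PLS model
#' @param object a `qsar_pls`.
#' @param newdata matrix with the same columns as the training block.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.qsar_pls <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as.matrix(newdata)
  k <- ncomp %||% object$ncomp
  stopifnot(k >= 1L, k <= object$ncomp)
  b <- object$coefs[, k]
  intercept <- object$ymean - sum(object$xmean * b)
  as.vector(newdata %*% b) + intercept
}

#' Leave-one-out cross-validated predictions
#'
#' Each compound is predicted by a model refit without it (a literal n-refit;
#' no shortcut formulas), for every component count `1..max_comp` in one
#' pass.
#'
#' @param X,y training data.
#' @param max_comp maximum components.
#' @return n x max_comp matrix of LOO predictions.
#' @export
loo_predictions <- function(X, y, max_comp) {
  X <- as.matrix(X); n <- nrow(X)
  stopifnot(n >= 3L, max_comp >= 1L)
  out <- matrix(NA_real_, n, max_comp)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    # cap by the achievable rank of the centered fold (exactly collinear
    # data would otherwise abort the scan); higher counts repeat the last
    # achievable prediction
    ki <- min(max_comp, qr(sweep(Xi, 2, colMeans(Xi)))$rank, nrow(Xi) - 1L)
    fit <- fit_pls(Xi, y[-i], ki)
    for (k in seq_len(max_comp))
      out[i, k] <- predict(fit, X[i, , drop = FALSE], ncomp = min(k, ki))
  }
  out
}

#' Leave-one-out q2 and SEP
#'
#' `q2 = 1 - PRESS / sum((y - mean(y))^2)` with each prediction from a model
#' excluding that compound; `SEP = sqrt(PRESS / (n - ncomp - 1))` (SYBYL
#' degrees-of-freedom convention).
#'
#' @param X,y training data.
#' @param ncomp components.
#' @return list with `q2`, `sep`, `press` and the LOO `predictions`.
#' @export
loo_q2 <- function(X, y, ncomp) {
  y <- as.numeric(y)
  if (sd(y) == 0) stop("constant response: q2 undefined")
  pred <- loo_predictions(X, y, ncomp)[, ncomp]
  press <- sum((y - pred)^2)
  ss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / ss,
       sep = sqrt(press / (length(y) - ncomp - 1)),
       press = press, predictions = pred)
}

#' Select the number of PLS components by LOO q2
#'
#' Scans `1..max_comp` (one LOO pass) and returns the component count
#' maximizing q2, ties broken toward fewer components.
#'
#' @param X,y training data.
#' @param max_comp upper bound; default `min(15, floor(n/3), n-2, ncol(X))`.
#' @return list with `ncomp`, `q2`, `sep`, and the full `q2_scan`.
#' @export
select_components <- function(X, y, max_comp = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (sd(y) == 0) stop("constant response: q2 undefined")
  cap <- min(15L, max(1L, floor(n / 3)), n - 2L, ncol(X))
  max_comp <- max_comp %||% cap
  stopifnot(max_comp >= 1L)
  max_comp <- min(max_comp, n - 2L, ncol(X))
  pred <- loo_predictions(X, y, max_comp)
  ss <- sum((y - mean(y))^2)
  q2s <- 1 - colSums((y - pred)^2) / ss
  best <- which.max(q2s)                    # which.max takes the first maximum
  list(ncomp = as.integer(best), q2 = q2s[best],
       sep = sqrt(sum((y - pred[, best])^2) / (n - best - 1)),
       q2_scan = q2s)
}

#' Non-cross-validated training statistics
#'
#' `r2_ncv` is the squared Pearson correlation of fitted vs observed;
#' `SEE = sqrt(RSS / (n - PCs - 1))`;
#' `F = (r2/PCs) / ((1 - r2)/(n - PCs - 1))`. A numerically perfect fit
#' yields `F = Inf` (flagged, not an error).
#'
#' @param model fitted `qsar_pls`.
#' @param X,y training data (default: the data stored in the model).
#' @return list with `r2_ncv`, `see`, `f`, `n`, `ncomp`.
#' @export
final_stats <- function(model, X = NULL, y = NULL) {
  y <- y %||% model$y
  fit <- if (is.null(X)) model$fitted else predict(model, X)
  n <- length(y); k <- model$ncomp
  if (n <= k + 1L) stop("need n > ncomp + 1 for SEE/F")
  r2 <- cor(fit, y)^2
  see <- sqrt(sum((y - fit)^2) / (n - k - 1))
  f <- if (1 - r2 < .Machine$double.eps) Inf
       else (r2 / k) / ((1 - r2) / (n - k - 1))
  list(r2_ncv = r2, see = see, f = f, n = n, ncomp = k)
}

#' Per-field relative contributions
#'
#' SYBYL-style field contributions: for field kind k,
#' `sum_{j in k} |b_j| * sd_j`, normalized to sum to 1 over the kinds.
#'
#' @param model fitted `qsar_pls` on the block's `X`.
#' @param block the `qsar_block` the model was fitted on.
#' @return named numeric vector (one entry per field kind, sums to 1).
#' @export
field_contributions <- function(model, block) {
  sds <- apply(block$X, 2, sd)
  w <- abs(model$coef) * sds
  contrib <- tapply(w, block$meta$field, sum)
  contrib <- contrib[block$fields[block$fields %in% names(contrib)]]
  total <- sum(contrib)
  if (total == 0) stop("all coefficients zero: contributions undefined")
  as.vector(contrib / total) -> out
  setNames(out, names(contrib))
}

#' StDev*Coeff lattice grids
#'
#' Maps `sd_j * b_j` back onto the lattice, one value vector per field kind.
#' Columns dropped by the minimum-sigma filter get the fill value `NA`
#' (recorded in the result).
#'
#' @param model fitted `qsar_pls`.
#' @param block the `qsar_block` it was fitted on.
#' @return named list (per field kind) of numeric vectors over all lattice
#'   points, with attribute `fill = NA`; plus attribute `grid`.
#' @export
stdev_coeff_grid <- function(model, block) {
  sds <- apply(block$X, 2, sd)
  vals <- sds * model$coef
  np <- n_points(block$grid)
  out <- lapply(block$fields, function(k) {
    v <- rep(NA_real_, np)
    sel <- block$meta$field == k
    v[block$meta$point[sel]] <- vals[sel]
    v
  })
  names(out) <- block$fields
  attr(out, "fill") <- NA_real_
  attr(out, "grid") <- block$grid
  out
}
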