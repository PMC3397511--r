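# Shared fixtures and independent oracles for the test suite.

# ---- independent PLS oracle -------------------------------------------------
# PLS1 with k components equals least squares restricted to the Krylov
# subspace span{X'y, (X'X)X'y, ..., (X'X)^(k-1) X'y} of the centered data.
# This characterization shares no code with the NIPALS path in R/pls.R.
pls_krylov_oracle <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  v <- crossprod(Xc, yc)
  K <- matrix(0, ncol(Xc), ncomp)
  for (k in seq_len(ncomp)) {
    K[, k] <- v
    v <- crossprod(Xc, Xc %*% v)
  }
  Z <- Xc %*% K
  a <- qr.coef(qr(Z), yc)
  a[is.na(a)] <- 0
  b <- as.vector(K %*% a)
  list(coef = b, intercept = ym - sum(xm * b),
       fitted = as.vector(X %*% b) + ym - sum(xm * b))
}

# naive LOO built on the oracle (independent of loo_predictions)
loo_krylov_oracle <- function(X, y, ncomp) {
  vapply(seq_len(nrow(X)), function(i) {
    fit <- pls_krylov_oracle(X[-i, , drop = FALSE], y[-i], ncomp)
    sum(X[i, ] * fit$coef) + fit$intercept
  }, numeric(1))
}

# ---- tiny geometric fixtures ------------------------------------------------
toy_molecule <- function(id = "toy", xyz, elements = NULL, charges = NULL,
                         ...) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  molecule(id,
           data.frame(element = elements %||% rep("C", n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = charges %||% rep(0, n)),
           ...)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# methane with explicit bonds, for native charge tests
methane <- function() {
  d <- 1.09 / sqrt(3)
  molecule("methane",
           data.frame(element = c("C", "H", "H", "H", "H"),
                      x = c(0,  d,  d, -d, -d),
                      y = c(0,  d, -d,  d, -d),
                      z = c(0,  d, -d, -d,  d),
                      charge = 0),
           bonds = data.frame(from = 1L, to = 2:5, order = 1))
}

# ---- session-cached expensive fixtures -------------------------------------
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the full packaged series, built and aligned once per test session
full_series_aligned <- function() {
  cached("full_series_aligned", {
    b <- build_thiourea_series()
    list(aligned = scaffold_align(b$set, "70"), activity = b$activity)
  })
}

# a small synthetic benchmark shared across tests
small_synth <- function() {
  cached("small_synth",
         generate_set(synthetic_spec(n_compounds = 30, seed = 11)))
}
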