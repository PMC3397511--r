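# PLS engine: NIPALS fit, LOO cross-validation, component selection,
# training statistics, field contributions and StDev*Coeff back-projection.

test_that("exact relations: single-column fit, OLS at full rank, weights", {
  set.seed(41)
  # y exactly linear in one column
  x <- rnorm(10)
  X <- cbind(x, 0)                          # second column constant
  y <- 2 + 3 * x
  fit <- fit_pls(X, y, 1)
  expect_equal(fit$fitted, y, tolerance = 1e-10)
  expect_equal(final_stats(fit)$r2_ncv, 1, tolerance = 1e-10)

  # ncomp = rank(X): PLS equals ordinary least squares (normal equations)
  X <- matrix(rnorm(30 * 4), 30); y <- rnorm(30)
  fit <- fit_pls(X, y, 4)
  Xi <- cbind(1, X)
  beta_ols <- solve(crossprod(Xi), crossprod(Xi, y))
  expect_equal(fit$fitted, as.vector(Xi %*% beta_ols), tolerance = 1e-8)
  expect_equal(unname(fit$coef), unname(beta_ols[-1]), tolerance = 1e-8)

  # orthonormal columns: first-component weights proportional to X'y
  Q <- qr.Q(qr(matrix(rnorm(20 * 5), 20)))
  y2 <- rnorm(20)
  Qc <- sweep(Q, 2, colMeans(Q)); yc <- y2 - mean(y2)
  w_expected <- crossprod(Qc, yc)
  w_expected <- w_expected / sqrt(sum(w_expected^2))
  fit2 <- fit_pls(Q, y2, 1)
  expect_equal(as.vector(fit2$weights), as.vector(w_expected),
               tolerance = 1e-10)
})

test_that("NIPALS equals the Krylov-subspace oracle", {
  set.seed(7)
  for (trial in 1:4) {
    X <- matrix(rnorm(25 * 10), 25); y <- rnorm(25)
    for (k in 1:5) {
      oracle <- pls_krylov_oracle(X, y, k)
      fit <- fit_pls(X, y, k)
      expect_equal(fit$fitted, oracle$fitted, tolerance = 1e-8)
      expect_equal(predict(fit, X, ncomp = k), oracle$fitted,
                   tolerance = 1e-8)
    }
  }
})

test_that("fit_pls rejects impossible component counts", {
  X <- matrix(rnorm(12), 6)
  expect_error(fit_pls(X, rnorm(6), 5), "ncomp")
  # rank-deficient: duplicated column, ncomp beyond rank
  X2 <- cbind(1:8, 2 * (1:8))
  expect_error(fit_pls(X2, rnorm(8), 2), "rank")
})

test_that("LOO predictions equal brute-force refits and the toy enumeration", {
  X <- matrix(c(1, 2, 3, 4,
                1, 0, 2, 1), ncol = 2)
  y <- c(1, 2, 3, 4)
  # explicit 4-fold enumeration with the independent oracle
  oracle_pred <- loo_krylov_oracle(X, y, 1)
  got <- loo_q2(X, y, 1)
  expect_equal(got$predictions, oracle_pred, tolerance = 1e-10)
  press <- sum((y - oracle_pred)^2)
  expect_equal(got$q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(got$sep, sqrt(press / (4 - 1 - 1)), tolerance = 1e-12)

  # larger random case, all component counts
  set.seed(13)
  X <- matrix(rnorm(15 * 6), 15); y <- rnorm(15)
  engine <- loo_predictions(X, y, 3)
  for (k in 1:3)
    expect_equal(engine[, k], loo_krylov_oracle(X, y, k), tolerance = 1e-8)

  # perfect LOO predictions give q2 = 1
  xlin <- rnorm(12); ylin <- 1 + 2 * xlin
  expect_equal(loo_q2(cbind(xlin), ylin, 1)$q2, 1, tolerance = 1e-8)
  expect_error(loo_q2(X, rep(1, 15), 1), "constant")
})

test_that("component selection finds planted dimensionality", {
  set.seed(23)
  # pure 1-factor data (exactly rank one): later components cannot improve
  # and the tie breaks toward fewer
  t1 <- rnorm(30)
  X <- outer(t1, rnorm(8))
  y <- t1
  expect_identical(select_components(X, y, max_comp = 5)$ncomp, 1L)

  # planted 3-latent-factor data, low noise
  Tm <- matrix(rnorm(120 * 3), 120)
  P <- matrix(rnorm(30 * 3), ncol = 3)
  X3 <- Tm %*% t(P) + matrix(rnorm(120 * 30, sd = 0.02), 120)
  y3 <- Tm %*% c(1, -1, 0.5) + rnorm(120, sd = 0.02)
  expect_identical(select_components(X3, y3, max_comp = 6)$ncomp, 3L)

  # monotone q2 up to the cap selects the cap
  sel <- select_components(X3, y3, max_comp = 3)
  expect_identical(sel$ncomp, 3L)
})

test_that("final_stats formulas and overflow sentinel", {
  # toy residuals: n = 4, PCs = 1, residuals 0.1/-0.1/0.2/-0.2
  x <- c(1, 2, 3, 4)
  y_fit <- 2 * x
  y <- y_fit + c(0.1, -0.1, 0.2, -0.2)
  model <- list(ncomp = 1L, fitted = y_fit, y = y)
  class(model) <- "qsar_pls"
  st <- final_stats(model)
  expect_equal(st$see, sqrt(0.1 / 2), tolerance = 1e-12)
  expect_equal(st$f, (st$r2_ncv / 1) / ((1 - st$r2_ncv) / 2), tolerance = 1e-12)

  model$fitted <- y                          # perfect fit
  st2 <- final_stats(model)
  expect_identical(st2$f, Inf)
  expect_equal(st2$r2_ncv, 1)
  expect_equal(st2$see, 0)

  model$y <- y[1:2]
  expect_error(final_stats(list(ncomp = 3L, fitted = y[1:2], y = y[1:2])))
})

test_that("q2 never exceeds r2_ncv on the same data", {
  set.seed(77)
  for (trial in 1:5) {
    X <- matrix(rnorm(20 * 12), 20)
    y <- X[, 1] - X[, 3] + rnorm(20, sd = 0.5)
    for (k in c(1, 3)) {
      fit <- fit_pls(X, y, k)
      expect_lte(loo_q2(X, y, k)$q2, final_stats(fit)$r2_ncv + 1e-12)
    }
  }
})

test_that("field contributions: single field, symmetry, construction", {
  gen <- small_synth()
  blk <- gen$block
  y <- gen$activity$pIC50
  fit <- fit_pls(blk$X, y, 3)

  # single-field block
  sel_s <- blk$meta$field == "S"
  blk_s <- blk; blk_s$X <- blk$X[, sel_s]; blk_s$meta <- blk$meta[sel_s, ]
  blk_s$fields <- "S"
  fit_s <- fit_pls(blk_s$X, y, 3)
  expect_equal(unname(field_contributions(fit_s, blk_s)), 1)

  # duplicated field halves exactly
  blk_d <- blk_s
  blk_d$X <- cbind(blk_s$X, blk_s$X)
  blk_d$meta <- rbind(blk_s$meta,
                      within(blk_s$meta, field <- "E"))
  blk_d$fields <- c("S", "E")
  fit_d <- fit_pls(blk_d$X, y, 3)
  expect_equal(unname(field_contributions(fit_d, blk_d)), c(0.5, 0.5),
               tolerance = 1e-8)

  # full block: non-negative, sums to one
  contrib <- field_contributions(fit, blk)
  expect_true(all(contrib >= 0))
  expect_equal(sum(contrib), 1, tolerance = 1e-12)
})

test_that("StDev*Coeff back-projection: locality and linearity", {
  gen <- small_synth()
  blk <- gen$block
  np <- n_points(blk$grid)
  # zero-coefficient model maps to an all-zero (or NA) grid
  fake <- list(coef = rep(0, ncol(blk$X)))
  sc0 <- stdev_coeff_grid(fake, blk)
  expect_true(all(unlist(sc0) == 0 | is.na(unlist(sc0))))
  expect_identical(length(sc0$S), np)

  # single nonzero coefficient -> exactly one nonzero voxel at its index
  fake$coef[5] <- 2
  sc1 <- stdev_coeff_grid(fake, blk)
  k5 <- blk$meta$field[5]; p5 <- blk$meta$point[5]
  nonzero <- which(sc1[[k5]] != 0)
  expect_identical(nonzero, p5)
  expect_equal(sc1[[k5]][p5], 2 * sd(blk$X[, 5]), tolerance = 1e-12)

  # doubling a column's spread doubles its voxel value
  blk2 <- blk; blk2$X[, 5] <- 2 * blk2$X[, 5]
  sc2 <- stdev_coeff_grid(fake, blk2)
  expect_equal(sc2[[k5]][p5], 2 * sc1[[k5]][p5], tolerance = 1e-12)
})

test_that("adding a pure-noise column barely changes the fit", {
  set.seed(99)
  gen <- small_synth()
  X <- gen$block$X; y <- gen$activity$pIC50
  fit <- fit_pls(X, y, 3)
  Xn <- cbind(X, noise = rnorm(nrow(X), sd = 0.01))
  fitn <- fit_pls(Xn, y, 3)
  expect_lt(max(abs(fit$fitted - fitn$fitted)), 0.05)
})
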