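test_that("Bartlett sphericity matches its closed form and df rule", {
  expect_equal(bartlett_sphericity(diag(5), 100)$statistic, 0)
  expect_equal(bartlett_sphericity(diag(5), 100)$p.value, 1)
  expect_equal(bartlett_sphericity(diag(8), 276)$df, 28)
  expect_equal(bartlett_sphericity(diag(4), 277)$df, 6)

  R2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  b <- bartlett_sphericity(R2, 100)
  expect_equal(b$statistic, -97.5 * log(0.75), tolerance = 1e-12)

  # invariance to variable reordering
  R4 <- withr::with_seed(3, stats::cor(matrix(rnorm(200 * 4), 200, 4)))
  perm <- c(3, 1, 4, 2)
  expect_equal(bartlett_sphericity(R4, 200)$statistic,
               bartlett_sphericity(R4[perm, perm], 200)$statistic,
               tolerance = 1e-10)
  expect_error(bartlett_sphericity(matrix(c(1, 1, 1, 1), 2, 2), 50),
               "singular")
})

test_that("KMO equals 0.5 for every two-variable input and matches partial correlations", {
  for (r in c(-0.9, -0.3, 0.1, 0.5, 0.9)) {
    R <- matrix(c(1, r, r, 1), 2, 2)
    expect_equal(kmo(R)$overall, 0.5)
  }
  # 3x3 oracle: anti-image partials from the closed-form first-order
  # partial correlation r_ij.k
  R <- matrix(c(1, 0.4, 0.2,
                0.4, 1, 0.5,
                0.2, 0.5, 1), 3, 3)
  pc <- function(rij, rik, rjk) (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
  q12 <- pc(R[1, 2], R[1, 3], R[2, 3])
  q13 <- pc(R[1, 3], R[1, 2], R[3, 2])
  q23 <- pc(R[2, 3], R[2, 1], R[3, 1])
  r2 <- 2 * (R[1, 2]^2 + R[1, 3]^2 + R[2, 3]^2)
  q2 <- 2 * (q12^2 + q13^2 + q23^2)
  k <- kmo(R)
  expect_equal(k$overall, r2 / (r2 + q2), tolerance = 1e-10)
  expect_true(all(k$per_variable >= 0 & k$per_variable <= 1))
})

test_that("VIF matches the per-regression R^2 definition", {
  # mutually uncorrelated contrast columns -> VIF exactly 1
  X <- cbind(a = rep(c(1, -1), 4),
             b = rep(c(1, 1, -1, -1), 2),
             c = rep(c(1, -1, -1, 1), 2))
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-10)

  Y <- withr::with_seed(6, MASS::mvrnorm(400, c(0, 0),
                                         matrix(c(1, 0.6, 0.6, 1), 2, 2),
                                         empirical = TRUE))
  colnames(Y) <- c("a", "b")
  expect_equal(unname(vif(Y)), rep(1 / (1 - 0.36), 2), tolerance = 1e-10)

  Z <- withr::with_seed(7, matrix(rnorm(500 * 3), 500, 3))
  Z[, 3] <- 0.5 * Z[, 1] - 0.3 * Z[, 2] + rnorm(500, 0, 0.8)
  colnames(Z) <- c("x", "y", "z")
  v <- vif(Z)
  oracle <- vapply(1:3, function(j) {
    r2 <- summary(stats::lm(Z[, j] ~ Z[, -j]))$r.squared
    1 / (1 - r2)
  }, 0)
  expect_equal(unname(v), oracle, tolerance = 1e-10)
  expect_error(vif(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
})

test_that("Doornik-Hansen has 2p df and detects non-normality", {
  X <- withr::with_seed(8, matrix(rnorm(500 * 8), 500, 8))
  dh <- doornik_hansen(X)
  expect_equal(dh$df, 16)
  expect_equal(doornik_hansen(X[, 1:4])$df, 8)

  # exponential marginals: strong rejection
  rej <- mean(vapply(1:50, function(r) {
    E <- withr::with_seed(900 + r, matrix(rexp(500 * 4), 500, 4))
    doornik_hansen(E)$p.value < 0.05
  }, TRUE))
  expect_gte(rej, 0.95)
  expect_error(doornik_hansen(matrix(rnorm(10), 5, 2)[, c(1, 1)]),
               "singular")
})

test_that("iterated principal factoring recovers planted loadings", {
  expect_equal(unname(efa_principal_factors(diag(4), 1)$loadings[, 1]),
               rep(0, 4), tolerance = 1e-6)

  lam <- c(0.8, 0.7, 0.6)
  R <- lam %*% t(lam)
  diag(R) <- 1
  ef <- efa_principal_factors(R, 1)
  expect_true(ef$converged)
  expect_equal(unname(ef$loadings[, 1]), lam, tolerance = 1e-3)
  expect_equal(sum(ef$proportion), 1)

  # two-factor bipolar population structure (left networks negative on F1).
  # Principal factoring is determined only up to rotation, so the planted
  # loadings are built as principal axes: orthogonal columns with distinct
  # norms.
  # (a 2-factor model needs >= 6 variables to be identified; use 8, the
  # size of the lateralized-network battery)
  L2 <- cbind(c(0.73, 0.28, 0.29, 0.28, 0.22, -0.38, -0.51, -0.37),
              c(-0.32, 0.06, 0.04, 0.26, 0.23, -0.75, 0.05, 0.48))
  L2[, 2] <- L2[, 2] - L2[, 1] * sum(L2[, 1] * L2[, 2]) / sum(L2[, 1]^2)
  R2 <- L2 %*% t(L2)
  diag(R2) <- 1
  ef2 <- efa_principal_factors(R2, 2)
  # align signs per factor before comparing
  for (j in 1:2) {
    rec <- ef2$loadings[, j]
    tgt <- L2[, j]
    if (sum(rec * tgt) < 0) rec <- -rec
    expect_equal(unname(rec), unname(tgt), tolerance = 0.05)
  }
  # the common-factor covariance is rotation-free and recovered tightly
  expect_equal(ef2$loadings %*% t(ef2$loadings), L2 %*% t(L2),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_true(all(ef2$communalities >= 0 & ef2$communalities <= 1))
  # proportions follow the retained eigenvalues
  expect_equal(ef2$proportion,
               ef2$eigenvalues / sum(ef2$eigenvalues))
})

test_that("parallel analysis retains the planted number of factors", {
  p <- 8
  # null data: no factor retained in most datasets
  zero <- vapply(1:10, function(r) {
    X <- withr::with_seed(400 + r, matrix(rnorm(1000 * p), 1000, p))
    obs <- latnet:::reduced_eigenvalues(stats::cor(X))
    parallel_analysis(1000, p, obs, reps = 100, seed = r)$n_factors
  }, 0L)
  expect_gte(mean(zero == 0L), 0.9)

  # one strong factor (all loadings 0.9): exactly one retained
  one <- vapply(1:5, function(r) {
    F1 <- withr::with_seed(500 + r, rnorm(1000))
    X <- 0.9 * F1 %*% t(rep(1, p)) +
      withr::with_seed(600 + r, matrix(rnorm(1000 * p, 0, sqrt(1 - 0.81)),
                                       1000, p))
    obs <- latnet:::reduced_eigenvalues(stats::cor(X))
    parallel_analysis(1000, p, obs, reps = 100, seed = r)$n_factors
  }, 0L)
  expect_true(all(one == 1L))
  expect_true(all(one <= p))
})

test_that("CFA reproduces the 4-indicator identification and fits exactly at the optimum", {
  spec <- list(f1 = c("a", "b"), f2 = c("c", "d"))
  Lt <- matrix(0, 4, 2); Lt[1:2, 1] <- 0.7; Lt[3:4, 2] <- 0.7
  Sig <- Lt %*% t(Lt) + diag(1 - 0.49, 4)
  X <- withr::with_seed(31, MASS::mvrnorm(400, rep(0, 4), Sig,
                                          empirical = TRUE))
  colnames(X) <- letters[1:4]

  fit <- cfa_fit(X, spec)
  expect_equal(fit$df, 2)                       # 10 moments - 8 free
  expect_equal(cfa_fit(X, spec, "free")$df, 1)  # +1 factor covariance
  # sample covariance equals the model-implied covariance -> saturated fit
  expect_lt(fit$discrepancy, 1e-8)
  expect_equal(unname(fit$fit_indices["CFI"]), 1)
  expect_equal(unname(fit$fit_indices["RMSEA"]), 0)
  expect_lt(fit$fit_indices["SRMR"], 1e-4)
  expect_equal(unname(fit$loadings[cbind(1:4, c(1, 1, 2, 2))]),
               rep(0.7, 4), tolerance = 1e-4)
})

test_that("CFA discrepancy matches an independent optimizer on misspecified data", {
  X <- withr::with_seed(32, {
    g <- rnorm(60)
    cbind(a = 0.6 * g + rnorm(60, 0, 0.8), b = 0.5 * g + rnorm(60, 0, 0.9),
          c = 0.4 * g + rnorm(60, 0, 0.9), d = -0.5 * g + rnorm(60, 0, 0.8))
  })
  spec <- list(f1 = c("a", "b"), f2 = c("c", "d"))
  fit <- cfa_fit(X, spec)

  # independent route: Nelder-Mead from several starts over the same
  # parameterization of Sigma(theta)
  S <- stats::cov(X)
  p <- 4
  obj <- function(par) {
    lam <- par[1:4]; th <- exp(par[5:8])
    Sg <- diag(th)
    Sg[1:2, 1:2] <- Sg[1:2, 1:2] + lam[1:2] %*% t(lam[1:2])
    Sg[3:4, 3:4] <- Sg[3:4, 3:4] + lam[3:4] %*% t(lam[3:4])
    ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) return(1e10)
    sum(log(ev)) - determinant(S)$modulus + sum(diag(S %*% solve(Sg))) - p
  }
  best <- Inf
  for (s in 1:5) {
    st <- withr::with_seed(700 + s,
                           c(rnorm(4, 0.5, 0.2), log(runif(4, 0.2, 1))))
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_equal(fit$discrepancy, as.numeric(best), tolerance = 1e-4)
  expect_gt(fit$statistic, 0)
})

test_that("CFA recovers planted parameters and its T follows chi-squared", {
  spec <- list(f1 = c("a", "b"), f2 = c("c", "d"))
  Lt <- matrix(0, 4, 2); Lt[1:2, 1] <- 0.65; Lt[3:4, 2] <- 0.75
  Sig <- Lt %*% t(Lt) + diag(1 - diag(Lt %*% t(Lt)))
  X <- withr::with_seed(33, MASS::mvrnorm(2000, rep(0, 4), Sig))
  colnames(X) <- letters[1:4]
  fit <- cfa_fit(X, spec)
  expect_equal(unname(fit$loadings[cbind(1:4, c(1, 1, 2, 2))]),
               c(0.65, 0.65, 0.75, 0.75), tolerance = 0.05)
  expect_lt(fit$statistic, stats::qchisq(0.975, 2))
  expect_true(all(fit$communalities >= 0 & fit$communalities <= 1))
  expect_error(cfa_fit(X, list(f1 = c("a", "b"), f2 = c("b", "c"))),
               "exactly one factor")
})
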