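#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from the identity:
#' `chi^2 = -(n - 1 - (2p + 5)/6) * ln|R|` on `p(p - 1)/2` degrees of
#' freedom. A significant result indicates correlated variables, a
#' prerequisite for factoring them.
#'
#' @param R correlation matrix (symmetric, unit diagonal).
#' @param n sample size used to estimate `R` (n > p).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (n <= p) stop("need n > p")
  check_corr(R)
  detR <- det(R)
  if (detR <= 0) stop("singular correlation matrix (det <= 0)")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

check_corr <- function(R) {
  if (nrow(R) != ncol(R)) stop("correlation matrix must be square")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("diagonal of R must be 1")
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  invisible(R)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Contrasts marginal correlations r with anti-image partial correlations
#' q (computed from the inverse of R):
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over i != j, with a
#' per-variable analogue over row sums. For any two-variable input the
#' partial correlation equals the marginal one, forcing KMO = 0.5.
#'
#' @param R invertible correlation matrix.
#' @return list with `overall` and `per_variable` (named if R has
#'   dimnames).
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  check_corr(R)
  Ri <- tryCatch(solve(R), error = function(e) stop("singular correlation matrix"))
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(d, d)   # anti-image partial correlations (off-diagonal)
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per) <- colnames(R)
  list(overall = overall, per_variable = per)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` with `R^2_j` from regressing variable j on
#' the remaining variables; computed as the diagonal of the inverse
#' correlation matrix. Perfectly collinear variables yield `Inf`.
#'
#' @param data numeric data.frame or matrix (subjects x variables), no
#'   constant columns, n > p.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(data) {
  X <- as.matrix(data)
  if (nrow(X) <= ncol(X)) stop("need n > p")
  if (any(apply(X, 2L, stats::sd) == 0)) stop("constant column in data")
  R <- stats::cor(X)
  Ri <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Ri)) return(stats::setNames(rep(Inf, ncol(X)), colnames(X)))
  stats::setNames(diag(Ri), colnames(X))
}

#' Doornik-Hansen multivariate normality test
#'
#' Standardizes the variables, orthogonalizes them through the
#' eigenstructure of their correlation matrix, applies the transformed
#' skewness and kurtosis statistics per component, and sums the squares:
#' the statistic is asymptotically chi-squared on 2p degrees of freedom.
#'
#' @param data numeric data.frame or matrix (subjects x variables),
#'   n > p + 1, nonsingular covariance.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
doornik_hansen <- function(data) {
  X <- as.matrix(data)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop("need n > p + 1")
  Z <- scale(X)  # unit-variance standardization (sd with n - 1)
  C <- stats::cor(X)
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) <= 1e-12) stop("singular covariance: cannot orthogonalize")
  Ci_sqrt <- ev$vectors %*% diag(1 / sqrt(ev$values), p) %*% t(ev$vectors)
  St <- Z %*% Ci_sqrt
  m2 <- colMeans(St^2) - colMeans(St)^2
  b1 <- (colMeans(St^3) - 3 * colMeans(St) * m2 - colMeans(St)^3) / m2^1.5
  b2 <- colMeans(scale(St, scale = FALSE)^4) / m2^2
  # transformed skewness (D'Agostino)
  beta <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta - 1))
  dl <- 1 / sqrt(log(sqrt(w2)))
  y <- b1 * sqrt((w2 - 1) * (n + 1) * (n + 3) / (12 * (n - 2)))
  z1 <- dl * log(y + sqrt(y^2 + 1))
  # transformed kurtosis (Bowman-Shenton / Doornik-Hansen form)
  dd <- (n - 3) * (n + 1) * (n^2 + 15 * n - 4)
  a <- (n - 2) * (n + 5) * (n + 7) * (n^2 + 27 * n - 70) / (6 * dd)
  cc <- (n - 7) * (n + 5) * (n + 7) * (n^2 + 2 * n - 5) / (6 * dd)
  kk <- (n + 5) * (n + 7) * (n^3 + 37 * n^2 + 11 * n - 313) / (12 * dd)
  al <- a + b1^2 * cc
  chi <- (b2 - 1 - b1^2) * 2 * kk
  z2 <- (((chi / (2 * al))^(1 / 3)) - 1 + 1 / (9 * al)) * sqrt(9 * al)
  stat <- sum(z1^2) + sum(z2^2)
  df <- 2 * p
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

smc <- function(R) 1 - 1 / diag(solve(R))

#' Eigenvalues of the reduced correlation matrix
#'
#' Replaces the diagonal of `R` with communalities (squared multiple
#' correlations by default) and returns the eigenvalues of the result —
#' the quantities that principal-axis factoring extracts and that
#' [parallel_analysis()] compares against random-data thresholds.
#'
#' @param R correlation matrix.
#' @param communalities optional replacement diagonal.
#' @return numeric vector of eigenvalues, decreasing.
#' @export
reduced_eigenvalues <- function(R, communalities = NULL) {
  if (is.null(communalities)) communalities <- smc(R)
  Rr <- R
  diag(Rr) <- communalities
  eigen(Rr, symmetric = TRUE, only.values = TRUE)$values
}

#' Iterated principal-axis exploratory factor analysis
#'
#' Classic iterated principal factoring: initial communalities are the
#' squared multiple correlations; the correlation matrix's diagonal is
#' replaced by the communalities, the reduced matrix eigendecomposed,
#' loadings taken as the top eigenvectors scaled by the square roots of
#' their (positive) eigenvalues, and the communalities updated from the
#' loadings until the largest change falls below `tol` (or `max_iter`).
#' Communalities that would exceed 1 (Heywood cases) are clipped to 1 with
#' a warning. Loadings are unrotated; the per-factor proportion of
#' variance is each retained eigenvalue over their sum.
#'
#' @param R correlation matrix.
#' @param n_factors number of factors, `1 <= n_factors < p`.
#' @param tol convergence tolerance on communalities (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @return object of class `factor_model` with `loadings` (p x m),
#'   `eigenvalues` (retained, of the final reduced matrix),
#'   `communalities`, `proportion` (of extracted variance), `iterations`,
#'   `converged`.
#' @export
efa_principal_factors <- function(R, n_factors, tol = 1e-6, max_iter = 200L) {
  R <- as.matrix(R)
  check_corr(R)
  p <- ncol(R)
  if (n_factors < 1L || n_factors >= p) stop("need 1 <= n_factors < p")
  h2 <- tryCatch(smc(R), error = function(e) rep(0.5, p))
  h2 <- pmin(pmax(h2, 0), 1)
  converged <- FALSE
  iter <- 0L
  heywood <- FALSE
  L <- matrix(0, p, n_factors)
  eigvals <- numeric(n_factors)
  repeat {
    iter <- iter + 1L
    Rr <- R
    diag(Rr) <- h2
    ev <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(ev$values[seq_len(n_factors)], 0)
    L <- ev$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(lam), n_factors)
    h2_new <- rowSums(L^2)
    if (any(h2_new > 1)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 1)
    }
    eigvals <- lam
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (heywood)
    warning("Heywood case: communality clipped to 1")
  # sign convention: each factor's largest-magnitude loading positive
  for (j in seq_len(n_factors)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(R), paste0("F", seq_len(n_factors)))
  structure(list(method = "iterated principal factors",
                 loadings = L,
                 eigenvalues = eigvals,
                 communalities = stats::setNames(h2, colnames(R)),
                 proportion = eigvals / sum(eigvals),
                 iterations = iter, converged = converged),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, digits = 2, ...) {
  cat("factor_model (", x$method, ")\n", sep = "")
  print(round(x$loadings, digits))
  if (!is.null(x$eigenvalues))
    cat("eigenvalues:", paste(round(x$eigenvalues, 2), collapse = " "),
        " proportions:", paste(round(x$proportion, 2), collapse = " "), "\n")
  if (!is.null(x$fit_indices))
    cat(sprintf("chi^2(%d) = %.2f, p = %.3g, CFI = %.2f, RMSEA = %.2f, SRMR = %.3f\n",
                x$df, x$statistic, x$p.value, x$fit_indices["CFI"],
                x$fit_indices["RMSEA"], x$fit_indices["SRMR"]))
  invisible(x)
}

#' Parallel analysis for factor retention
#'
#' Compares the observed reduced-matrix eigenvalues with the 95th
#' percentile of eigenvalues from `reps` random standard-normal datasets
#' of the same dimensions; the retained count is the number of leading
#' observed eigenvalues above their percentile. Deterministic under a
#' fixed seed.
#'
#' @param n sample size.
#' @param p number of variables.
#' @param observed_eigenvalues eigenvalues of the observed reduced
#'   correlation matrix (see the internal reduction used by
#'   [efa_principal_factors()]).
#' @param reps number of random datasets (>= 100).
#' @param seed integer seed.
#' @param quantile percentile of the null eigenvalue distribution
#'   (default 0.95).
#' @return list with `n_factors`, `thresholds`, `observed`.
#' @export
parallel_analysis <- function(n, p, observed_eigenvalues, reps = 200L,
                              seed = 1L, quantile = 0.95) {
  if (reps < 1L) stop("reps must be >= 1")
  if (reps < 100L) warning("fewer than 100 replicates gives unstable thresholds")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  null_eig <- matrix(0, reps, p)
  for (r in seq_len(reps)) {
    X <- matrix(stats::rnorm(n * p), n, p)
    null_eig[r, ] <- reduced_eigenvalues(stats::cor(X))
  }
  thresholds <- apply(null_eig, 2L, stats::quantile, probs = quantile)
  above <- observed_eigenvalues[seq_len(p)] > thresholds
  n_factors <- if (above[1L]) which.min(c(above, FALSE)) - 1L else 0L
  list(n_factors = as.integer(n_factors), thresholds = thresholds,
       observed = observed_eigenvalues)
}

#' Maximum-likelihood confirmatory factor analysis
#'
#' Fits a prespecified loading pattern by minimizing the normal-theory
#' discrepancy
#' `F_ML = ln|Sigma(theta)| - ln|S| + tr(S Sigma(theta)^-1) - p`
#' over the free loadings and residual variances, with factor variances
#' fixed at 1. The factor covariance is fixed at 0 by default (for 4
#' indicators on 2 factors this gives the df = 2 identification); set
#' `factor_covariance = "free"` to estimate it (df = 1 in that case).
#' `T = (n - 1) F_ML` is referred to chi-squared on
#' `p(p + 1)/2 - n_free` degrees of freedom; CFI uses the diagonal
#' (independence) baseline with the same `n - 1` multiplier, RMSEA is
#' `sqrt(max(T - df, 0) / (df (n - 1)))`, and SRMR is the root mean
#' square of the standardized residual covariances (diagonal included).
#'
#' @param data data.frame or matrix of indicators (subjects x variables).
#' @param spec named list mapping factor names to character vectors of
#'   indicator column names; every indicator loads on exactly one factor.
#' @param factor_covariance `"fixed_zero"` (default) or `"free"`.
#' @return object of class `factor_model` with standardized `loadings`,
#'   `communalities`, `discrepancy` (minimized F_ML), `statistic` (T),
#'   `df`, `p.value`, `fit_indices` (CFI, RMSEA, SRMR), `factor_cor`,
#'   `residual_variances`, `convergence`.
#' @export
cfa_fit <- function(data, spec, factor_covariance = c("fixed_zero", "free")) {
  factor_covariance <- match.arg(factor_covariance)
  X <- as.matrix(data)
  indicators <- unlist(spec, use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("every indicator must load on exactly one factor")
  if (!all(indicators %in% colnames(X)))
    stop("indicator(s) missing from data: ",
         paste(setdiff(indicators, colnames(X)), collapse = ", "))
  X <- X[, indicators, drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  m <- length(spec)
  S <- stats::cov(X)
  if (det(S) <= 0) stop("sample covariance is not positive definite")
  free_phi <- factor_covariance == "free" && m == 2L
  if (factor_covariance == "free" && m != 2L)
    stop("free factor covariance is implemented for 2 factors")
  n_free <- p + p + as.integer(free_phi)
  df <- p * (p + 1) / 2 - n_free
  if (df < 0) stop("negative degrees of freedom: model not identified")
  if (n <= n_free) stop("need n > number of free parameters")
  fac_of <- rep(seq_along(spec), lengths(spec))
  Lpat <- matrix(0, p, m)
  Lpat[cbind(seq_len(p), fac_of)] <- 1
  implied <- function(par) {
    lam <- par[seq_len(p)]
    th <- exp(par[p + seq_len(p)])
    phi <- diag(m)
    if (free_phi) phi[1L, 2L] <- phi[2L, 1L] <- tanh(par[2L * p + 1L])
    Lam <- Lpat * lam
    Lam %*% phi %*% t(Lam) + diag(th, p)
  }
  ldS <- determinant(S, logarithm = TRUE)$modulus
  fml <- function(par) {
    Sig <- implied(par)
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) return(1e10)
    as.numeric(sum(log(ev)) - ldS + sum(diag(S %*% solve(Sig))) - p)
  }
  start <- c(sqrt(diag(S) / 2), log(diag(S) / 2), if (free_phi) 0)
  opt <- stats::nlminb(start, fml, control = list(iter.max = 500L))
  # polish from a second start to guard against local minima
  start2 <- c(sqrt(diag(S) * 0.8), log(diag(S) * 0.2), if (free_phi) 0.1)
  opt2 <- stats::nlminb(start2, fml, control = list(iter.max = 500L))
  if (opt2$objective < opt$objective) opt <- opt2
  par <- opt$par
  Fmin <- max(opt$objective, 0)
  Tstat <- (n - 1) * Fmin
  Sig <- implied(par)
  lam <- par[seq_len(p)]
  th <- exp(par[p + seq_len(p)])
  phi_off <- if (free_phi) tanh(par[2L * p + 1L]) else 0
  # standardized loadings: indicator variance from the implied covariance
  std_lam <- lam / sqrt(diag(Sig))
  # sign convention: majority of loadings per factor positive
  L <- matrix(0, p, m, dimnames = list(indicators, names(spec)))
  L[cbind(seq_len(p), fac_of)] <- std_lam
  for (j in seq_len(m)) {
    lj <- L[fac_of == j, j]
    if (sum(lj) < 0) {
      L[fac_of == j, j] <- -lj
      if (free_phi) phi_off <- -phi_off
    }
  }
  # baseline (independence) model: diagonal covariance
  Tb <- -(n - 1) * as.numeric(determinant(stats::cov2cor(S),
                                          logarithm = TRUE)$modulus)
  dfb <- p * (p - 1) / 2
  cfi <- 1 - max(Tstat - df, 0) / max(Tb - dfb, Tstat - df, 0)
  rmsea <- if (df > 0) sqrt(max(Tstat - df, 0) / (df * (n - 1))) else 0
  Ds <- 1 / sqrt(diag(S))
  res_std <- (S - Sig) * outer(Ds, Ds)
  srmr <- sqrt(mean(res_std[lower.tri(res_std, diag = TRUE)]^2))
  structure(list(method = "ML confirmatory factor analysis",
                 loadings = L,
                 eigenvalues = NULL, proportion = NULL,
                 communalities = stats::setNames(std_lam^2, indicators),
                 residual_variances = stats::setNames(th, indicators),
                 factor_cor = phi_off,
                 factor_covariance = factor_covariance,
                 discrepancy = Fmin,
                 statistic = Tstat, df = df,
                 p.value = stats::pchisq(Tstat, df, lower.tail = FALSE),
                 fit_indices = c(CFI = cfi, RMSEA = rmsea, SRMR = srmr),
                 convergence = opt$convergence,
                 n = n, spec = spec),
            class = "factor_model")
}
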