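#' Bonferroni-corrected per-test alpha
#'
#' Family-wise level divided by the number of tests; comparisons always use
#' the unrounded value. `display` gives the 3-decimal rendering used in
#' reports (0.05 over 17 networks displays as 0.003).
#'
#' @param alpha family-wise error level in (0, 1).
#' @param m number of tests (>= 1).
#' @return list with `alpha` (exact corrected level) and `display`
#'   (rounded to 3 decimals, for reporting only).
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  corrected <- alpha / m
  list(alpha = corrected, display = round(corrected, 3))
}

#' Intercept test of lateralization for one network
#'
#' Ordinary least squares of a network's NSAR values on mean-centered age,
#' sex, mean-centered mean framewise displacement and handedness. The test
#' of lateralization is the two-sided t test of the model intercept: a
#' significantly negative intercept indicates left lateralization,
#' positive right.
#'
#' @param table an [nsar_table()].
#' @param network network column name (or index into [nsar_networks()]).
#' @return list with `network`, `estimate` (intercept), `se`, `t`, `df`,
#'   `p.value` and the full fitted `lm` object as `fit`.
#' @export
fit_network_lateralization <- function(table, network) {
  stopifnot(inherits(table, "nsar_table"))
  nets <- nsar_networks(table)
  if (is.numeric(network)) network <- nets[network]
  if (!network %in% nets) stop("unknown network: ", network)
  X <- covariate_design(table)
  n <- nrow(table)
  if (n < ncol(X) + 1L + 6L)
    stop("need at least ", ncol(X) + 7L, " subjects")
  df <- data.frame(nsar = table[[network]], X)
  fit <- stats::lm(nsar ~ c_age + sex + c_mean_fd + handedness, data = df)
  cf <- summary(fit)$coefficients
  list(network = network,
       estimate = cf["(Intercept)", "Estimate"],
       se = cf["(Intercept)", "Std. Error"],
       t = cf["(Intercept)", "t value"],
       df = fit$df.residual,
       p.value = cf["(Intercept)", "Pr(>|t|)"],
       fit = fit)
}

#' Identify consistently lateralized networks across datasets
#'
#' A network qualifies iff its intercept test passes the
#' Bonferroni-corrected threshold (`alpha` divided by the number of
#' networks) in every dataset, with the same sign of the intercept
#' throughout. The direction attached is `"left"` for negative intercepts
#' and `"right"` for positive ones.
#'
#' @param tables a single [nsar_table()] or a list of them (one per
#'   dataset), all sharing one network set.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame with columns `network`, `direction`, and per-dataset
#'   intercepts and p-values; only qualifying networks are returned (zero
#'   rows if none). The corrected alpha used is attached as attribute
#'   `corrected_alpha`.
#' @export
identify_lateralized <- function(tables, alpha = 0.05) {
  if (inherits(tables, "nsar_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  nets <- nsar_networks(tables[[1L]])
  for (tb in tables)
    if (!setequal(nsar_networks(tb), nets))
      stop("datasets have different network sets")
  corrected <- bonferroni_alpha(alpha, length(nets))$alpha
  res <- lapply(tables, function(tb) {
    t(vapply(nets, function(nw) {
      f <- fit_network_lateralization(tb, nw)
      c(estimate = f$estimate, p.value = f$p.value)
    }, c(estimate = 0, p.value = 0)))
  })
  est <- vapply(res, function(m) m[, "estimate"], numeric(length(nets)))
  pv <- vapply(res, function(m) m[, "p.value"], numeric(length(nets)))
  est <- matrix(est, nrow = length(nets))
  pv <- matrix(pv, nrow = length(nets))
  sig <- pv < corrected
  same_sign <- apply(est, 1L, function(e) all(e > 0) || all(e < 0))
  keep <- apply(sig, 1L, all) & same_sign
  out <- data.frame(network = nets[keep],
                    direction = ifelse(est[keep, 1L] < 0, "left", "right"),
                    stringsAsFactors = FALSE)
  for (d in seq_along(tables)) {
    out[[paste0("estimate_", d)]] <- est[keep, d]
    out[[paste0("p_", d)]] <- pv[keep, d]
  }
  attr(out, "corrected_alpha") <- corrected
  rownames(out) <- NULL
  out
}

#' Pairwise comparison of two like-lateralized networks
#'
#' Stacks the two networks' NSAR values in long format (two rows per
#' subject) and regresses on a 0/1 network indicator (1 = `netB`) plus the
#' four covariates, the classical long-format design. The indicator
#' coefficient is reported on the raw NSAR scale: for right-lateralized
#' pairs a positive coefficient means `netB` is more lateralized; for left
#' pairs a negative coefficient does. The long-format stacking ignores
#' within-subject dependence; `paired_check = TRUE` adds a paired t test
#' on the per-subject differences as a cross-check.
#'
#' @param table an [nsar_table()].
#' @param netA,netB distinct network column names.
#' @param paired_check also run a paired t test?
#' @return list with `coefficient`, `se`, `t`, `p.value` for the network
#'   indicator, and optionally `paired` (htest).
#' @export
compare_networks_pairwise <- function(table, netA, netB, paired_check = FALSE) {
  stopifnot(inherits(table, "nsar_table"))
  if (identical(netA, netB)) stop("netA and netB must differ")
  nets <- nsar_networks(table)
  if (!all(c(netA, netB) %in% nets)) stop("unknown network name(s)")
  X <- covariate_design(table)
  long <- data.frame(
    nsar = c(table[[netA]], table[[netB]]),
    network = rep(c(0, 1), each = nrow(table)),
    rbind(X, X))
  fit <- stats::lm(nsar ~ network + c_age + sex + c_mean_fd + handedness,
                   data = long)
  cf <- summary(fit)$coefficients["network", ]
  out <- list(netA = netA, netB = netB,
              coefficient = unname(cf["Estimate"]),
              se = unname(cf["Std. Error"]),
              t = unname(cf["t value"]),
              p.value = unname(cf["Pr(>|t|)"]))
  if (paired_check)
    out$paired <- stats::t.test(table[[netB]], table[[netA]], paired = TRUE)
  out
}

#' Correlation of averaged left- and right-lateralized values
#'
#' Averages (row-wise) the NSAR values over the left-lateralized networks
#' and, separately, over the right-lateralized networks, then correlates
#' the two per-subject averages (Pearson, two-sided).
#'
#' @param table an [nsar_table()] (normally adjusted).
#' @param left_set,right_set disjoint nonempty character vectors of
#'   network names.
#' @return list with `left_mean`, `right_mean` (per-subject vectors), `r`,
#'   `p.value`, `conf.int` and `n`.
#' @export
average_like_lateralized <- function(table, left_set, right_set) {
  stopifnot(inherits(table, "nsar_table"))
  if (!length(left_set) || !length(right_set))
    stop("both network sets must be nonempty")
  if (length(intersect(left_set, right_set)))
    stop("left and right network sets overlap")
  nets <- nsar_networks(table)
  if (!all(c(left_set, right_set) %in% nets)) stop("unknown network name(s)")
  lm_ <- rowMeans(as.matrix(table[left_set]))
  rm_ <- rowMeans(as.matrix(table[right_set]))
  ct <- stats::cor.test(lm_, rm_)
  list(left_mean = lm_, right_mean = rm_,
       r = unname(ct$estimate), p.value = ct$p.value,
       conf.int = as.numeric(ct$conf.int), n = length(lm_))
}

#' Network-by-network correlation matrix
#'
#' Pairwise Pearson correlations of NSAR values with two-sided p-values
#' from the t transform and Fisher-z 95% confidence intervals. The display
#' threshold only controls which entries a renderer should mask; the
#' returned matrices are complete. Constant columns yield `NA`
#' correlations.
#'
#' @param table an [nsar_table()].
#' @param networks network column names (default: all).
#' @param display_alpha masking level recorded for rendering (default .05).
#' @return object of class `relation_matrix`: list with symmetric matrices
#'   `r`, `p`, `ci_lower`, `ci_upper`, plus `n` and `display_alpha`.
#' @export
correlation_matrix <- function(table, networks = NULL, display_alpha = 0.05) {
  stopifnot(inherits(table, "nsar_table"))
  if (is.null(networks)) networks <- nsar_networks(table)
  if (nrow(table) < 3L) stop("need at least 3 subjects")
  X <- as.matrix(table[networks])
  p <- ncol(X)
  n <- nrow(X)
  r <- pm <- lo <- hi <- matrix(NA_real_, p, p,
                                dimnames = list(networks, networks))
  diag(r) <- 1; diag(pm) <- 0; diag(lo) <- 1; diag(hi) <- 1
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (stats::sd(X[, i]) == 0 || stats::sd(X[, j]) == 0) next
    ct <- stats::cor.test(X[, i], X[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pm[i, j] <- pm[j, i] <- ct$p.value
    z <- atanh(r[i, j])
    se <- 1 / sqrt(n - 3)
    lo[i, j] <- lo[j, i] <- tanh(z - stats::qnorm(0.975) * se)
    hi[i, j] <- hi[j, i] <- tanh(z + stats::qnorm(0.975) * se)
  }
  structure(list(r = r, p = pm, ci_lower = lo, ci_upper = hi,
                 n = n, display_alpha = display_alpha),
            class = "relation_matrix")
}

#' @export
print.relation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("relation_matrix: %d networks, n = %d (entries with p >= %.2f shown as '.')\n",
              ncol(x$r), x$n, x$display_alpha))
  shown <- format(round(x$r, digits))
  shown[x$p >= x$display_alpha] <- "."
  print(shown, quote = FALSE)
  invisible(x)
}
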