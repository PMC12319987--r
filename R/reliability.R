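#' Two-session intraclass correlation
#'
#' Two-way model, single measures, for k = 2 sessions. The default
#' `"consistency"` form is
#'
#'   `ICC = (MSR - MSE) / (MSR + (k - 1) MSE)`,
#'
#' whose F statistic `MSR/MSE` has `(n - 1, (n - 1)(k - 1))` degrees of
#' freedom — for two sessions, `(n - 1, n - 1)` — and satisfies
#' `ICC = (F - 1)/(F + 1)`. The `"agreement"` (absolute-agreement) form
#' additionally charges the session-mean difference to the denominator.
#' Confidence intervals follow McGraw & Wong's F-based construction.
#'
#' @param x,y numeric vectors of per-subject values for sessions 1 and 2
#'   (equal length, n >= 3, no missing values).
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf confidence level for the interval.
#' @return object of class `icc_result`: list with `icc`, `F`, `df1`,
#'   `df2`, `p.value`, `ci` (length-2), `type` and the mean squares.
#' @export
icc_two_session <- function(x, y, type = c("consistency", "agreement"),
                            conf = 0.95) {
  type <- match.arg(type)
  if (length(x) != length(y)) stop("sessions have different lengths")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 3L) stop("need at least 3 subjects")
  k <- 2L
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (ssr + ssc + sse <= 0) stop("zero total variance: ICC undefined")
  if (mse == 0 && msr == 0) stop("zero variance: ICC undefined")
  alpha <- 1 - conf
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  Fobs <- msr / mse
  p <- stats::pf(Fobs, df1, df2, lower.tail = FALSE)
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    Fs <- stats::qf(1 - alpha / 2, df1, v)
    lower <- n * (msr - Fs * mse) /
      (Fs * (k * msc + (k * n - k - n) * mse) + n * msr)
    Fs2 <- stats::qf(1 - alpha / 2, v, df1)
    upper <- n * (Fs2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * Fs2 * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, F = Fobs, df1 = df1, df2 = df2, p.value = p,
                 ci = ci, conf = conf, type = type,
                 msr = msr, msc = msc, mse = mse, n = n),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s, single) = %.3f, F(%d, %d) = %.2f, p = %.3g, %d%% CI [%.3f, %.3f]\n",
              if (x$type == "consistency") "C,1" else "A,1",
              x$icc, x$df1, x$df2, x$F, x$p.value, round(100 * x$conf),
              x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' Stability of estimates across data increments
#'
#' Computes the two-session ICC of each data increment (e.g., 5, 10, ...,
#' 30 min worth of data) against one independent reference estimate per
#' subject.
#'
#' @param values_by_increment named list; each element a numeric vector of
#'   per-subject values at that increment, aligned with `reference` (if
#'   both carry subject names, alignment is checked).
#' @param reference numeric vector of per-subject reference values.
#' @param type ICC form, see [icc_two_session()].
#' @return data.frame with one row per increment: `increment`, `icc`, `F`,
#'   `df1`, `df2`, `ci_lower`, `ci_upper`, `p.value`.
#' @export
incremental_stability <- function(values_by_increment, reference,
                                  type = c("consistency", "agreement")) {
  type <- match.arg(type)
  stopifnot(is.list(values_by_increment), length(values_by_increment) >= 1L)
  rows <- lapply(names(values_by_increment), function(lvl) {
    v <- values_by_increment[[lvl]]
    if (length(v) != length(reference))
      stop("increment '", lvl, "' not aligned with reference")
    if (!is.null(names(v)) && !is.null(names(reference)) &&
        !identical(names(v), names(reference)))
      stop("subject names of increment '", lvl, "' disagree with reference")
    r <- icc_two_session(v, reference, type = type)
    data.frame(increment = lvl, icc = r$icc, F = r$F, df1 = r$df1,
               df2 = r$df2, ci_lower = r$ci[1L], ci_upper = r$ci[2L],
               p.value = r$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split runs into two disjoint halves
#'
#' @param run_ids ordered vector of run identifiers (even count).
#' @param scheme `"even_odd"` (odd-numbered positions vs even-numbered
#'   positions), `"first_second"` (first half vs second half) or
#'   `"random"` (seeded random balanced split).
#' @param seed integer seed (required for `"random"`).
#' @return list with elements `first` and `second`: disjoint, exhaustive
#'   halves of `run_ids`.
#' @export
split_runs <- function(run_ids, scheme = c("even_odd", "first_second", "random"),
                       seed = NULL) {
  scheme <- match.arg(scheme)
  n <- length(run_ids)
  if (n < 2L) stop("need at least 2 runs")
  if (n %% 2L != 0L) stop("need an even number of runs for balanced halves")
  idx <- switch(scheme,
    even_odd = seq(1L, n, by = 2L),
    first_second = seq_len(n %/% 2L),
    random = {
      if (is.null(seed)) stop("scheme 'random' requires a seed")
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      sort(sample.int(n, n %/% 2L))
    })
  list(first = run_ids[idx], second = run_ids[-idx])
}

#' Exact Wilcoxon signed-rank test
#'
#' V is the sum of the ranks of the positive differences (zeros dropped
#' before ranking; ties share average ranks). The exact two-sided p-value
#' is the doubled smaller tail of the null distribution of V over all
#' `2^n` equiprobable sign assignments, computed by a generating-function
#' convolution that is exact even under ties. Above `n = 25` a normal
#' approximation with continuity and tie corrections is used.
#'
#' @param differences numeric vector of paired differences.
#' @param exact force exact (`TRUE`) or approximate (`FALSE`); default
#'   `NULL` chooses exact for n <= 25 nonzero differences.
#' @return object of class `wilcoxon_exact`: list with `statistic` (V),
#'   `p.value`, `n` (nonzero differences) and `method`.
#' @export
wilcoxon_signed_rank_exact <- function(differences, exact = NULL) {
  d <- differences[differences != 0]
  n <- length(d)
  if (n < 1L) stop("all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (is.null(exact)) exact <- n <= 25L
  if (exact) {
    r2 <- as.integer(round(2 * r))  # doubled ranks are integers under ties
    total <- sum(r2)
    counts <- c(1, numeric(total))  # counts[v + 1] = #assignments with 2V = v
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (sign-assignment distribution)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  structure(list(statistic = c(V = V), p.value = p, n = n, method = method),
            class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: V = %g, p = %.4g (%s, n = %d)\n",
              x$statistic, x$p.value, x$method, x$n))
  invisible(x)
}
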