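test_that("ICC is 1 for perfect agreement and matches a hand ANOVA", {
  x <- c(0.1, 0.4, 0.7, 0.9, 0.2)
  r <- icc_two_session(x, x)
  expect_equal(r$icc, 1.0)
  expect_equal(r$df1, 4L)
  expect_equal(r$df2, 4L)

  # 4-subject hand table: variance components via aov as an oracle
  x1 <- c(0.10, 0.30, 0.55, 0.80)
  x2 <- c(0.18, 0.24, 0.60, 0.70)
  long <- data.frame(y = c(x1, x2),
                     subj = factor(rep(1:4, 2)),
                     sess = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + sess, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  r2 <- icc_two_session(x1, x2)
  expect_equal(r2$icc, (msr - mse) / (msr + mse), tolerance = 1e-10)
  expect_equal(r2$F, msr / mse, tolerance = 1e-10)
  ra <- icc_two_session(x1, x2, type = "agreement")
  expect_equal(ra$icc,
               (msr - mse) / (msr + mse + (2 / 4) * (msc - mse)),
               tolerance = 1e-10)
  # consistency identity (F - 1)/(F + 1) for two sessions
  expect_equal(r2$icc, (r2$F - 1) / (r2$F + 1), tolerance = 1e-12)
  expect_true(r2$ci[1] <= r2$icc && r2$icc <= r2$ci[2])
})

test_that("ICC recovers planted variance ratios at large n", {
  n <- 2000
  for (icc_true in c(0.2, 0.5, 0.9)) {
    vs <- icc_true            # subject variance
    ve <- 1 - icc_true        # error variance
    withr::with_seed(round(100 * icc_true), {
      subj <- rnorm(n, 0, sqrt(vs))
      x <- subj + rnorm(n, 0, sqrt(ve))
      y <- subj + rnorm(n, 0, sqrt(ve))
    })
    r <- icc_two_session(x, y)
    expect_lt(abs(r$icc - icc_true), 0.05)
  }
})

test_that("ICC rejects degenerate input", {
  expect_error(icc_two_session(c(1, 2), c(1, 2)), "3 subjects")
  expect_error(icc_two_session(rep(1, 5), rep(1, 5)), "variance")
  expect_error(icc_two_session(c(1, NA, 2), c(1, 2, 3)), "missing")
})

test_that("incremental stability tracks the planted noise model", {
  n <- 200
  withr::with_seed(71, {
    truth <- rnorm(n, 0, 1)
    reference <- truth + rnorm(n, 0, 0.3)
    incs <- lapply(c(5, 10, 20, 30), function(minutes)
      truth + rnorm(n, 0, 1 / sqrt(minutes)))
    names(incs) <- c("5", "10", "20", "30")
  })
  rep_ <- incremental_stability(incs, reference)
  expect_equal(rep_$increment, c("5", "10", "20", "30"))
  # ICC non-decreasing in data quantity (within simulation error)
  expect_true(all(diff(rep_$icc) > -0.05))

  same <- incremental_stability(list(a = reference, b = reference), reference)
  expect_equal(same$icc, c(1, 1))

  # uncorrelated noise only: the mean of several null ICC estimates at
  # n = 200 sits near zero (single-draw sd is ~ 1/sqrt(n))
  null_iccs <- vapply(1:10, function(r) withr::with_seed(720 + r, {
    incremental_stability(list(x = rnorm(n)), rnorm(n))$icc
  }), 0)
  expect_lt(abs(mean(null_iccs)), 0.1)

  expect_error(incremental_stability(list(a = 1:5), 1:4), "not aligned")
})

test_that("run splitting schemes are deterministic, disjoint and exhaustive", {
  expect_equal(split_runs(1:4, "even_odd"), list(first = c(1L, 3L), second = c(2L, 4L)))
  expect_equal(split_runs(1:4, "first_second"), list(first = 1:2, second = 3:4))
  r1 <- split_runs(1:12, "random", seed = 7)
  r2 <- split_runs(1:12, "random", seed = 7)
  expect_identical(r1, r2)
  expect_length(intersect(r1$first, r1$second), 0)
  expect_setequal(c(r1$first, r1$second), 1:12)
  expect_error(split_runs(1L, "even_odd"), "at least 2")
  expect_error(split_runs(1:3, "even_odd"), "even number")
  expect_error(split_runs(1:4, "random"), "seed")
})

test_that("the exact signed-rank test reproduces the all-positive worked example", {
  d <- c(0.11, 0.05, 0.21, 0.08, 0.13, 0.02, 0.17, 0.09)  # n = 8, all > 0
  w <- wilcoxon_signed_rank_exact(d)
  expect_equal(unname(w$statistic), 36)
  expect_equal(w$p.value, 2 / 256)
  expect_equal(round(w$p.value, 3), 0.008)

  w1 <- wilcoxon_signed_rank_exact(1)
  expect_equal(unname(w1$statistic), 1)
  expect_equal(w1$p.value, 1.0)
  expect_error(wilcoxon_signed_rank_exact(c(0, 0)), "zero")
})

test_that("exact p-values equal full 2^n enumeration and agree with wilcox.test", {
  for (n in c(3, 5, 8, 12)) {
    for (rep in 1:4) {
      d <- withr::with_seed(n * 10 + rep, round(rnorm(n), 2))
      d <- d[d != 0]
      if (length(d) < 1) next
      w <- wilcoxon_signed_rank_exact(d)
      oracle <- wilcoxon_enum_oracle(d)
      expect_equal(unname(w$statistic), oracle$V)
      expect_equal(w$p.value, oracle$p)
      expect_gt(w$p.value, 0)
      expect_lte(w$p.value, 1)
      expect_gte(unname(w$statistic), 0)
      expect_lte(unname(w$statistic), length(d) * (length(d) + 1) / 2)
      # base-R cross-check when |d| has no ties (wilcox.test exact path)
      if (!any(duplicated(abs(d)))) {
        bw <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
        expect_equal(w$p.value, bw$p.value)
      }
    }
  }
})

test_that("ties are handled via average ranks in both exact and approximate paths", {
  d <- c(1, 1, -1, 2, 2)
  w <- wilcoxon_signed_rank_exact(d)
  oracle <- wilcoxon_enum_oracle(d)
  expect_equal(w$p.value, oracle$p)
  wa <- wilcoxon_signed_rank_exact(rep(c(1, -2), 15))  # n = 30 -> approximate
  expect_match(wa$method, "approximation")
  expect_gt(wa$p.value, 0)
})

test_that("the split-comparison harness keeps its size under the null", {
  # within-split vs between-split dice where both arise from one
  # generative parcellation process: no declared effect in >= 90% of reps
  lm <- get_ico(2, "left"); rm <- get_ico(2, "right")
  la <- get_adj(2, "left"); ra <- get_adj(2, "right")
  tab <- toy_label_table(1:4)
  fractions <- stats::setNames(rep(0.22, 4), unname(tab))
  targets <- stats::setNames(c(-0.3, 0.3, 0, 0), unname(tab))
  subjects <- lapply(1:8, function(i)
    render_parcellation(targets, fractions, lm, rm, seed = 900 + i,
                        label_table = tab, left_adj = la, right_adj = ra))
  n_reps <- 30
  rejections <- 0
  for (r in seq_len(n_reps)) {
    diffs <- vapply(seq_along(subjects), function(i) {
      runs <- generate_runs(subjects[[i]], 4, boundary_noise = 0.15,
                            seed = 5000 + 37 * r + i,
                            left_adj = la, right_adj = ra)
      halves <- split_runs(1:4, "even_odd")
      within <- dice(runs[[halves$first[1]]], runs[[halves$first[2]]])
      between <- dice(runs[[halves$second[1]]], runs[[halves$second[2]]])
      within - between
    }, 0)
    diffs <- diffs[diffs != 0]
    if (length(diffs) &&
        wilcoxon_signed_rank_exact(diffs)$p.value < 0.05)
      rejections <- rejections + 1
  }
  expect_lte(rejections / n_reps, 0.10)
})
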