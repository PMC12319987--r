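test_that("population generation is reproducible and hits planted means", {
  cfg <- default_simulation_config(n_subjects = 100, seed = 5)
  t1 <- generate_population(cfg)
  t2 <- generate_population(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  big <- default_simulation_config(n_subjects = 10000, seed = 6)
  tb <- generate_population(big)
  expect_lt(abs(mean(tb[["Dorsal Attention-A"]]) - (-0.30)), 0.01)
  expect_lt(abs(mean(tb[["Limbic-B"]]) - 0.35), 0.01)
  expect_true(all(abs(as.matrix(tb[nsar_networks(tb)])) <= 1))
})

test_that("zero loadings and zero covariate effects give uncorrelated networks", {
  nets <- unname(yeo17_label_table())
  cfg <- simulation_config(
    n_subjects = 5000, mu = stats::setNames(numeric(17), nets),
    loadings = matrix(0, 17, 2), seed = 9)
  tb <- generate_population(cfg)
  R <- stats::cor(as.matrix(tb[nets]))
  diag(R) <- 0
  expect_lt(max(abs(R)), 0.05)
})

test_that("the implied left/right coupling matches its analytic target", {
  cfg <- default_simulation_config(seed = 2)
  expect_equal(implied_left_right_cor(cfg), -0.65, tolerance = 1e-6)
  S <- implied_network_cov(cfg)
  expect_equal(S, t(S))
  expect_gt(min(eigen(S, only.values = TRUE)$values), 0)
  cfg2 <- default_simulation_config(coupling = -0.5, seed = 2)
  expect_equal(implied_left_right_cor(cfg2), -0.5, tolerance = 1e-6)
})

test_that("rendered parcellations achieve their NSAR targets", {
  lm <- get_ico(4, "left"); rm <- get_ico(4, "right")
  la <- get_adj(4, "left"); ra <- get_adj(4, "right")
  cfg <- default_simulation_config(seed = 3)

  # symmetric target
  tg0 <- stats::setNames(numeric(17), cfg$networks)
  s0 <- render_parcellation(tg0, cfg$fractions, lm, rm, seed = 12,
                            left_adj = la, right_adj = ra)
  expect_lt(max(abs(compute_nsar(s0, lm, rm))), 0.02)

  # +1 endpoint is exact: the network exists only on the right
  tg1 <- tg0; tg1["Language"] <- 1
  s1 <- render_parcellation(tg1, cfg$fractions, lm, rm, seed = 13,
                            left_adj = la, right_adj = ra)
  expect_identical(sum(s1$left$labels == 17L), 0L)
  expect_equal(unname(compute_nsar(s1, lm, rm)["Language"]), 1.0)

  # the study-like sign pattern: 3 left-negative, 5 right-positive
  sp <- render_parcellation(cfg$mu, cfg$fractions, lm, rm, seed = 14,
                            left_adj = la, right_adj = ra)
  v <- compute_nsar(sp, lm, rm)
  expect_lt(max(abs(v - cfg$mu[names(v)])), 0.02)
  expect_true(all(v[cfg$left_set] < 0))
  expect_true(all(v[cfg$right_set] > 0))

  expect_error(render_parcellation(tg0,
                                   stats::setNames(rep(0.1, 17), cfg$networks),
                                   lm, rm, seed = 1),
               "sum to <= 1")
})

test_that("rendered parcellations are valid inputs to the other modules", {
  lm <- get_ico(3, "left"); rm <- get_ico(3, "right")
  tab <- toy_label_table(1:5)
  tg <- stats::setNames(c(-0.3, 0.2, 0, 0.4, -0.1), unname(tab))
  fr <- stats::setNames(rep(0.18, 5), unname(tab))
  s <- render_parcellation(tg, fr, lm, rm, seed = 15, label_table = tab)
  expect_length(s$left$labels, nrow(lm$vertices))
  expect_true(all(s$left$labels %in% 0:5))
  expect_equal(dice(s, s), 1.0)
  m <- overlap_matrix(s, s)
  expect_true(all(m[upper.tri(m)] == 0))
  h <- hungarian_match(-m)
  expect_equal(h$mapping$to, 1:5)
})

test_that("run perturbations degrade overlap monotonically and reproducibly", {
  lm <- get_ico(3, "left"); rm <- get_ico(3, "right")
  la <- get_adj(3, "left"); ra <- get_adj(3, "right")
  tab <- toy_label_table(1:4)
  tg <- stats::setNames(c(-0.3, 0.3, 0, 0), unname(tab))
  fr <- stats::setNames(rep(0.22, 4), unname(tab))
  s <- render_parcellation(tg, fr, lm, rm, seed = 16, label_table = tab,
                           left_adj = la, right_adj = ra)

  r0 <- generate_runs(s, 2, 0, seed = 1, left_adj = la, right_adj = ra)
  expect_identical(r0[[1]]$left$labels, s$left$labels)
  expect_equal(dice(s, r0[[1]]), 1.0)

  mean_dice <- vapply(c(0, 0.05, 0.2), function(bn) {
    runs <- generate_runs(s, 3, bn, seed = 17, left_adj = la, right_adj = ra)
    mean(vapply(runs, function(r) dice(s, r), 0))
  }, 0)
  expect_true(all(diff(mean_dice) < 1e-9))

  a <- generate_runs(s, 3, 0.1, seed = 18, left_adj = la, right_adj = ra)
  b <- generate_runs(s, 3, 0.1, seed = 18, left_adj = la, right_adj = ra)
  expect_identical(lapply(a, function(x) x$left$labels),
                   lapply(b, function(x) x$left$labels))
  # label-0 territory untouched
  expect_identical(a[[1]]$left$labels == 0L, s$left$labels == 0L)
})

test_that("synthetic connectivity yields autonomy decreasing in homotopy", {
  lm <- get_ico(2, "left"); rm <- get_ico(2, "right")
  tab <- toy_label_table(1:3)
  tg <- stats::setNames(c(-0.2, 0.2, 0), unname(tab))
  fr <- stats::setNames(rep(0.3, 3), unname(tab))
  s <- render_parcellation(tg, fr, lm, rm, seed = 19, label_table = tab)

  ai_by_h <- vapply(c(0, 0.5, 1), function(h) {
    prof <- generate_connectivity(s, homotopy = h, seed = 20)
    mean(autonomy_index(prof, s), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(ai_by_h) < 0))      # strictly decreasing
  expect_gt(ai_by_h[1], 0.1)               # no contralateral links: maximal
  expect_lt(abs(ai_by_h[3]), 0.05)         # full homotopy: near zero

  p1 <- generate_connectivity(s, homotopy = 0.5, seed = 21)
  p2 <- generate_connectivity(s, homotopy = 0.5, seed = 21)
  expect_identical(p1$R, p2$R)
  expect_error(generate_connectivity(s, homotopy = 2, seed = 1), "homotopy")
})

test_that("a rendered round trip returns the planted NSAR values", {
  lm <- get_ico(4, "left"); rm <- get_ico(4, "right")
  la <- get_adj(4, "left"); ra <- get_adj(4, "right")
  cfg <- default_simulation_config(n_subjects = 8, seed = 23)
  tb <- generate_population(cfg)
  vals <- as.matrix(tb[nsar_networks(tb)])
  for (i in seq_len(nrow(tb))) {
    tg <- stats::setNames(vals[i, ], cfg$networks)
    s <- render_parcellation(tg, cfg$fractions, lm, rm, seed = 1000 + i,
                             left_adj = la, right_adj = ra)
    achieved <- compute_nsar(s, lm, rm)
    expect_lt(max(abs(achieved - tg[names(achieved)])), 0.02)
  }
})

test_that("configuration validation catches bad inputs", {
  nets <- unname(yeo17_label_table())
  mu <- stats::setNames(numeric(17), nets)
  expect_error(simulation_config(10, mu = mu, loadings = matrix(0, 17, 2)),
               "seed")
  expect_error(simulation_config(10, mu = mu + 2,
                                 loadings = matrix(0, 17, 2), seed = 1),
               "<= 1")
  expect_error(simulation_config(10, mu = mu, sigma = 0,
                                 loadings = matrix(0, 17, 2), seed = 1),
               "sd")
  expect_error(simulation_config(10, mu = mu, loadings = matrix(0, 17, 2),
                                 factor_cov = matrix(c(1, 2, 2, 1), 2, 2),
                                 seed = 1),
               "positive definite")
})
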