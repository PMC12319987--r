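with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic population generator: planted
#' per-network mean NSAR and residual sd, a latent factor structure
#' driving cross-network covariation, covariate effect sizes, and the
#' rendering/run-noise settings. The seed is mandatory: all generators are
#' reproducible.
#'
#' @param n_subjects number of subjects.
#' @param networks character vector of network names (default the
#'   17-network scheme of [yeo17_label_table()]).
#' @param mu named numeric vector of planted mean NSAR per network
#'   (|mu| <= 1).
#' @param sigma residual standard deviation of NSAR (> 0), shared across
#'   networks.
#' @param loadings networks x factors matrix of factor loadings on the
#'   NSAR scale.
#' @param factor_cov factor covariance matrix (positive definite).
#' @param beta networks x 4 matrix of covariate effects (columns age, sex,
#'   handedness, mean_fd), applied to mean-centered covariates.
#' @param left_set,right_set names of the planted left-/right-lateralized
#'   networks (ground truth for recovery checks).
#' @param fractions named numeric vector: fraction of the total (two
#'   hemisphere) surface area occupied by each network; the remainder is
#'   medial wall (label 0).
#' @param seed integer seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects, networks = unname(yeo17_label_table()),
                              mu, sigma = 0.10, loadings, factor_cov = NULL,
                              beta = NULL, left_set = character(),
                              right_set = character(),
                              fractions = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  p <- length(networks)
  mu <- mu[networks]
  if (anyNA(mu)) stop("mu must name every network")
  if (any(abs(mu) > 1)) stop("|mean NSAR| must be <= 1")
  if (sigma <= 0) stop("residual sd must be > 0")
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != p) stop("loadings must have one row per network")
  if (is.null(factor_cov)) factor_cov <- diag(ncol(loadings))
  ev <- eigen(factor_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("factor covariance must be positive definite")
  if (is.null(beta)) beta <- matrix(0, p, 4L)
  colnames(beta) <- c("age", "sex", "handedness", "mean_fd")
  if (is.null(fractions))
    fractions <- stats::setNames(rep(0.90 / p, p), networks)
  if (sum(fractions) > 1 + 1e-9) stop("network area fractions must sum to <= 1")
  structure(list(n_subjects = as.integer(n_subjects), networks = networks,
                 mu = mu, sigma = sigma, loadings = loadings,
                 factor_cov = factor_cov, beta = beta,
                 left_set = left_set, right_set = right_set,
                 fractions = fractions, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Population covariance of network NSAR values implied by a config
#'
#' `Sigma = Lambda Phi Lambda' + sigma^2 I` (covariate effects excluded).
#' @param config a [simulation_config()].
#' @return p x p covariance matrix with network dimnames.
#' @export
implied_network_cov <- function(config) {
  S <- config$loadings %*% config$factor_cov %*% t(config$loadings) +
    diag(config$sigma^2, length(config$networks))
  dimnames(S) <- list(config$networks, config$networks)
  S
}

#' Implied correlation between averaged left- and right-lateralized NSAR
#'
#' The population Pearson correlation between the mean NSAR of the
#' planted left-lateralized networks and the mean NSAR of the planted
#' right-lateralized networks, computed from the implied covariance.
#' @param config a [simulation_config()].
#' @return scalar correlation.
#' @export
implied_left_right_cor <- function(config) {
  S <- implied_network_cov(config)
  wl <- as.numeric(config$networks %in% config$left_set)
  wr <- as.numeric(config$networks %in% config$right_set)
  wl <- wl / sum(wl); wr <- wr / sum(wr)
  as.numeric((wl %*% S %*% wr) /
               sqrt((wl %*% S %*% wl) * (wr %*% S %*% wr)))
}

#' Default study-like simulation configuration
#'
#' Plants the headline structure of the study the package models: among 17
#' networks, 3 left-lateralized (Language, Dorsal Attention-A, Default-C,
#' mean NSAR -0.25, -0.30, -0.15) and 5 right-lateralized (Visual-B +0.15,
#' Salience/VenAttn-A +0.10, Control-B +0.25, Control-C +0.15, Limbic-B
#' +0.35), residual sd 0.10, and two orthogonal latent factors: a bipolar
#' factor loading negatively on the left set and positively on the right
#' set, and a smaller second factor contrasting Language with Dorsal
#' Attention-A. The bipolar factor's loading scale is solved analytically
#' so that the implied correlation between averaged left- and
#' right-lateralized values equals `coupling` (default -0.65). Covariate
#' effects default to zero (none were reliably present in the study
#' conditions this emulates); covariate distributions mimic a young-adult
#' low-motion sample.
#'
#' @param n_subjects number of subjects (default 276).
#' @param coupling implied averaged left/right correlation (default -0.65).
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
default_simulation_config <- function(n_subjects = 276L, coupling = -0.65,
                                      seed = 1L) {
  networks <- unname(yeo17_label_table())
  p <- length(networks)
  left_set <- c("Language", "Dorsal Attention-A", "Default-C")
  right_set <- c("Visual-B", "Salience/VenAttn-A", "Control-B", "Control-C",
                 "Limbic-B")
  mu <- stats::setNames(numeric(p), networks)
  mu[c("Language", "Dorsal Attention-A", "Default-C")] <- c(-0.25, -0.30, -0.15)
  mu[right_set] <- c(0.15, 0.10, 0.25, 0.15, 0.35)
  sigma <- 0.10
  # second factor: Language vs Dorsal Attention-A contrast (fixed flavor)
  l2 <- stats::setNames(numeric(p), networks)
  l2[c("Language", "Dorsal Attention-A", "Limbic-B")] <- c(-0.06, 0.04, -0.026)
  build <- function(s) {
    l1 <- stats::setNames(numeric(p), networks)
    l1[left_set] <- -s
    l1[right_set] <- s
    cbind(F1 = l1, F2 = l2)
  }
  cfg_for <- function(s)
    simulation_config(n_subjects, networks, mu = mu, sigma = sigma,
                      loadings = build(s), left_set = left_set,
                      right_set = right_set, seed = seed)
  f <- function(s) implied_left_right_cor(cfg_for(s)) - coupling
  s <- stats::uniroot(f, c(1e-4, 0.5), tol = 1e-12)$root
  cfg_for(s)
}

#' Generate a synthetic NSAR population
#'
#' Subject-level NSAR = planted mean + loadings x latent factor scores +
#' covariate effects (on mean-centered covariates) + Gaussian residual,
#' clipped to \[-1, 1\] (with a warning if more than 1% of values are
#' clipped). Covariates: age ~ N(28.5, 3.6) years, sex ~ Bernoulli(0.5),
#' handedness a right-skewed Edinburgh score mixture, mean FD ~ N(0.08,
#' 0.02) mm floored at 0.03. Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return an [nsar_table()] with attribute `ground_truth` (the config
#'   plus factor scores and the implied left/right correlation).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- length(config$networks)
  n <- config$n_subjects
  with_seed(config$seed, {
    age <- stats::rnorm(n, 28.5, 3.6)
    sex <- stats::rbinom(n, 1L, 0.5)
    lefty <- stats::runif(n) < 0.10
    handedness <- ifelse(lefty, stats::rnorm(n, -40, 30),
                         stats::rnorm(n, 65, 25))
    handedness <- pmin(pmax(handedness, -100), 100)
    mean_fd <- pmax(stats::rnorm(n, 0.08, 0.02), 0.03)
    scores <- MASS::mvrnorm(n, mu = rep(0, ncol(config$loadings)),
                            Sigma = config$factor_cov)
    scores <- matrix(scores, nrow = n)
    E <- matrix(stats::rnorm(n * p, 0, config$sigma), n, p)
    Xc <- scale(cbind(age, sex, handedness, mean_fd), scale = FALSE)
    vals <- matrix(config$mu, n, p, byrow = TRUE) +
      scores %*% t(config$loadings) + Xc %*% t(config$beta) + E
    clipped <- vals < -1 | vals > 1
    if (mean(clipped) > 0.01)
      warning(sprintf("%.1f%% of NSAR values clipped to [-1, 1]",
                      100 * mean(clipped)))
    vals <- pmin(pmax(vals, -1), 1)
    colnames(vals) <- config$networks
    covs <- data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
                       age = age, sex = sex, handedness = handedness,
                       mean_fd = mean_fd)
    out <- nsar_table(vals, covs, adjusted = FALSE)
    attr(out, "ground_truth") <- list(
      config = config, factor_scores = scores,
      implied_left_right_cor = implied_left_right_cor(config))
    out
  })
}

#' Render a labeled parcellation achieving target NSAR values
#'
#' Inverse of [compute_nsar()]: allocates seeded, mostly contiguous vertex
#' patches on the two hemisphere meshes so that each network's achieved
#' NSAR is within about +/-0.02 of its target (exact at the +/-1
#' endpoints, where a network is placed on a single hemisphere). Network
#' k's total area is `fractions[k]` times the combined mesh area, split
#' across hemispheres as `(1 - t)/2 : (1 + t)/2` for target t. Region
#' growing claims unassigned vertices breadth-first from a random seed
#' vertex, jumping to a fresh patch when a region is walled in. Unclaimed
#' vertices keep label 0 (medial wall).
#'
#' @param targets named numeric vector of target NSAR values, one per
#'   network of `label_table` (|target| <= 1).
#' @param fractions named numeric vector of total-area fractions (sums to
#'   <= 1).
#' @param left_mesh,right_mesh [surface_mesh()] templates.
#' @param seed integer seed.
#' @param label_table label table (default [yeo17_label_table()]).
#' @param subject_id id for the returned parcellation.
#' @param left_adj,right_adj optional precomputed [mesh_adjacency()] lists
#'   (reuse across subjects for speed).
#' @return a [subject_parcellation()].
#' @export
render_parcellation <- function(targets, fractions, left_mesh, right_mesh,
                                seed, label_table = yeo17_label_table(),
                                subject_id = "synthetic",
                                left_adj = NULL, right_adj = NULL) {
  nets <- unname(label_table)
  ids <- names_to_ids(label_table)
  targets <- targets[nets]
  fractions <- fractions[nets]
  if (anyNA(targets) || anyNA(fractions))
    stop("targets and fractions must name every network in label_table")
  if (any(abs(targets) > 1)) stop("|targets| must be <= 1")
  if (sum(fractions) > 1 + 1e-9) stop("fractions must sum to <= 1")
  if (is.null(left_adj)) left_adj <- mesh_adjacency(left_mesh)
  if (is.null(right_adj)) right_adj <- mesh_adjacency(right_mesh)
  A_total <- sum(left_mesh$vertex_area) + sum(right_mesh$vertex_area)
  T_k <- fractions * A_total
  tgt_left <- T_k * (1 - targets) / 2
  tgt_right <- T_k * (1 + targets) / 2
  if (sum(tgt_left) > sum(left_mesh$vertex_area) ||
      sum(tgt_right) > sum(right_mesh$vertex_area))
    stop("infeasible targets: hemisphere capacity exceeded")
  with_seed(seed, {
    lab_l <- grow_regions(tgt_left, ids, left_mesh$vertex_area, left_adj)
    lab_r <- grow_regions(tgt_right, ids, right_mesh$vertex_area, right_adj)
    subject_parcellation(
      subject_id,
      parcellation(lab_l, label_table, "left"),
      parcellation(lab_r, label_table, "right"))
  })
}

# Sequential seeded region growing on one hemisphere. Tiny targets
# (below half the smallest vertex area) get no vertices, making the
# +/-1 NSAR endpoints exact.
grow_regions <- function(tgt, ids, va, adj) {
  nv <- length(va)
  labels <- integer(nv)
  unclaimed <- rep(TRUE, nv)
  min_tgt <- min(va) / 2
  for (k in sample(seq_along(ids))) {
    goal <- tgt[k]
    if (goal < min_tgt) next
    area <- 0
    frontier <- integer(0)
    repeat {
      v <- 0L
      while (length(frontier)) {
        cand <- frontier[1L]
        frontier <- frontier[-1L]
        if (unclaimed[cand]) { v <- cand; break }
      }
      if (v == 0L) {
        pool <- which(unclaimed)
        if (!length(pool)) break
        v <- pool[sample.int(length(pool), 1L)]
      }
      overshoot <- area + va[v] - goal
      if (overshoot > 0 && overshoot > goal - area) break
      labels[v] <- ids[k]
      unclaimed[v] <- FALSE
      area <- area + va[v]
      nb <- adj[[v]]
      frontier <- c(frontier, nb[unclaimed[nb]])
      if (area >= goal) break
    }
  }
  labels
}

#' Run-to-run parcellation perturbations
#'
#' Emulates run-level parcellation variability: each run independently
#' reassigns a fraction of the label-boundary vertices (nonzero-labeled
#' vertices adjacent to a different nonzero label) to a neighbouring
#' network's label. Label-0 territory is never created or consumed.
#'
#' @param subject a [subject_parcellation()].
#' @param n_runs number of runs (>= 1).
#' @param boundary_noise fraction of boundary vertices resampled, in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @param left_adj,right_adj optional precomputed adjacency lists for the
#'   two hemisphere meshes.
#' @param left_mesh,right_mesh meshes (needed if adjacencies not given).
#' @return list of `n_runs` perturbed [subject_parcellation()] objects.
#' @export
generate_runs <- function(subject, n_runs, boundary_noise, seed,
                          left_mesh = NULL, right_mesh = NULL,
                          left_adj = NULL, right_adj = NULL) {
  stopifnot(inherits(subject, "subject_parcellation"))
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (boundary_noise < 0 || boundary_noise >= 1)
    stop("boundary_noise must be in [0, 1)")
  if (is.null(left_adj)) left_adj <- mesh_adjacency(left_mesh)
  if (is.null(right_adj)) right_adj <- mesh_adjacency(right_mesh)
  perturb <- function(labels, adj) {
    nz <- which(labels != 0L)
    boundary <- nz[vapply(nz, function(v) {
      nb_lab <- labels[adj[[v]]]
      any(nb_lab != 0L & nb_lab != labels[v])
    }, TRUE)]
    n_flip <- round(boundary_noise * length(boundary))
    if (n_flip < 1L) return(labels)
    flip <- sample(boundary, n_flip)
    new_labels <- labels
    for (v in flip) {
      opts <- setdiff(unique(labels[adj[[v]]]), c(0L, labels[v]))
      if (length(opts))
        new_labels[v] <- opts[sample.int(length(opts), 1L)]
    }
    new_labels
  }
  with_seed(seed, {
    lapply(seq_len(n_runs), function(r) {
      subject_parcellation(
        paste0(subject$subject_id, "_run", r),
        parcellation(perturb(subject$left$labels, left_adj),
                     subject$left$label_table, "left"),
        parcellation(perturb(subject$right$labels, right_adj),
                     subject$right$label_table, "right"))
    })
  })
}

#' Block-structured synthetic connectivity profile
#'
#' Builds a vertex-by-vertex correlation matrix from a per-network latent
#' factor model: vertex v in network k gets a factor loading `a_v` with
#' `a_v^2 ~ U(0.3, 0.8)`, the left and right factors of network k are
#' correlated `homotopy`, and off-network correlations are near zero plus
#' noise. The construction is positive semidefinite by design before the
#' noise; if noise breaks that, it is halved and re-applied (error after 5
#' attempts). Intended for small meshes (<= ~2000 vertices in total).
#'
#' @param subject a [subject_parcellation()].
#' @param homotopy weight in `[0, 1]`: correlation between a network's
#'   left and right factors (1 = contralateral as strong as ipsilateral).
#' @param within_network_r scales the within-network loading range.
#' @param seed integer seed.
#' @param noise_sd sd of the symmetric perturbation (default 0.005).
#' @param threshold correlation cutoff stored in the profile.
#' @return a [connectivity_profile()].
#' @export
generate_connectivity <- function(subject, homotopy, within_network_r = 1,
                                  seed = 1L, noise_sd = 0.005,
                                  threshold = 0.25) {
  stopifnot(inherits(subject, "subject_parcellation"))
  if (homotopy < 0 || homotopy > 1) stop("homotopy must be in [0, 1]")
  labels <- c(subject$left$labels, subject$right$labels)
  hemi <- rep(c("left", "right"),
              c(length(subject$left$labels), length(subject$right$labels)))
  nv <- length(labels)
  if (nv > 2000L) stop("generate_connectivity is meant for small meshes (<= 2000 vertices)")
  ids <- names_to_ids(subject$left$label_table)
  with_seed(seed, {
    a <- sqrt(stats::runif(nv, 0.3, 0.8)) * sqrt(within_network_r)
    a[labels == 0L] <- 0
    # loading matrix onto per-network left/right factors
    L <- matrix(0, nv, 2L * length(ids))
    for (j in seq_along(ids)) {
      sel_l <- labels == ids[j] & hemi == "left"
      sel_r <- labels == ids[j] & hemi == "right"
      L[sel_l, 2L * j - 1L] <- a[sel_l]
      L[sel_r, 2L * j] <- a[sel_r]
    }
    Phi <- diag(2L * length(ids))
    for (j in seq_along(ids)) {
      Phi[2L * j - 1L, 2L * j] <- Phi[2L * j, 2L * j - 1L] <- homotopy
    }
    R0 <- L %*% Phi %*% t(L)
    diag(R0) <- 1
    for (attempt in seq_len(5L)) {
      N <- matrix(stats::rnorm(nv * nv, 0, noise_sd), nv, nv)
      N <- (N + t(N)) / 2
      diag(N) <- 0
      R <- R0 + N
      R <- pmin(pmax(R, -1), 1)
      ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min > -1e-8)
        return(connectivity_profile(R, hemi, threshold = threshold))
      noise_sd <- noise_sd / 2
    }
    stop("could not produce a positive semidefinite profile after 5 attempts")
  })
}
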