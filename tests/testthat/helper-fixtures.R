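# Shared fixtures and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

get_ico <- function(subdivisions, hemisphere) {
  key <- paste0("ico", subdivisions, hemisphere)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- icosphere(subdivisions, hemisphere = hemisphere)
  .fixture_cache[[key]]
}

get_adj <- function(subdivisions, hemisphere) {
  key <- paste0("adj", subdivisions, hemisphere)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- mesh_adjacency(get_ico(subdivisions, hemisphere))
  .fixture_cache[[key]]
}

# right triangle with legs `leg` in the xy plane (area leg^2 / 2)
tri_mesh <- function(leg = 1, hemisphere = "left") {
  surface_mesh(rbind(c(0, 0, 0), c(leg, 0, 0), c(0, leg, 0)),
               rbind(c(1, 2, 3)), hemisphere)
}

# unit square split into two triangles (total area 1)
square_mesh <- function(hemisphere = "left") {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3), c(1, 3, 4)), hemisphere)
}

toy_label_table <- function(ids) {
  stats::setNames(paste0("Net", ids), as.character(ids))
}

toy_subject <- function(left_labels, right_labels, id = "toy",
                        label_table = NULL) {
  if (is.null(label_table)) {
    ids <- setdiff(sort(unique(c(left_labels, right_labels))), 0L)
    label_table <- toy_label_table(ids)
  }
  subject_parcellation(
    id,
    parcellation(left_labels, label_table, "left"),
    parcellation(right_labels, label_table, "right"))
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(perms(n - 1L), function(p) {
      rest <- setdiff(seq_len(n), i)
      c(i, rest[p])
    })
  }))
}

# exhaustive-search assignment oracle
brute_force_min_cost <- function(C) {
  n <- nrow(C)
  min(vapply(perms(n), function(p) sum(C[cbind(seq_len(n), p)]), 0))
}

# literal 2^n sign-assignment oracle for the signed-rank test
wilcoxon_enum_oracle <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  V_all <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, 0)
  p <- min(1, 2 * min(mean(V_all <= V_obs), mean(V_all >= V_obs)))
  list(V = V_obs, p = p)
}

# quick covariate frame for hand-built NSAR tables
toy_covariates <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = rnorm(n, 28, 3), sex = rbinom(n, 1, 0.5),
    handedness = runif(n, -100, 100), mean_fd = runif(n, 0.04, 0.14)))
}
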