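#' Network surface area ratio (NSAR)
#'
#' The package's core lateralization statistic. For each network k with
#' left- and right-hemisphere surface areas `LH_SA` and `RH_SA`,
#'
#'   `NSAR_k = (RH_SA - LH_SA) / (LH_SA + RH_SA)`.
#'
#' No scaling factor enters the denominator, so values are hard-bounded to
#' \[-1, 1\]: negative values indicate left-hemisphere lateralization,
#' positive values right-hemisphere lateralization, and the endpoints are
#' attained when a network occupies only one hemisphere. A network absent
#' from both hemispheres has an undefined ratio and is returned as `NA`,
#' never imputed.
#'
#' @param subject a [subject_parcellation()].
#' @param left_mesh,right_mesh [surface_mesh()] objects matching the two
#'   parcellations.
#' @return named numeric vector (one value per label-table network).
#' @export
compute_nsar <- function(subject, left_mesh, right_mesh) {
  stopifnot(inherits(subject, "subject_parcellation"))
  tab <- subject$left$label_table
  ids <- names_to_ids(tab)
  la <- left_mesh$vertex_area
  ra <- right_mesh$vertex_area
  out <- vapply(ids, function(id) {
    L <- sum(la[subject$left$labels == id])
    R <- sum(ra[subject$right$labels == id])
    if (L + R == 0) NA_real_ else (R - L) / (L + R)
  }, 0)
  names(out) <- unname(tab)
  out
}

#' Assemble an NSAR table
#'
#' Rows are subjects, one column per network, plus the four covariates the
#' downstream models use: `age` (years), `sex` (0/1), `handedness`
#' (Edinburgh Handedness Inventory, -100..100) and `mean_fd` (mm).
#'
#' @param values numeric matrix or data.frame, subjects x networks, with
#'   column names naming the networks.
#' @param covariates data.frame with columns `subject_id`, `age`, `sex`,
#'   `handedness`, `mean_fd` (one row per subject, same order).
#' @param adjusted logical flag: have covariate effects been regressed out?
#' @return a data.frame of class `nsar_table` with attributes `networks`
#'   and `adjusted`.
#' @export
nsar_table <- function(values, covariates, adjusted = FALSE) {
  values <- as.data.frame(values)
  need <- c("subject_id", "age", "sex", "handedness", "mean_fd")
  if (!all(need %in% names(covariates)))
    stop("covariates must contain: ", paste(need, collapse = ", "))
  if (nrow(values) != nrow(covariates))
    stop("values and covariates have different row counts")
  rng <- range(as.matrix(values), na.rm = TRUE)
  if (rng[1L] < -1 || rng[2L] > 1)
    stop("NSAR values must lie in [-1, 1]")
  out <- cbind(covariates[need], values)
  attr(out, "networks") <- names(values)
  attr(out, "adjusted") <- isTRUE(adjusted)
  class(out) <- c("nsar_table", "data.frame")
  out
}

#' Networks of an NSAR table
#' @param table an [nsar_table()].
#' @return character vector of network column names.
#' @export
nsar_networks <- function(table) attr(table, "networks")

covariate_design <- function(table) {
  cc <- c("age", "sex", "handedness", "mean_fd")
  X <- as.matrix(table[cc])
  if (anyNA(X)) stop("covariates contain missing values")
  # age and mean FD enter mean-centered; sex and handedness raw
  X[, "age"] <- X[, "age"] - mean(X[, "age"])
  X[, "mean_fd"] <- X[, "mean_fd"] - mean(X[, "mean_fd"])
  colnames(X) <- c("c_age", "sex", "handedness", "c_mean_fd")
  X
}

#' Covariate-adjusted NSAR values
#'
#' Per network, ordinary least squares of raw NSAR on mean-centered age,
#' mean-centered mean framewise displacement, sex and handedness; the
#' adjusted value subtracts each fitted effect measured from the sample
#' mean of its covariate:
#'
#'   `adjusted = raw - sum_i beta_i * (x_i - mean(x_i))`.
#'
#' A subject whose covariates all sit at the sample means keeps its raw
#' value exactly, and re-adjusting an adjusted table is a no-op (the refit
#' coefficients vanish). Adjustment is done separately per network.
#'
#' @param table a raw [nsar_table()] with complete covariates.
#' @return an [nsar_table()] flagged as adjusted.
#' @export
adjust_nsar <- function(table) {
  stopifnot(inherits(table, "nsar_table"))
  nets <- nsar_networks(table)
  X <- covariate_design(table)
  Xc <- scale(X, center = TRUE, scale = FALSE)  # effects measured from means
  if (nrow(table) < ncol(Xc) + 2L)
    stop("need at least ", ncol(Xc) + 2L, " subjects")
  if (any(apply(Xc, 2L, function(x) all(x == 0))))
    stop("constant covariate column: singular adjustment fit")
  vals <- as.matrix(table[nets])
  fit <- stats::lm.fit(cbind(1, Xc), vals)
  beta <- fit$coefficients[-1L, , drop = FALSE]
  adjusted <- vals - Xc %*% beta
  out <- table
  out[nets] <- as.data.frame(adjusted)
  attr(out, "adjusted") <- TRUE
  out
}

#' Vertex-wise connectivity profile
#'
#' Container for a symmetric cross-hemisphere vertex correlation matrix
#' used by the autonomy index.
#'
#' @param R symmetric numeric matrix with entries in `[-1, 1]` spanning the
#'   vertices of both hemispheres (left block first).
#' @param hemisphere character vector (`"left"`/`"right"`), one entry per
#'   row of `R`.
#' @param threshold correlation cutoff in (-1, 1) above which a connection
#'   counts; default 0.25.
#' @return object of class `connectivity_profile`.
#' @export
connectivity_profile <- function(R, hemisphere, threshold = 0.25) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("connectivity matrix must be square")
  if (length(hemisphere) != nrow(R))
    stop("hemisphere vector must have one entry per vertex")
  if (!all(hemisphere %in% c("left", "right")))
    stop("hemisphere entries must be 'left' or 'right'")
  if (max(abs(R - t(R))) > 1e-8) stop("connectivity matrix must be symmetric")
  off <- R[upper.tri(R)]
  if (length(off) && (min(off) < -1 || max(off) > 1))
    stop("correlations must lie in [-1, 1]")
  if (threshold <= -1 || threshold >= 1) stop("threshold must be in (-1, 1)")
  structure(list(R = R, hemisphere = hemisphere, threshold = threshold),
            class = "connectivity_profile")
}

#' Autonomy index per network
#'
#' A count-based functional measure of hemispheric specialization used as
#' a convergent-validity companion to NSAR. For each vertex v,
#'
#'   `AI(v) = n_ipsi(v) / N_ipsi - n_contra(v) / N_contra`,
#'
#' where `n_ipsi` / `n_contra` count the supra-threshold correlations from
#' v to vertices of its own / the opposite hemisphere and `N_ipsi` /
#' `N_contra` are the hemisphere vertex counts. The per-network index
#' averages AI(v) over the network's vertices on both hemispheres, so it
#' is positive for hemispherically autonomous (specialized) networks
#' regardless of which hemisphere hosts them. Because of that, its
#' correlation with NSAR across subjects is negative for left-lateralized
#' networks and positive for right-lateralized ones — the convergent
#' validity signature this index is used for. `sign_flip = TRUE` negates
#' the output (the opposite sign convention of the index family this
#' reimplements).
#'
#' @param profile a [connectivity_profile()].
#' @param parc a [subject_parcellation()] on the same vertex sets.
#' @param sign_flip negate the output?
#' @return named numeric vector, one value per network.
#' @export
autonomy_index <- function(profile, parc, sign_flip = FALSE) {
  stopifnot(inherits(profile, "connectivity_profile"),
            inherits(parc, "subject_parcellation"))
  labels <- c(parc$left$labels, parc$right$labels)
  if (length(labels) != nrow(profile$R))
    stop("parcellation and connectivity profile vertex sets disagree")
  hemi <- profile$hemisphere
  n_left <- sum(hemi == "left"); n_right <- sum(hemi == "right")
  A <- profile$R > profile$threshold
  diag(A) <- FALSE
  to_left <- rowSums(A[, hemi == "left", drop = FALSE])
  to_right <- rowSums(A[, hemi == "right", drop = FALSE])
  ai_v <- ifelse(hemi == "left",
                 to_left / n_left - to_right / n_right,
                 to_right / n_right - to_left / n_left)
  tab <- parc$left$label_table
  out <- vapply(names_to_ids(tab), function(id) {
    sel <- labels == id
    if (!any(sel)) return(NA_real_)
    mean(ai_v[sel])
  }, 0)
  names(out) <- unname(tab)
  if (sign_flip) -out else out
}
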