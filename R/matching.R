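#' Label-by-label overlap matrix of two subject parcellations
#'
#' Entry (i, j) counts the vertices (or sums the vertex areas) labeled
#' `ids[i]` in `parcA` and `ids[j]` in `parcB`, pooled across the two
#' hemispheres. Vertices carrying label 0 in either parcellation are
#' excluded, so the entries sum to the vertices (area) assigned in both.
#'
#' @param parcA,parcB [subject_parcellation()] objects on the same meshes.
#' @param weighting `"vertex_count"` or `"area"`; area weighting requires
#'   `left_mesh` and `right_mesh`.
#' @param left_mesh,right_mesh [surface_mesh()] objects (area weighting only).
#' @param ids integer label ids indexing the matrix; defaults to the ids of
#'   the shared label table.
#' @return K x K numeric matrix with `dimnames` set to `ids`.
#' @export
overlap_matrix <- function(parcA, parcB,
                           weighting = c("vertex_count", "area"),
                           left_mesh = NULL, right_mesh = NULL,
                           ids = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(parcA, "subject_parcellation"),
            inherits(parcB, "subject_parcellation"))
  if (length(parcA$left$labels) != length(parcB$left$labels) ||
      length(parcA$right$labels) != length(parcB$right$labels))
    stop("parcellations have different vertex counts")
  if (is.null(ids))
    ids <- sort(unique(c(names_to_ids(parcA$left$label_table),
                         names_to_ids(parcB$left$label_table))))
  a <- c(parcA$left$labels, parcA$right$labels)
  b <- c(parcB$left$labels, parcB$right$labels)
  w <- if (weighting == "area") {
    if (is.null(left_mesh) || is.null(right_mesh))
      stop("area weighting requires left_mesh and right_mesh")
    c(left_mesh$vertex_area, right_mesh$vertex_area)
  } else rep(1, length(a))
  keep <- a != 0L & b != 0L
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (any(keep)) {
    tab <- tapply(w[keep],
                  list(factor(a[keep], levels = ids),
                       factor(b[keep], levels = ids)),
                  sum, default = 0)
    m[] <- tab
  }
  m
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix with the
#' O(K^3) Hungarian (Kuhn-Munkres) algorithm. For matching an individual's
#' clusters to a reference network scheme, use `cost = -overlap_matrix(...)`
#' so the maximal-overlap assignment minimizes cost. Ties between equally
#' optimal assignments are broken deterministically (lowest index first,
#' following the row scan order).
#'
#' @param cost_matrix finite square numeric matrix; rows index individual
#'   cluster ids, columns reference network ids.
#' @return object of class `assignment_result`: list with `mapping`
#'   (data.frame `from`, `to` of row -> column indices), `total_cost`, and
#'   the input `cost_matrix`.
#' @export
hungarian_match <- function(cost_matrix) {
  C <- as.matrix(cost_matrix)
  if (nrow(C) != ncol(C)) stop("cost matrix must be square")
  if (any(!is.finite(C))) stop("cost matrix must be finite")
  n <- nrow(C)
  # Potentials-and-augmenting-paths formulation; index 1 holds the dummy
  # row/column 0.
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- C[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      minv[free_j[upd] + 1L] <- cur[upd]
      way[free_j[upd] + 1L] <- j0
      k <- which.min(minv[free_j + 1L])
      delta <- minv[free_j[k] + 1L]
      j1 <- free_j[k]
      uidx <- which(used)
      rows <- p[uidx]
      u[rows + 1L] <- u[rows + 1L] + delta
      v[uidx] <- v[uidx] - delta
      minv[-uidx] <- minv[-uidx] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  to <- integer(n)
  to[p[-1L]] <- seq_len(n)
  mapping <- data.frame(from = seq_len(n), to = to)
  structure(list(mapping = mapping,
                 total_cost = sum(C[cbind(mapping$from, mapping$to)]),
                 cost_matrix = C),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("assignment_result: ", nrow(x$mapping), " ids, total cost ",
      format(x$total_cost), "\n", sep = "")
  invisible(x)
}

#' Relabel a subject parcellation under an assignment
#'
#' Replaces every nonzero label by its assigned reference id; label 0 and
#' the vertex geometry are untouched.
#'
#' @param parc a [subject_parcellation()].
#' @param assignment an `assignment_result` from [hungarian_match()], or a
#'   named integer vector (names = old ids, values = new ids).
#' @param label_table optional label table for the relabeled parcellation;
#'   defaults to the reference ids named by the original table's entries.
#' @return a relabeled [subject_parcellation()].
#' @export
relabel <- function(parc, assignment, label_table = NULL) {
  map <- if (inherits(assignment, "assignment_result")) {
    stats::setNames(assignment$mapping$to, assignment$mapping$from)
  } else {
    stats::setNames(as.integer(assignment), names(assignment))
  }
  remap <- function(labels) {
    out <- labels
    nz <- labels != 0L
    hit <- match(as.character(labels[nz]), names(map))
    if (anyNA(hit))
      stop("unmapped nonzero label(s): ",
           paste(unique(labels[nz][is.na(hit)]), collapse = ", "))
    out[nz] <- as.integer(map[hit])
    out
  }
  if (is.null(label_table)) {
    old <- parc$left$label_table
    hit <- match(names(old), names(map))
    keep <- !is.na(hit)
    label_table <- stats::setNames(unname(old[keep]),
                                   as.character(map[hit[keep]]))
    label_table <- label_table[order(as.integer(names(label_table)))]
  }
  subject_parcellation(
    parc$subject_id,
    parcellation(remap(parc$left$labels), label_table, "left"),
    parcellation(remap(parc$right$labels), label_table, "right"))
}

#' Dice overlap between two matched parcellations
#'
#' Per-network dice is `2 |A_k intersect B_k| / (|A_k| + |B_k|)` with sizes
#' as vertex counts or vertex areas, pooled across hemispheres; the overall
#' coefficient combines networks by their sizes:
#' `2 sum_k |A_k intersect B_k| / sum_k (|A_k| + |B_k|)`. Label-0 vertices
#' are excluded throughout. A network absent from both parcellations has an
#' undefined coefficient and is reported as `NA` (and contributes nothing
#' to the overall value).
#'
#' @inheritParams overlap_matrix
#' @param mode `"overall"` or `"per_network"`.
#' @return a scalar in `[0, 1]` for `"overall"`; a named numeric vector
#'   (possibly with `NA`) for `"per_network"`.
#' @export
dice <- function(parcA, parcB, mode = c("overall", "per_network"),
                 weighting = c("vertex_count", "area"),
                 left_mesh = NULL, right_mesh = NULL) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  stopifnot(inherits(parcA, "subject_parcellation"),
            inherits(parcB, "subject_parcellation"))
  if (length(parcA$left$labels) != length(parcB$left$labels) ||
      length(parcA$right$labels) != length(parcB$right$labels))
    stop("parcellations have different vertex counts")
  a <- c(parcA$left$labels, parcA$right$labels)
  b <- c(parcB$left$labels, parcB$right$labels)
  w <- if (weighting == "area") {
    if (is.null(left_mesh) || is.null(right_mesh))
      stop("area weighting requires left_mesh and right_mesh")
    c(left_mesh$vertex_area, right_mesh$vertex_area)
  } else rep(1, length(a))
  ids <- sort(unique(c(names_to_ids(parcA$left$label_table),
                       names_to_ids(parcB$left$label_table))))
  inter <- vapply(ids, function(k) sum(w[a == k & b == k]), 0)
  sizes <- vapply(ids, function(k) sum(w[a == k]) + sum(w[b == k]), 0)
  per <- ifelse(sizes > 0, 2 * inter / sizes, NA_real_)
  names(per) <- ids
  if (mode == "per_network") return(per)
  present <- sizes > 0
  if (!any(present)) stop("both parcellations are empty (all label 0)")
  2 * sum(inter[present]) / sum(sizes[present])
}
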