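#' Per-vertex network parcellation of one hemisphere
#'
#' @param labels integer vector, one network id per vertex. 0 marks the
#'   medial wall / unassigned vertices and is excluded from all network
#'   statistics.
#' @param label_table named character vector mapping id (name of element,
#'   as a string) to network name. Every nonzero id occurring in `labels`
#'   must be present.
#' @param hemisphere `"left"` or `"right"`.
#' @return object of class `parcellation`.
#' @export
parcellation <- function(labels, label_table, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must not contain NA")
  ids <- as.integer(names(label_table))
  if (anyNA(ids)) stop("label_table names must be integer ids")
  used <- setdiff(unique(labels), 0L)
  missing_ids <- setdiff(used, ids)
  if (length(missing_ids))
    stop("labels contain ids absent from label_table: ",
         paste(missing_ids, collapse = ", "))
  structure(list(hemisphere = hemisphere, labels = labels,
                 label_table = label_table),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %s hemisphere, %d vertices, %d networks (%d unassigned)\n",
              x$hemisphere, length(x$labels),
              length(setdiff(unique(x$labels), 0L)), sum(x$labels == 0L)))
  invisible(x)
}

#' Paired left/right parcellation for one subject
#'
#' @param subject_id character scalar.
#' @param left,right [parcellation()] objects for the two hemispheres; they
#'   must share one label table.
#' @return object of class `subject_parcellation`.
#' @export
subject_parcellation <- function(subject_id, left, right) {
  stopifnot(inherits(left, "parcellation"), inherits(right, "parcellation"))
  if (left$hemisphere != "left" || right$hemisphere != "right")
    stop("'left' must be a left-hemisphere and 'right' a right-hemisphere parcellation")
  if (!identical(left$label_table, right$label_table))
    stop("left and right parcellations must share one label table")
  structure(list(subject_id = as.character(subject_id),
                 left = left, right = right),
            class = "subject_parcellation")
}

#' @export
print.subject_parcellation <- function(x, ...) {
  cat(sprintf("subject_parcellation '%s': %d + %d vertices, %d networks\n",
              x$subject_id, length(x$left$labels), length(x$right$labels),
              length(x$left$label_table)))
  invisible(x)
}

#' Default 17-network label table
#'
#' Network names follow the widely used 17-network resting-state scheme
#' (visual, somatomotor, attention, salience, limbic, control, default and
#' language/temporoparietal divisions), ids 1..17.
#'
#' @return named character vector of length 17 (names are the ids).
#' @export
yeo17_label_table <- function() {
  nets <- c("Visual-A", "Visual-B", "Somatomotor-A", "Somatomotor-B",
            "Dorsal Attention-A", "Dorsal Attention-B",
            "Salience/VenAttn-A", "Salience/VenAttn-B",
            "Limbic-A", "Limbic-B", "Control-A", "Control-B", "Control-C",
            "Default-A", "Default-B", "Default-C", "Language")
  names(nets) <- as.character(seq_along(nets))
  nets
}
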