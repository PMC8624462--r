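#' Construct an annotation dataset
#'
#' Bundles a table of landmark observations with the catalog they refer to.
#' One observation is one landmark located by one operator in one session
#' for one subject, with its position in mm in the scanner coordinate
#' system.
#'
#' @param observations A data frame with columns `subject_id`,
#'   `operator_id`, `session_id`, `landmark`, `x`, `y`, `z` (mm) and
#'   optionally logical columns `missing` and `outlier_removed` (both
#'   default `FALSE`).
#' @param catalog A `landmark_catalog`; defaults to [default_catalog()].
#' @return An object of class `annotation_dataset`: a list with elements
#'   `observations`, `catalog` and `design` (named counts `n_subjects`,
#'   `n_operators`, `n_sessions`).
#' @seealso [read_annotations()], [write_annotations()]
#' @export
annotation_dataset <- function(observations, catalog = default_catalog()) {
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  required <- c("subject_id", "operator_id", "session_id", "landmark",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    stop("observations are missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"missing" %in% names(obs)) obs$missing <- rep(FALSE, nrow(obs))
  if (!"outlier_removed" %in% names(obs)) {
    obs$outlier_removed <- rep(FALSE, nrow(obs))
  }
  obs$subject_id  <- as.character(obs$subject_id)
  obs$operator_id <- as.character(obs$operator_id)
  obs$session_id  <- as.character(obs$session_id)
  obs$landmark    <- as.character(obs$landmark)
  for (v in c("x", "y", "z")) obs[[v]] <- as.numeric(obs[[v]])
  obs$missing <- as.logical(obs$missing)
  obs$outlier_removed <- as.logical(obs$outlier_removed)
  obs <- obs[required_cols_first(obs)]
  rownames(obs) <- NULL

  ds <- structure(
    list(observations = obs, catalog = catalog, design = dataset_design(obs)),
    class = "annotation_dataset"
  )
  validate_dataset(ds)
  ds
}

required_cols_first <- function(obs) {
  lead <- c("subject_id", "operator_id", "session_id", "landmark",
            "x", "y", "z", "missing", "outlier_removed")
  c(lead, setdiff(names(obs), lead))
}

dataset_design <- function(obs) {
  c(n_subjects  = length(unique(obs$subject_id)),
    n_operators = length(unique(obs$operator_id)),
    n_sessions  = length(unique(obs$session_id)))
}

#' Validate an annotation dataset
#'
#' Checks that every observation refers to a catalog landmark, that
#' (subject, operator, session, landmark) keys are unique, that positions
#' are finite unless flagged missing, and that the stored design matches
#' the identifiers present.
#'
#' @param dataset An `annotation_dataset`.
#' @return The dataset, invisibly, if valid.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "annotation_dataset"))
  obs <- dataset$observations
  unknown <- setdiff(unique(obs$landmark), dataset$catalog$name)
  if (length(unknown)) {
    stop("unknown landmark name(s) not in catalog: ",
         paste(unknown, collapse = ", "))
  }
  key <- paste(obs$subject_id, obs$operator_id, obs$session_id, obs$landmark,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- obs[duplicated(key), c("subject_id", "operator_id",
                                  "session_id", "landmark")]
    stop("duplicate (subject, operator, session, landmark) keys, e.g. ",
         paste(unlist(dup[1, ]), collapse = "/"))
  }
  pos_ok <- is.finite(obs$x) & is.finite(obs$y) & is.finite(obs$z)
  if (any(!pos_ok & !obs$missing)) {
    stop("non-finite coordinates in observations not flagged as missing")
  }
  if (!identical(unname(dataset$design), unname(dataset_design(obs)))) {
    stop("stored design does not match identifiers present in observations")
  }
  invisible(dataset)
}

# Observations usable for statistics: neither missing nor removed as outliers.
active_observations <- function(dataset) {
  obs <- dataset$observations
  obs[!obs$missing & !obs$outlier_removed, , drop = FALSE]
}

#' @export
print.annotation_dataset <- function(x, ...) {
  d <- x$design
  cat("Annotation dataset: ", nrow(x$observations), " observations\n",
      "  subjects: ", d["n_subjects"],
      "  operators: ", d["n_operators"],
      "  sessions: ", d["n_sessions"],
      "  landmarks: ", length(unique(x$observations$landmark)), "\n",
      sep = "")
  flagged <- sum(x$observations$missing | x$observations$outlier_removed)
  if (flagged) cat("  flagged missing/outlier:", flagged, "\n")
  invisible(x)
}
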