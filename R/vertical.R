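#' Session-wise Frankfort Horizontal planes
#'
#' Builds, from one operator's annotations in one session, the
#' conventional FH plane (through that session's Or-L, Po-R, Po-L) and
#' the novel FH plane (through Or-R, Or-L and the midpoint of IAF-L and
#' IAF-R), both oriented toward `superior_hint`.
#'
#' @param dataset An [annotation_dataset()].
#' @param subject,operator,session Identifiers of the session.
#' @param superior_hint 3-vector fixing the superior side of both planes.
#' @return A list with elements `conventional` and `novel`, both
#'   `ceph_plane`.
#' @export
session_planes <- function(dataset, subject, operator, session,
                           superior_hint = c(0, 0, 1)) {
  obs <- active_observations(dataset)
  sel <- obs$subject_id == subject & obs$operator_id == operator &
    obs$session_id == session
  obs <- obs[sel, , drop = FALSE]
  need <- c("Or-L", "Or-R", "Po-R", "Po-L", "IAF-L", "IAF-R")
  have <- need %in% obs$landmark
  if (!all(have)) {
    stop("session ", subject, "/", operator, "/", session,
         " skipped: missing landmark(s) ",
         paste(need[!have], collapse = ", "))
  }
  pt <- function(nm) {
    i <- match(nm, obs$landmark)
    c(obs$x[i], obs$y[i], obs$z[i])
  }
  list(conventional = plane_from_points(pt("Or-L"), pt("Po-R"), pt("Po-L"),
                                        orient_hint = superior_hint),
       novel = plane_from_points(pt("Or-R"), pt("Or-L"),
                                 midpoint(pt("IAF-L"), pt("IAF-R")),
                                 orient_hint = superior_hint))
}

#' R&R of vertical measurements under the two FH planes
#'
#' For every subject, operator and session, constructs that session's
#' conventional and novel FH planes and takes the signed vertical
#' distance of every landmark annotated in the session to each plane.
#' The signed distances are then fed, per landmark, to
#' [rr_components()], yielding one repeatability/reproducibility table
#' per reference plane (axis `"vertical"`).
#'
#' @param dataset An [annotation_dataset()] (outlier screening applied).
#' @param superior_hint 3-vector fixing the superior side of the planes.
#' @return A list with `conventional` and `novel`, each an `rr_table`
#'   with `axis == "vertical"`; sessions lacking a defining landmark are
#'   skipped and listed in the `"skipped_sessions"` attribute.
#' @export
vertical_rr <- function(dataset, superior_hint = c(0, 0, 1)) {
  obs <- active_observations(dataset)
  ses_key <- unique(obs[c("subject_id", "operator_id", "session_id")])
  rows <- list()
  skipped <- character(0)
  for (r in seq_len(nrow(ses_key))) {
    su <- ses_key$subject_id[r]
    op <- ses_key$operator_id[r]
    se <- ses_key$session_id[r]
    pl <- tryCatch(session_planes(dataset, su, op, se, superior_hint),
                   error = function(e) e)
    if (inherits(pl, "error")) {
      skipped <- c(skipped, conditionMessage(pl))
      next
    }
    sel <- obs$subject_id == su & obs$operator_id == op &
      obs$session_id == se
    P <- cbind(obs$x[sel], obs$y[sel], obs$z[sel])
    rows[[length(rows) + 1L]] <- data.frame(
      subject = su, operator = op, session = se,
      landmark = obs$landmark[sel],
      conventional = signed_vertical_distance(pl$conventional, P),
      novel = signed_vertical_distance(pl$novel, P),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no session with all five FH-defining landmarks")
  vert <- do.call(rbind, rows)

  one_table <- function(col) {
    records <- list()
    skipped_strata <- character(0)
    for (lm in unique(vert$landmark)) {
      sel <- vert$landmark == lm
      comp <- tryCatch(suppressWarnings(
        rr_components(data.frame(subject = vert$subject[sel],
                                 operator = vert$operator[sel],
                                 value = vert[[col]][sel]))),
        error = function(e) e)
      if (inherits(comp, "error")) {
        skipped_strata <- c(skipped_strata,
                            paste0(lm, ": ", conditionMessage(comp)))
        next
      }
      records[[length(records) + 1L]] <- data.frame(
        landmark = lm, axis = "vertical",
        s_r = comp$s_r, s_L = comp$s_L, s_R = comp$s_R,
        ci_repeat = 2 * comp$s_r, ci_repro = 2 * comp$s_R,
        n_cells_used = comp$n_cells_used, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, records)
    out$reliability_class <- classify_reliability(out$ci_repeat,
                                                 out$ci_repro)
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped_strata
    attr(out, "design") <- dataset$design
    class(out) <- c("rr_table", "data.frame")
    out
  }

  out <- list(conventional = one_table("conventional"),
              novel = one_table("novel"))
  attr(out, "skipped_sessions") <- skipped
  out
}

#' Parallelism of the conventional and novel FH planes
#'
#' Per subject, builds the mean conventional FH plane (from the
#' 6-repetition mean positions of Or-L, Po-R, Po-L) and the mean novel FH
#' plane (mean Or-R, Or-L, midpoint of mean IAF-L/IAF-R), measures the
#' signed vertical distance of every IAF annotation to the mean
#' conventional plane, and the absolute angle between the two mean
#' planes. The cohort summary reports the mean and SD of the absolute
#' angles and of the absolute IAF vertical distances per side.
#'
#' @param dataset An [annotation_dataset()].
#' @param superior_hint 3-vector fixing the superior side of the planes.
#' @return An object of class `parallelism_result`: list with
#'   `distances` (one row per IAF observation: `subject_id`, `landmark`,
#'   `operator_id`, `session_id`, `distance` mm), `per_subject`
#'   (`subject_id`, `mean_abs_iaf_l`, `mean_abs_iaf_r`, `angle_deg`) and
#'   `summary` (cohort means and SDs). Subjects without a constructible
#'   mean plane or IAF observations are excluded (attribute
#'   `"excluded"`).
#' @export
parallelism <- function(dataset, superior_hint = c(0, 0, 1)) {
  obs <- active_observations(dataset)
  subjects <- unique(obs$subject_id)
  per_subject <- list()
  dists <- list()
  excluded <- character(0)
  for (su in subjects) {
    res <- tryCatch({
      conv <- plane_from_points(mean_landmark(dataset, su, "Or-L"),
                                mean_landmark(dataset, su, "Po-R"),
                                mean_landmark(dataset, su, "Po-L"),
                                orient_hint = superior_hint)
      nov <- plane_from_points(mean_landmark(dataset, su, "Or-R"),
                               mean_landmark(dataset, su, "Or-L"),
                               midpoint(mean_landmark(dataset, su, "IAF-L"),
                                        mean_landmark(dataset, su, "IAF-R")),
                               orient_hint = superior_hint)
      sel <- obs$subject_id == su & obs$landmark %in% c("IAF-L", "IAF-R")
      if (!any(sel)) stop("no IAF observations")
      d <- signed_vertical_distance(conv,
                                    cbind(obs$x[sel], obs$y[sel],
                                          obs$z[sel]))
      list(dist = data.frame(subject_id = su,
                             landmark = obs$landmark[sel],
                             operator_id = obs$operator_id[sel],
                             session_id = obs$session_id[sel],
                             distance = d, stringsAsFactors = FALSE),
           row = data.frame(
             subject_id = su,
             mean_abs_iaf_l = mean(abs(d[obs$landmark[sel] == "IAF-L"])),
             mean_abs_iaf_r = mean(abs(d[obs$landmark[sel] == "IAF-R"])),
             angle_deg = angle_between_planes(conv, nov),
             stringsAsFactors = FALSE))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, paste0(su, ": ", conditionMessage(res)))
      next
    }
    dists[[length(dists) + 1L]] <- res$dist
    per_subject[[length(per_subject) + 1L]] <- res$row
  }
  if (!length(per_subject)) stop("no subject with constructible FH planes")
  per_subject <- do.call(rbind, per_subject)
  dists <- do.call(rbind, dists)
  abs_l <- abs(dists$distance[dists$landmark == "IAF-L"])
  abs_r <- abs(dists$distance[dists$landmark == "IAF-R"])
  out <- structure(list(
    distances = dists,
    per_subject = per_subject,
    summary = list(mean_abs_angle_deg = mean(per_subject$angle_deg),
                   sd_abs_angle_deg = stats::sd(per_subject$angle_deg),
                   mean_abs_iaf_l_mm = mean(abs_l),
                   sd_abs_iaf_l_mm = stats::sd(abs_l),
                   mean_abs_iaf_r_mm = mean(abs_r),
                   sd_abs_iaf_r_mm = stats::sd(abs_r),
                   n_subjects = nrow(per_subject))),
    class = "parallelism_result")
  attr(out, "excluded") <- excluded
  out
}

#' @export
print.parallelism_result <- function(x, ...) {
  s <- x$summary
  cat("FH plane parallelism over", s$n_subjects, "subjects\n",
      sprintf("  absolute angle: %.2f deg (SD %.2f)\n",
              s$mean_abs_angle_deg, s$sd_abs_angle_deg),
      sprintf("  |IAF-L| to conventional FH: %.2f mm (SD %.2f)\n",
              s$mean_abs_iaf_l_mm, s$sd_abs_iaf_l_mm),
      sprintf("  |IAF-R| to conventional FH: %.2f mm (SD %.2f)\n",
              s$mean_abs_iaf_r_mm, s$sd_abs_iaf_r_mm))
  invisible(x)
}
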