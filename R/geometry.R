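#' Oriented planes and orthonormal frames
#'
#' `plane()` builds an oriented plane from an anchor point and a normal;
#' `plane_from_points()` fits the plane through three non-collinear points.
#' When an `orient_hint` is supplied the normal is flipped, if needed, so
#' that it points into the half-space of the hint (by convention toward the
#' head for the Frankfort Horizontal plane).
#'
#' @param anchor Numeric 3-vector, a point on the plane (mm).
#' @param normal Numeric 3-vector; normalized internally.
#' @return An object of class `ceph_plane` with unit `normal`.
#' @export
plane <- function(anchor, normal) {
  anchor <- as_vec3(anchor, "anchor")
  normal <- as_vec3(normal, "normal")
  n <- vnorm(normal)
  if (n < 1e-12) stop("degenerate plane: zero-length normal")
  structure(list(anchor = anchor, normal = normal / n), class = "ceph_plane")
}

as_vec3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3 || any(!is.finite(p))) {
    stop(what, " must be a finite numeric 3-vector")
  }
  p
}

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @rdname plane
#' @param p1,p2,p3 Numeric 3-vectors (mm) spanning the plane.
#' @param orient_hint Optional 3-vector; the returned normal satisfies
#'   `normal %*% orient_hint > 0`.
#' @examples
#' fh <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
#'                         orient_hint = c(0, 0, 1))
#' fh$normal
#' @export
plane_from_points <- function(p1, p2, p3, orient_hint = NULL) {
  p1 <- as_vec3(p1); p2 <- as_vec3(p2); p3 <- as_vec3(p3)
  n <- cross3(p2 - p1, p3 - p1)
  area <- vnorm(n) / 2
  if (area <= 1e-6) {
    stop("degenerate geometry: the three points are (near-)collinear ",
         "(triangle area ", format(area), " mm^2)")
  }
  pl <- plane(p1, n)
  if (!is.null(orient_hint)) {
    h <- as_vec3(orient_hint, "orient_hint")
    d <- sum(pl$normal * h)
    if (abs(d) < 1e-12) {
      stop("orientation ambiguous: hint is orthogonal to the plane normal")
    }
    if (d < 0) pl$normal <- -pl$normal
  }
  pl
}

#' Midpoint of two points
#'
#' @param p,q Numeric 3-vectors (mm).
#' @return `(p + q) / 2`.
#' @export
midpoint <- function(p, q) (as_vec3(p) + as_vec3(q)) / 2

#' Signed vertical distance from a point to a plane
#'
#' The signed orthogonal distance `(p - anchor) . normal`; positive on the
#' side of the normal (superior, for a head-oriented horizontal plane).
#' `p` may be a single 3-vector or an n-by-3 matrix of points.
#'
#' @param plane A `ceph_plane`.
#' @param p A 3-vector or n-by-3 matrix (mm).
#' @return Signed distance(s) in mm.
#' @export
signed_vertical_distance <- function(plane, p) {
  stopifnot(inherits(plane, "ceph_plane"))
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    return(drop((p - matrix(plane$anchor, nrow(p), 3, byrow = TRUE)) %*%
                  plane$normal))
  }
  sum((as_vec3(p) - plane$anchor) * plane$normal)
}

#' Absolute angle between two planes
#'
#' Computed from the normals as `acos(|n_a . n_b|)`, in degrees; the result
#' lies in `[0, 90]`, is symmetric in its arguments and invariant under a
#' common rigid transform of both planes.
#'
#' @param a,b `ceph_plane` objects.
#' @return Angle in degrees.
#' @export
angle_between_planes <- function(a, b) {
  stopifnot(inherits(a, "ceph_plane"), inherits(b, "ceph_plane"))
  d <- abs(sum(a$normal * b$normal))
  acos(min(1, d)) * 180 / pi
}

#' Mean position of a landmark for one subject
#'
#' Componentwise arithmetic mean over all non-missing, non-outlier
#' observations of the landmark across operators and sessions.
#'
#' @param dataset An [annotation_dataset()].
#' @param subject Subject identifier.
#' @param landmark Landmark name.
#' @return Numeric 3-vector (mm).
#' @export
mean_landmark <- function(dataset, subject, landmark) {
  obs <- active_observations(dataset)
  sel <- obs$subject_id == subject & obs$landmark == landmark
  if (!any(sel)) {
    stop("no usable observation of landmark ", landmark,
         " for subject ", subject)
  }
  c(x = mean(obs$x[sel]), y = mean(obs$y[sel]), z = mean(obs$z[sel]))
}

#' Build the Frankfort-Horizontal coordinate frame
#'
#' Constructs the right-handed orthonormal subject frame used for head
#' reorientation: origin at mid-porion, x axis from right porion toward
#' left porion (sagittal, right to left), z axis normal to the FH plane
#' through the two porions and the left orbitale (axial, toward the head),
#' and y = z x x (frontal, front to back).
#'
#' @param por_r,por_l,orb_l Positions (mm) of right porion, left porion and
#'   left orbitale.
#' @param superior_hint 3-vector indicating the superior direction, used to
#'   fix the sign of the z axis (default scanner `+z`).
#' @return An object of class `ceph_frame` with fields `origin`, `x_axis`,
#'   `y_axis`, `z_axis`.
#' @examples
#' fr <- build_fh_frame(c(-40, 0, 0), c(40, 0, 0), c(30, -70, 0))
#' fr$origin
#' @export
build_fh_frame <- function(por_r, por_l, orb_l, superior_hint = c(0, 0, 1)) {
  por_r <- as_vec3(por_r); por_l <- as_vec3(por_l); orb_l <- as_vec3(orb_l)
  h <- as_vec3(superior_hint, "superior_hint")
  pl <- plane_from_points(por_r, por_l, orb_l)  # errors if degenerate
  d <- sum(pl$normal * h)
  if (abs(d) < 1e-6) {
    stop("orientation ambiguous: superior hint is orthogonal to the FH ",
         "plane normal")
  }
  z <- if (d > 0) pl$normal else -pl$normal
  x <- por_l - por_r
  x <- x / vnorm(x)
  y <- cross3(z, x)
  structure(list(origin = (por_r + por_l) / 2,
                 x_axis = x, y_axis = y, z_axis = z),
            class = "ceph_frame")
}

#' Express points in a frame
#'
#' Rigidly maps scanner coordinates into a subject frame:
#' `((p - origin) . x_axis, (p - origin) . y_axis, (p - origin) . z_axis)`.
#' Pairwise distances and angles are preserved.
#'
#' @param frame A `ceph_frame`.
#' @param p A 3-vector or n-by-3 matrix of points (mm).
#' @return Coordinates in the frame, same shape as `p`.
#' @export
to_frame <- function(frame, p) {
  stopifnot(inherits(frame, "ceph_frame"))
  R <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    out <- (p - matrix(frame$origin, nrow(p), 3, byrow = TRUE)) %*% R
    colnames(out) <- c("x", "y", "z")
    return(out)
  }
  drop(crossprod(R, as_vec3(p) - frame$origin))
}

#' Per-subject mean FH frames for a dataset
#'
#' For every subject, computes the 6-repetition mean positions of Po-R,
#' Po-L and Or-L (after any outlier flagging) and builds the FH frame.
#' When `superior_hint` is `NULL` the normal sign is instead chosen so
#' that the subject's mean Menton gets a negative z coordinate (Menton is
#' unambiguously below the FH plane).
#'
#' @param dataset An [annotation_dataset()].
#' @param superior_hint 3-vector or `NULL` for the Menton fallback.
#' @return Named list of `ceph_frame`, one per subject with the three
#'   required landmarks; subjects lacking them are dropped with a warning.
#' @export
fh_frames <- function(dataset, superior_hint = c(0, 0, 1)) {
  subjects <- unique(dataset$observations$subject_id)
  frames <- list()
  skipped <- character(0)
  for (su in subjects) {
    fr <- tryCatch({
      por_r <- mean_landmark(dataset, su, "Po-R")
      por_l <- mean_landmark(dataset, su, "Po-L")
      orb_l <- mean_landmark(dataset, su, "Or-L")
      if (is.null(superior_hint)) {
        f0 <- build_fh_frame(por_r, por_l, orb_l,
                             superior_hint = fallback_hint(por_r, por_l,
                                                           orb_l))
        me <- mean_landmark(dataset, su, "Me")
        if (to_frame(f0, me)[3] > 0) {
          f0 <- build_fh_frame(por_r, por_l, orb_l,
                               superior_hint = -f0$z_axis)
        }
        f0
      } else {
        build_fh_frame(por_r, por_l, orb_l, superior_hint = superior_hint)
      }
    }, error = function(e) e)
    if (inherits(fr, "error")) skipped <- c(skipped, su) else frames[[su]] <- fr
  }
  if (length(skipped)) {
    warning("no FH frame for subject(s): ", paste(skipped, collapse = ", "))
  }
  frames
}

# Any non-degenerate hint; sign fixed afterwards by the Menton rule.
fallback_hint <- function(por_r, por_l, orb_l) {
  plane_from_points(por_r, por_l, orb_l)$normal
}

#' Serialize frames and planes to JSON
#'
#' @param x A `ceph_frame` or `ceph_plane`.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
geometry_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "ceph_frame")) {
    list(type = "frame", origin = x$origin, x_axis = x$x_axis,
         y_axis = x$y_axis, z_axis = x$z_axis)
  } else if (inherits(x, "ceph_plane")) {
    list(type = "plane", anchor = x$anchor, normal = x$normal)
  } else {
    stop("x must be a ceph_frame or ceph_plane")
  }
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.ceph_plane <- function(x, ...) {
  cat("Plane: anchor (", paste(signif(x$anchor, 6), collapse = ", "),
      ") mm, normal (", paste(signif(x$normal, 6), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' @export
print.ceph_frame <- function(x, ...) {
  cat("FH frame: origin (", paste(signif(x$origin, 6), collapse = ", "),
      ") mm\n  x ", paste(signif(x$x_axis, 6), collapse = ", "),
      "\n  y ", paste(signif(x$y_axis, 6), collapse = ", "),
      "\n  z ", paste(signif(x$z_axis, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}
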