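#' Template skull geometry for the simulator
#'
#' A plausible adult craniofacial landmark layout, in mm, in a scanner-like
#' frame with +x to the subject's left, +y posterior and +z superior. The
#' coordinates are synthetic design values, not measured data: they are
#' chosen to satisfy anatomical ordering (Menton below Nasion, porions
#' 65 mm apart, orbital points anterior to the porions, internal acoustic
#' foramina medial to the porions, dental landmarks inferior-anterior) so
#' that Frankfort-Horizontal constructions behave as on a real head.
#'
#' @return A 33-by-3 numeric matrix, rows named by catalog landmark.
#' @export
default_template <- function() {
  tpl <- rbind(
    "Na"    = c(0, -72, 25),
    "Or-L"  = c(28, -65, -2),
    "Or-R"  = c(-28, -65, -2),
    "ANS"   = c(0, -80, -20),
    "A"     = c(0, -78, -28),
    "B"     = c(0, -75, -60),
    "Pog"   = c(0, -77, -70),
    "Gn"    = c(0, -74.5, -74),
    "Me"    = c(0, -72, -78),
    "Go-L"  = c(45, -5, -55),
    "Go-R"  = c(-45, -5, -55),
    "Po-L"  = c(32.5, 10, 0),
    "Po-R"  = c(-32.5, 10, 0),
    "PNS"   = c(0, -35, -22),
    "S"     = c(0, -15, 10),
    "IF-L"  = c(25, -62, -12),
    "IF-R"  = c(-25, -62, -12),
    "MF-L"  = c(22, -60, -60),
    "MF-R"  = c(-22, -60, -60),
    "IAF-L" = c(12, 8, 2),
    "IAF-R" = c(-12, 8, 2),
    "11E"   = c(-4, -78, -42),
    "21E"   = c(4, -78, -42),
    "31E"   = c(4, -76, -44),
    "41E"   = c(-4, -76, -44),
    "11A"   = c(-4, -76, -30),
    "21A"   = c(4, -76, -30),
    "31A"   = c(4, -74, -56),
    "41A"   = c(-4, -74, -56),
    "16O"   = c(-28, -45, -40),
    "26O"   = c(28, -45, -40),
    "36O"   = c(30, -45, -42),
    "46O"   = c(-30, -45, -42)
  )
  colnames(tpl) <- c("x", "y", "z")
  tpl
}

#' Define the generative truth of a landmarking simulation
#'
#' The simulator follows the ISO 5725 decomposition `y = m + B + e`: for
#' every subject a true anatomy (template plus per-subject anatomical
#' offsets, plus an optional controlled cant of the IAF pair against the
#' conventional FH plane, plus a random rigid pose), for every operator a
#' persistent bias `B` per landmark and axis (shared across subjects and
#' sessions), and independent session noise `e`. Gross-error outliers can
#' be injected on top.
#'
#' @param template Landmark template matrix (rows named by landmark);
#'   default [default_template()].
#' @param sigma_r Repeatability SD of the session noise, mm: a scalar, a
#'   length-3 per-axis vector, or a full landmark-by-axis matrix.
#' @param sigma_L Between-operator SD of the persistent bias, mm; same
#'   shapes accepted.
#' @param subject_sd SD of the mirror-symmetric per-subject anatomical
#'   offsets, mm: bilateral landmark pairs receive a shared offset
#'   reflected about the midsagittal plane, midline landmarks an offset
#'   in y/z only, so that anatomies vary in shape while staying broadly
#'   symmetric, as real skulls do.
#' @param asymmetry_sd SD of the additional independent (asymmetric)
#'   offset applied to every landmark and axis, mm. This is what makes
#'   the two FH planes genuinely non-parallel beyond the controlled
#'   cant.
#' @param pose List `max_rot_deg`, `max_trans_mm`: ranges of the random
#'   rigid pose applied per subject (rotation about a random axis,
#'   uniform translation).
#' @param cant Controlled tilt of the IAF pair against the conventional
#'   FH plane: `NULL` to leave the template IAF untouched,
#'   `list(type = "fixed", deg = a)` for a fixed angle, or
#'   `list(type = "half_normal", sd_deg = s)` to draw per-subject angles
#'   as `|N(0, s^2)|`.
#' @param outliers Injected gross errors: a data frame with columns
#'   `operator`, `session`, `landmark`, `subject` (integer subject index),
#'   `dx`, `dy`, `dz` (mm, applied in scanner coordinates, after the
#'   pose).
#' @param seed Optional integer seed stored with the truth.
#' @return An object of class `simulation_truth`.
#' @seealso [simulate_annotations()], [paperlike_scenario()]
#' @export
simulation_truth <- function(template = default_template(),
                             sigma_r = 0.25, sigma_L = 0.15,
                             subject_sd = 3, asymmetry_sd = 0.5,
                             pose = list(max_rot_deg = 10, max_trans_mm = 30),
                             cant = list(type = "fixed", deg = 0),
                             outliers = NULL, seed = NULL) {
  stopifnot(is.matrix(template), ncol(template) == 3,
            !is.null(rownames(template)))
  truth <- structure(list(
    template = template,
    sigma_r = expand_sigma(sigma_r, template, "sigma_r"),
    sigma_L = expand_sigma(sigma_L, template, "sigma_L"),
    subject_sd = subject_sd,
    asymmetry_sd = asymmetry_sd,
    pose = pose,
    cant = cant,
    outliers = outliers,
    seed = seed
  ), class = "simulation_truth")
  validate_truth(truth)
  truth
}

expand_sigma <- function(s, template, what) {
  L <- nrow(template)
  if (is.matrix(s)) {
    stopifnot(nrow(s) == L, ncol(s) == 3)
    if (is.null(rownames(s))) rownames(s) <- rownames(template)
    m <- s[rownames(template), , drop = FALSE]
  } else if (length(s) == 1) {
    m <- matrix(s, L, 3, dimnames = list(rownames(template), NULL))
  } else if (length(s) == 3) {
    m <- matrix(s, L, 3, byrow = TRUE,
                dimnames = list(rownames(template), NULL))
  } else {
    stop(what, " must be a scalar, length-3 vector or landmark-by-3 matrix")
  }
  colnames(m) <- c("x", "y", "z")
  if (any(m < 0)) stop(what, " must be non-negative")
  m
}

validate_truth <- function(truth) {
  tpl <- truth$template
  if (truth$subject_sd < 0) stop("subject_sd must be non-negative")
  if (truth$asymmetry_sd < 0) stop("asymmetry_sd must be non-negative")
  if (!is.null(truth$cant) &&
      !truth$cant$type %in% c("fixed", "half_normal")) {
    stop("cant$type must be 'fixed' or 'half_normal'")
  }
  if (!is.null(truth$outliers)) {
    need <- c("operator", "session", "landmark", "subject",
              "dx", "dy", "dz")
    if (!all(need %in% names(truth$outliers))) {
      stop("outliers must have columns ", paste(need, collapse = ", "))
    }
    bad <- setdiff(unique(truth$outliers$landmark), rownames(tpl))
    if (length(bad)) stop("outlier landmarks not in template: ",
                          paste(bad, collapse = ", "))
  }
  ## bilateral template points should be mirror-plausible about x = 0
  nm <- rownames(tpl)
  lefts <- nm[grepl("-L$", nm)]
  for (l in lefts) {
    r <- sub("-L$", "-R", l)
    if (r %in% nm && abs(tpl[l, 1] + tpl[r, 1]) >= 10) {
      stop("template pair ", l, "/", r, " is not mirror-plausible")
    }
  }
  invisible(truth)
}

#' Simulate a multi-operator landmark annotation dataset
#'
#' Draws a complete annotation study from a [simulation_truth()]: subject
#' anatomies, persistent operator biases, session noise, injected
#' outliers. Operator biases and session noise are drawn per landmark and
#' axis in the subject's anatomical frame (where the anisotropy of manual
#' landmarking error is defined) before the rigid pose is applied.
#'
#' @param truth A `simulation_truth`.
#' @param n_subjects,n_operators,n_sessions Design counts (all >= 1).
#' @param seed Integer seed; overrides `truth$seed`. One of the two must
#'   be set so the draw is reproducible.
#' @return A list of class `ceph_simulation`: `dataset` (the
#'   [annotation_dataset()]) and `truth` — the input truth augmented with
#'   the realized values actually drawn: per-subject cant angles
#'   (`realized_cant_deg`), operator bias array (`bias`), subject poses
#'   and true anatomies.
#' @examples
#' sim <- simulate_annotations(simulation_truth(seed = 1), 4, 3, 2)
#' sim$dataset
#' @export
simulate_annotations <- function(truth, n_subjects, n_operators, n_sessions,
                                 seed = truth$seed) {
  stopifnot(inherits(truth, "simulation_truth"),
            n_subjects >= 1, n_operators >= 1, n_sessions >= 1)
  if (is.null(seed)) stop("a seed is required (in the truth or as argument)")
  set.seed(as.integer(seed))

  tpl <- truth$template
  L <- nrow(tpl)
  lms <- rownames(tpl)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  operators <- sprintf("O%d", seq_len(n_operators))
  sessions <- sprintf("R%d", seq_len(n_sessions))

  ## per-subject anatomy, cant, pose (drawn subject by subject)
  anatomies <- vector("list", n_subjects)
  poses <- vector("list", n_subjects)
  realized_cant <- numeric(n_subjects)
  for (j in seq_len(n_subjects)) {
    anat <- tpl + subject_offsets(tpl, truth$subject_sd,
                                  truth$asymmetry_sd)
    if (!is.null(truth$cant)) {
      deg <- switch(truth$cant$type,
                    fixed = truth$cant$deg,
                    half_normal = abs(stats::rnorm(1,
                                                   sd = truth$cant$sd_deg)))
      anat <- set_iaf_cant(anat, deg)
    }
    # the realized cant is the actual noise-free angle between the two FH
    # planes of this anatomy; residual anatomical asymmetry (Or-R off the
    # conventional plane) keeps it from equalling the drawn tilt exactly
    realized_cant[j] <- iaf_cant_angle(anat)
    poses[[j]] <- random_pose(truth$pose)
    anatomies[[j]] <- anat
  }

  ## persistent operator bias per landmark/axis
  bias <- array(stats::rnorm(n_operators * L * 3) *
                  rep(truth$sigma_L, each = n_operators),
                dim = c(n_operators, L, 3),
                dimnames = list(operators, lms, c("x", "y", "z")))

  ## observations: subject (outer) x operator x session x landmark
  blocks <- vector("list", n_subjects * n_operators * n_sessions)
  b <- 0L
  for (j in seq_len(n_subjects)) {
    pj <- poses[[j]]
    for (i in seq_len(n_operators)) {
      Bi <- matrix(bias[i, , ], L, 3)
      for (k in seq_len(n_sessions)) {
        e <- matrix(stats::rnorm(L * 3), L, 3) * truth$sigma_r
        pts <- (anatomies[[j]] + Bi + e) %*% t(pj$R)
        pts <- pts + matrix(pj$t, L, 3, byrow = TRUE)
        b <- b + 1L
        blocks[[b]] <- data.frame(
          subject_id = subjects[j], operator_id = operators[i],
          session_id = sessions[k], landmark = lms,
          x = pts[, 1], y = pts[, 2], z = pts[, 3],
          stringsAsFactors = FALSE)
      }
    }
  }
  obs <- do.call(rbind, blocks)

  if (!is.null(truth$outliers)) {
    o <- truth$outliers
    key <- paste(obs$subject_id, obs$operator_id, obs$session_id,
                 obs$landmark, sep = "\r")
    okey <- paste(subjects[o$subject], o$operator, o$session, o$landmark,
                  sep = "\r")
    hit <- match(okey, key)
    if (anyNA(hit)) {
      o <- o[!is.na(hit), , drop = FALSE]
      hit <- hit[!is.na(hit)]
    }
    obs$x[hit] <- obs$x[hit] + o$dx
    obs$y[hit] <- obs$y[hit] + o$dy
    obs$z[hit] <- obs$z[hit] + o$dz
  }

  catalog <- default_catalog()
  catalog <- catalog[catalog$name %in% lms, , drop = FALSE]
  class(catalog) <- c("landmark_catalog", "data.frame")

  truth$realized_cant_deg <- stats::setNames(realized_cant, subjects)
  truth$bias <- bias
  truth$poses <- stats::setNames(poses, subjects)
  truth$anatomies <- stats::setNames(anatomies, subjects)
  truth$seed <- as.integer(seed)

  structure(list(dataset = annotation_dataset(obs, catalog = catalog),
                 truth = truth),
            class = "ceph_simulation")
}

# Per-subject anatomical offsets: a mirror-symmetric shape component
# (shared by each bilateral pair, reflected in x; y/z only for midline
# landmarks) plus an independent asymmetric component on every landmark.
# Landmarks are visited in template order with the right member of a pair
# drawn together with its left member, so draws are reproducible.
subject_offsets <- function(tpl, subject_sd, asymmetry_sd) {
  nm <- rownames(tpl)
  lat <- template_laterality(nm)
  stem <- landmark_stem(nm)
  off <- matrix(0, nrow(tpl), 3, dimnames = dimnames(tpl))
  done <- logical(length(nm))
  for (i in seq_along(nm)) {
    if (done[i]) next
    if (lat[i] == "midline") {
      off[i, ] <- c(0, stats::rnorm(2, sd = subject_sd)) +
        stats::rnorm(3, sd = asymmetry_sd)
      done[i] <- TRUE
    } else {
      partner <- which(stem == stem[i] & lat != lat[i])
      s <- stats::rnorm(3, sd = subject_sd)
      off[i, ] <- s + stats::rnorm(3, sd = asymmetry_sd)
      if (length(partner) == 1) {
        off[partner, ] <- c(-s[1], s[2], s[3]) +
          stats::rnorm(3, sd = asymmetry_sd)
        done[partner] <- TRUE
      }
      done[i] <- TRUE
    }
  }
  off
}

template_laterality <- function(nm) {
  cat33 <- default_catalog()
  lat <- cat33$laterality[match(nm, cat33$name)]
  lat[is.na(lat)] <- "midline"
  lat
}

# Tilt the IAF pair so the novel FH plane makes exactly `deg` degrees with
# the conventional FH plane, rotating about the inter-orbital axis: project
# both IAF points onto the conventional plane, then lift them along its
# normal by d * tan(deg), d being the distance of projected mid-IAF from
# the Or-R--Or-L line.
set_iaf_cant <- function(anat, deg) {
  pl <- plane_from_points(anat["Or-L", ], anat["Po-R", ], anat["Po-L", ],
                          orient_hint = c(0, 0, 1))
  for (nm in c("IAF-L", "IAF-R")) {
    p <- anat[nm, ]
    anat[nm, ] <- p - signed_vertical_distance(pl, p) * pl$normal
  }
  m <- midpoint(anat["IAF-L", ], anat["IAF-R", ])
  d <- point_line_distance(m, anat["Or-R", ], anat["Or-L", ])
  t_mm <- d * tan(deg * pi / 180)
  for (nm in c("IAF-L", "IAF-R")) {
    anat[nm, ] <- anat[nm, ] + t_mm * pl$normal
  }
  anat
}

iaf_cant_angle <- function(anat) {
  conv <- plane_from_points(anat["Or-L", ], anat["Po-R", ], anat["Po-L", ])
  nov <- plane_from_points(anat["Or-R", ], anat["Or-L", ],
                           midpoint(anat["IAF-L", ], anat["IAF-R", ]))
  angle_between_planes(conv, nov)
}

point_line_distance <- function(p, a, b) {
  u <- (b - a) / vnorm(b - a)
  w <- p - a
  vnorm(w - sum(w * u) * u)
}

random_pose <- function(pose) {
  ang <- stats::runif(1, 0, pose$max_rot_deg) * pi / 180
  ax <- stats::rnorm(3)
  ax <- ax / vnorm(ax)
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  t <- stats::runif(3, -pose$max_trans_mm, pose$max_trans_mm)
  list(R = R, t = t)
}

#' Scenario emulating the published study conditions
#'
#' A packaged [simulation_truth()] for a 20-subject, 3-operator,
#' 2-session study of all 33 landmarks: anisotropic repeatability SDs
#' echoing the observed per-axis pattern (orbitale and porion noisiest
#' along x, gonion along y/z, B point along z, dental landmarks tight),
#' between-operator SDs at 70% of the repeatability SDs, a half-normal
#' per-subject cant of the IAF pair (SD 2.4 degrees) against the
#' conventional FH plane, and the historical gross-error episode: mental
#' foramen left/right displaced 8 mm posteriorly by operator 3 in session
#' 1 for subjects 4 to 20.
#'
#' @return A `simulation_truth`; pass it to [simulate_annotations()] with
#'   `n_subjects = 20, n_operators = 3, n_sessions = 2`.
#' @export
paperlike_scenario <- function() {
  tpl <- default_template()
  sig <- matrix(NA_real_, nrow(tpl), 3,
                dimnames = list(rownames(tpl), c("x", "y", "z")))
  set_sig <- function(sig, names, v) {
    for (nm in names) sig[nm, ] <- v
    sig
  }
  ## dental landmarks: tight, molar occlusal points looser in y
  sig <- set_sig(sig, c("11E", "21E", "31E", "41E"), c(0.12, 0.11, 0.04))
  sig <- set_sig(sig, c("11A", "21A", "31A", "41A"), c(0.11, 0.16, 0.13))
  sig <- set_sig(sig, c("16O", "26O"), c(0.32, 0.49, 0.10))
  sig <- set_sig(sig, c("36O", "46O"), c(0.26, 0.43, 0.15))
  ## foraminal landmarks
  sig <- set_sig(sig, c("MF-L", "MF-R"), c(0.12, 0.13, 0.16))
  sig <- set_sig(sig, c("IF-L", "IF-R"), c(0.44, 0.40, 0.32))
  sig <- set_sig(sig, c("IAF-L", "IAF-R"), c(0.26, 0.42, 0.35))
  ## conventional landmarks, per-axis pattern of the reliability ranking
  sig <- set_sig(sig, c("Or-L", "Or-R"), c(0.97, 0.52, 0.19))
  sig <- set_sig(sig, c("Po-L", "Po-R"), c(1.14, 0.50, 0.33))
  sig <- set_sig(sig, c("Go-L", "Go-R"), c(0.31, 0.73, 0.98))
  sig <- set_sig(sig, "B",   c(0.30, 0.28, 1.23))
  sig <- set_sig(sig, "A",   c(0.40, 0.15, 0.66))
  sig <- set_sig(sig, "ANS", c(0.29, 0.40, 0.29))
  sig <- set_sig(sig, "Na",  c(0.21, 0.11, 0.31))
  sig <- set_sig(sig, "Me",  c(0.38, 0.65, 0.19))
  sig <- set_sig(sig, "Gn",  c(0.38, 0.38, 0.53))
  sig <- set_sig(sig, "Pog", c(0.36, 0.19, 0.82))
  sig <- set_sig(sig, "PNS", c(0.15, 0.18, 0.31))
  sig <- set_sig(sig, "S",   c(0.47, 0.30, 0.41))

  outliers <- expand.grid(subject = 4:20, landmark = c("MF-L", "MF-R"),
                          stringsAsFactors = FALSE)
  outliers$operator <- "O3"
  outliers$session <- "R1"
  outliers$dx <- 0
  outliers$dy <- 8
  outliers$dz <- 0

  simulation_truth(template = tpl,
                   sigma_r = sig,
                   sigma_L = 0.7 * sig,
                   subject_sd = 3,
                   pose = list(max_rot_deg = 10, max_trans_mm = 30),
                   cant = list(type = "half_normal", sd_deg = 2.4),
                   outliers = outliers)
}

#' Simulate one scalar R&R stratum
#'
#' Fast generator for a single measurand under the ISO 5725 model
#' `y_ijk = m_j + B_i + e_ijk`: subject level `m_j ~ N(0, 5^2)` (the
#' analysis is location-invariant within subject), persistent operator
#' bias `B_i ~ N(0, sigma_L^2)` and replicate noise
#' `e_ijk ~ N(0, sigma_r^2)`. Used for variance-component recovery
#' studies where full 3D geometry is unnecessary.
#'
#' @param p,q,n Number of operators, subjects, replicates per cell.
#' @param sigma_r,sigma_L True SDs, mm.
#' @return A data frame with columns `subject`, `operator`, `session`,
#'   `value`, suitable for [rr_components()].
#' @export
simulate_rr_values <- function(p, q, n, sigma_r, sigma_L) {
  d <- expand.grid(session = seq_len(n), operator = seq_len(p),
                   subject = seq_len(q))
  m <- stats::rnorm(q, sd = 5)
  B <- stats::rnorm(p, sd = sigma_L)
  d$value <- m[d$subject] + B[d$operator] +
    stats::rnorm(nrow(d), sd = sigma_r)
  d[c("subject", "operator", "session", "value")]
}

#' @export
print.ceph_simulation <- function(x, ...) {
  cat("Simulated landmarking study (seed ", x$truth$seed, ")\n", sep = "")
  print(x$dataset)
  cat("realized cant (deg): ",
      paste(signif(utils::head(x$truth$realized_cant_deg, 5), 3),
            collapse = ", "),
      if (length(x$truth$realized_cant_deg) > 5) ", ..." else "", "\n",
      sep = "")
  invisible(x)
}
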