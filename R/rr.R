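#' ISO 5725 repeatability and reproducibility variance components
#'
#' Estimates the repeatability SD `s_r`, the between-operator SD `s_L` and
#' the reproducibility SD `s_R` (with `s_R^2 = s_r^2 + s_L^2`) from
#' repeated measurements of one scalar quantity, following the ISO 5725-2
#' variance-component scheme with operators in the role of laboratories
#' and subjects in the role of levels, pooled into a single estimate.
#'
#' A cell is one operator-by-subject combination with `n_ij` replicate
#' sessions. The estimators are
#' \deqn{s_r^2 = \frac{\sum_{ij} (n_{ij}-1)\, s^2_{ij}}{\sum_{ij}(n_{ij}-1)},
#' \qquad
#' s_L^2 = \max\!\left(0,\; \overline{s^2_{d,j}} - s_r^2/\bar n\right),}
#' where \eqn{s^2_{ij}} is the within-cell variance, \eqn{s^2_{d,j}} the
#' variance of cell means across the operators present for subject `j`
#' (subjects with at least two operators), and \eqn{\bar n} the mean
#' replicate count of the cells entering those cell means.
#'
#' @param values A data frame with columns `subject`, `operator`, `value`
#'   (one row per replicate; a `session` column may be present and is
#'   ignored by the estimator, replicates being exchangeable within a
#'   cell).
#' @return A list with `s_r`, `s_L`, `s_R`, `n_cells_used` (cells with at
#'   least two replicates, i.e. those pooled into `s_r`) and `s_L2_raw`,
#'   the between-operator variance before truncation at zero.
#' @examples
#' d <- expand.grid(subject = 1:5, operator = 1:3, session = 1:2)
#' d$value <- rnorm(nrow(d), sd = 0.3)
#' rr_components(d)
#' @export
rr_components <- function(values) {
  v <- as.data.frame(values)
  stopifnot(all(c("subject", "operator", "value") %in% names(v)))
  v$subject <- as.character(v$subject)
  v$operator <- as.character(v$operator)
  v <- v[is.finite(v$value), , drop = FALSE]
  if (length(unique(v$subject)) < 2) {
    stop("rr_components needs at least 2 subjects")
  }
  single_operator <- length(unique(v$operator)) < 2

  cell <- paste(v$subject, v$operator, sep = "\r")
  idx <- split(seq_len(nrow(v)), cell)
  n_ij <- lengths(idx)
  cell_mean <- vapply(idx, function(i) mean(v$value[i]), numeric(1))
  cell_var <- vapply(idx, function(i) {
    if (length(i) < 2) NA_real_ else stats::var(v$value[i])
  }, numeric(1))
  cell_subject <- vapply(idx, function(i) v$subject[i[1]], character(1))

  use_r <- n_ij >= 2
  if (!any(use_r)) {
    stop("cannot estimate repeatability: no cell has 2 or more replicates")
  }
  w <- n_ij[use_r] - 1
  s_r2 <- sum(w * cell_var[use_r]) / sum(w)

  if (single_operator) {
    warning("single operator: between-operator SD set to 0")
    s_L2_raw <- 0
    s_L2 <- 0
  } else {
    subj_split <- split(seq_along(cell_mean), as.character(cell_subject))
    sd2 <- numeric(0)
    contributing <- integer(0)
    for (cells in subj_split) {
      if (length(cells) >= 2) {
        sd2 <- c(sd2, stats::var(cell_mean[cells]))
        contributing <- c(contributing, cells)
      }
    }
    if (!length(sd2)) {
      s_L2_raw <- 0
      s_L2 <- 0
      warning("no subject observed by 2 or more operators: ",
              "between-operator SD set to 0")
    } else {
      nbar <- mean(n_ij[contributing])
      s_L2_raw <- mean(sd2) - s_r2 / nbar
      s_L2 <- max(0, s_L2_raw)
    }
  }
  list(s_r = sqrt(s_r2),
       s_L = sqrt(s_L2),
       s_R = sqrt(s_r2 + s_L2),
       n_cells_used = sum(use_r),
       s_L2_raw = s_L2_raw)
}

#' Classify landmark reliability from 95% confidence intervals
#'
#' Applies the clinical ranking used for cephalometric landmarks: an error
#' is clinically acceptable when the 95% CI (2 x SD) is at most 1 mm,
#' useful in most analyses between 1 and 2 mm, and to be used with caution
#' above 2 mm. The larger of the repeatability and reproducibility CI
#' decides the class.
#'
#' @param ci_repeat,ci_repro 95% CI values (2 x SD), mm, non-negative.
#' @return `"acceptable"`, `"useful"` or `"caution"` (vectorized).
#' @examples
#' classify_reliability(0.24, 0.35)  # acceptable
#' classify_reliability(2.05, 3.40)  # caution
#' @export
classify_reliability <- function(ci_repeat, ci_repro) {
  if (any(ci_repeat < 0) || any(ci_repro < 0)) {
    stop("confidence-interval values must be non-negative")
  }
  worst <- pmax(ci_repeat, ci_repro)
  ifelse(worst <= 1, "acceptable", ifelse(worst <= 2, "useful", "caution"))
}

#' Per-landmark, per-axis repeatability and reproducibility table
#'
#' Transforms every usable observation into its subject's FH frame and
#' runs [rr_components()] on each (landmark, axis) stratum, producing the
#' per-axis table of repeatability/reproducibility 95% CIs (2 x SD) with
#' the clinical reliability class.
#'
#' @param dataset An [annotation_dataset()]; outlier screening should
#'   already have been applied (see [apply_outlier_report()]).
#' @param frames Named list of `ceph_frame`, one per subject (see
#'   [fh_frames()]).
#' @return A data frame of class `rr_table` with one row per
#'   (landmark, axis): columns `landmark`, `axis`, `s_r`, `s_L`, `s_R`,
#'   `ci_repeat`, `ci_repro`, `n_cells_used`, `reliability_class`.
#'   Strata where the components cannot be estimated are omitted and
#'   reported via the `"skipped"` attribute.
#' @export
rr_table <- function(dataset, frames) {
  obs <- active_observations(dataset)
  obs <- obs[obs$subject_id %in% names(frames), , drop = FALSE]
  if (!nrow(obs)) stop("no usable observations with an available frame")

  local <- matrix(NA_real_, nrow(obs), 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  for (su in unique(obs$subject_id)) {
    sel <- obs$subject_id == su
    local[sel, ] <- to_frame(frames[[su]],
                             cbind(obs$x[sel], obs$y[sel], obs$z[sel]))
  }

  records <- list()
  skipped <- character(0)
  for (lm in unique(obs$landmark)) {
    lsel <- obs$landmark == lm
    for (axis in c("x", "y", "z")) {
      vals <- data.frame(subject = obs$subject_id[lsel],
                         operator = obs$operator_id[lsel],
                         value = local[lsel, axis],
                         stringsAsFactors = FALSE)
      comp <- tryCatch(suppressWarnings(rr_components(vals)),
                       error = function(e) e)
      if (inherits(comp, "error")) {
        skipped <- c(skipped, paste0(lm, "/", axis, ": ",
                                     conditionMessage(comp)))
        next
      }
      records[[length(records) + 1L]] <- data.frame(
        landmark = lm, axis = axis,
        s_r = comp$s_r, s_L = comp$s_L, s_R = comp$s_R,
        ci_repeat = 2 * comp$s_r, ci_repro = 2 * comp$s_R,
        n_cells_used = comp$n_cells_used,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, records)
  out$reliability_class <- classify_reliability(out$ci_repeat, out$ci_repro)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "design") <- dataset$design
  class(out) <- c("rr_table", "data.frame")
  out
}

#' @export
print.rr_table <- function(x, digits = 3, ...) {
  cat("Repeatability & reproducibility table:", nrow(x), "records\n")
  y <- unclass_df(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE, ...)
  if (length(attr(x, "skipped"))) {
    cat("skipped strata:", length(attr(x, "skipped")), "\n")
  }
  invisible(x)
}

#' Modified Bland-Altman series for one landmark and axis
#'
#' Deviations of every repetition from the subject's mean (over the
#' available repetitions) for the chosen coordinate after FH-frame
#' reorientation, with agreement limits at plus or minus two
#' reproducibility SDs estimated from the same stratum.
#'
#' @param dataset An [annotation_dataset()].
#' @param landmark Landmark name.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param frames Named list of subject frames, as in [rr_table()].
#' @return A data frame of class `bland_altman` with columns `subject_id`,
#'   `operator_id`, `session_id`, `value` (frame coordinate, mm),
#'   `deviation` (mm); attributes `limits` (`c(-2, 2) * s_R`), `landmark`,
#'   `axis`.
#' @export
bland_altman <- function(dataset, landmark, axis = c("x", "y", "z"),
                         frames = fh_frames(dataset)) {
  axis <- match.arg(axis)
  obs <- active_observations(dataset)
  obs <- obs[obs$landmark == landmark &
               obs$subject_id %in% names(frames), , drop = FALSE]
  if (!nrow(obs)) stop("no usable observation of landmark ", landmark)
  value <- numeric(nrow(obs))
  for (su in unique(obs$subject_id)) {
    sel <- obs$subject_id == su
    value[sel] <- to_frame(frames[[su]],
                           cbind(obs$x[sel], obs$y[sel], obs$z[sel]))[, axis]
  }
  dev <- value - stats::ave(value, obs$subject_id)
  comp <- suppressWarnings(
    rr_components(data.frame(subject = obs$subject_id,
                             operator = obs$operator_id,
                             value = value)))
  out <- data.frame(subject_id = obs$subject_id,
                    operator_id = obs$operator_id,
                    session_id = obs$session_id,
                    value = value, deviation = dev,
                    stringsAsFactors = FALSE)
  attr(out, "limits") <- c(-2, 2) * comp$s_R
  attr(out, "landmark") <- landmark
  attr(out, "axis") <- axis
  class(out) <- c("bland_altman", "data.frame")
  out
}

#' Minimum number of subjects for a target uncertainty of the R&R SD
#'
#' ISO 5725-1 style approximation for the number of subjects `q` needed so
#' that the repeatability (or reproducibility) SD estimated from `n`
#' repetitions per subject carries a given 95% relative uncertainty `A`:
#' \deqn{q = \mathrm{round}\!\left(\frac{z^2}{2 A^2 (n-1)}\right).}
#' Rounding is to the nearest integer; with `A = 0.15` and `n = 6` the
#' unrounded value is 17.07, giving the canonical 17 subjects.
#'
#' @param relative_uncertainty Target relative uncertainty `A`, in (0, 1).
#' @param repetitions Repetitions per subject `n`, at least 2.
#' @param z Normal quantile for the confidence level (default 1.96).
#' @return Integer number of subjects.
#' @examples
#' sample_size(0.15, 6)
#' @export
sample_size <- function(relative_uncertainty, repetitions, z = 1.96) {
  if (!is.finite(relative_uncertainty) ||
      relative_uncertainty <= 0 || relative_uncertainty >= 1) {
    stop("relative_uncertainty must lie strictly between 0 and 1")
  }
  if (!is.finite(repetitions) || repetitions < 2 ||
      repetitions != round(repetitions)) {
    stop("repetitions must be an integer >= 2")
  }
  if (!is.finite(z) || z <= 0) stop("z must be positive")
  as.integer(round(z^2 / (2 * relative_uncertainty^2 * (repetitions - 1))))
}
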