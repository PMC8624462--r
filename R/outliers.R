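#' Screen a dataset for outlying annotations
#'
#' Applies the measurement-system outlier rules in order:
#' \describe{
#'   \item{gross}{an observation farther than `gross_mm` (Euclidean
#'     distance, mm) from the cross-operator componentwise median position
#'     of that landmark for that subject. Deterministic and robust: with
#'     six repetitions a single grossly misplaced annotation cannot drag
#'     the median.}
#'   \item{grubbs}{Grubbs' single-outlier test at level `grubbs_alpha`
#'     applied, per subject/landmark/axis, to the operator cell means
#'     (session means per operator) remaining after gross-error
#'     exclusion. A significant cell is flagged whole. Strata with fewer
#'     than three cells are skipped.}
#'   \item{mandel}{Mandel's between-operator h and within-operator k
#'     consistency statistics at `mandel_alpha`, reported as advisory
#'     diagnostics only; they never remove data.}
#' }
#'
#' @param dataset An [annotation_dataset()].
#' @param gross_mm Gross-error distance threshold, mm (default 5).
#' @param grubbs_alpha Significance level of the Grubbs test (default 0.01).
#' @param mandel_alpha Significance level for Mandel's h/k (default 0.01).
#' @return An object of class `outlier_report`: list with `flagged`
#'   (data frame `subject_id`, `operator_id`, `session_id`, `landmark`,
#'   `rule`, `statistic`), `advisory` (Mandel exceedances), `skipped`
#'   (strata where a rule could not run) and `rules` (thresholds used).
#' @seealso [apply_outlier_report()]
#' @export
screen_outliers <- function(dataset, gross_mm = 5, grubbs_alpha = 0.01,
                            mandel_alpha = 0.01) {
  stopifnot(inherits(dataset, "annotation_dataset"))
  if (gross_mm <= 0 || grubbs_alpha <= 0 || grubbs_alpha >= 1 ||
      mandel_alpha <= 0 || mandel_alpha >= 1) {
    stop("outlier thresholds must be positive (alphas in (0, 1))")
  }
  obs <- active_observations(dataset)
  grp <- paste(obs$subject_id, obs$landmark, sep = "\r")

  ## gross rule: distance to the per-subject, per-landmark median -------
  medx <- stats::ave(obs$x, grp, FUN = stats::median)
  medy <- stats::ave(obs$y, grp, FUN = stats::median)
  medz <- stats::ave(obs$z, grp, FUN = stats::median)
  d <- sqrt((obs$x - medx)^2 + (obs$y - medy)^2 + (obs$z - medz)^2)
  gross_hit <- d > gross_mm
  flagged <- list()
  if (any(gross_hit)) {
    flagged[[1]] <- data.frame(
      subject_id = obs$subject_id[gross_hit],
      operator_id = obs$operator_id[gross_hit],
      session_id = obs$session_id[gross_hit],
      landmark = obs$landmark[gross_hit],
      rule = "gross", statistic = d[gross_hit], stringsAsFactors = FALSE)
  }

  ## Grubbs and Mandel on the remaining data ----------------------------
  kept <- obs[!gross_hit, , drop = FALSE]
  gm <- grubbs_mandel(kept, grubbs_alpha, mandel_alpha)
  if (!is.null(gm$flagged)) flagged[[length(flagged) + 1L]] <- gm$flagged

  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    empty_flag_frame()
  flagged <- flagged[!duplicated(flagged[c("subject_id", "operator_id",
                                           "session_id", "landmark",
                                           "rule")]), , drop = FALSE]
  rownames(flagged) <- NULL
  structure(list(flagged = flagged, advisory = gm$advisory,
                 skipped = gm$skipped,
                 rules = list(gross_mm = gross_mm,
                              grubbs_alpha = grubbs_alpha,
                              mandel_alpha = mandel_alpha)),
            class = "outlier_report")
}

empty_flag_frame <- function() {
  data.frame(subject_id = character(0), operator_id = character(0),
             session_id = character(0), landmark = character(0),
             rule = character(0), statistic = numeric(0),
             stringsAsFactors = FALSE)
}

# Vectorized Grubbs (flagging) and Mandel h/k (advisory) over all
# subject-by-landmark strata at once, via cell-level aggregation.
grubbs_mandel <- function(obs, grubbs_alpha, mandel_alpha) {
  out <- list(flagged = NULL, skipped = character(0),
              advisory = empty_advisory_frame())
  if (!nrow(obs)) return(out)
  P <- cbind(obs$x, obs$y, obs$z)
  cell_of_obs <- factor(paste(obs$subject_id, obs$landmark,
                              obs$operator_id, sep = "\r"))
  n_cell <- as.vector(table(cell_of_obs))
  M <- rowsum(P, cell_of_obs) / n_cell            # cell means, n_cells x 3
  first <- !duplicated(cell_of_obs)
  cell_subject <- obs$subject_id[first][order(cell_of_obs[first])]
  cell_landmark <- obs$landmark[first][order(cell_of_obs[first])]
  cell_operator <- obs$operator_id[first][order(cell_of_obs[first])]
  gf <- factor(paste(cell_subject, cell_landmark, sep = "\r"))
  p_g <- as.vector(table(gf))                     # operators per stratum
  p_c <- p_g[as.integer(gf)]

  gmean <- rowsum(M, gf) / p_g
  dev <- M - gmean[as.integer(gf), , drop = FALSE]
  sd_m <- sqrt(rowsum(dev^2, gf) / pmax(p_g - 1, 1))  # per-axis SD of means
  sd_c <- sd_m[as.integer(gf), , drop = FALSE]

  small <- p_g < 3
  if (any(small)) {
    lab <- strsplit(levels(gf)[small], "\r", fixed = TRUE)
    out$skipped <- vapply(lab, function(s) {
      paste0("grubbs: ", s[1], "/", s[2], " has fewer than 3 operator cells")
    }, character(1))
  }

  ## Grubbs: flag the most deviant cell mean where G exceeds the critical
  ## value for the stratum size
  crit_grubbs <- grubbs_critical(pmax(p_c, 3), grubbs_alpha)
  flag_rows <- NULL
  for (axis in 1:3) {
    ok <- p_c >= 3 & sd_c[, axis] > 0
    G <- abs(dev[, axis]) / sd_c[, axis]
    gmax <- stats::ave(abs(dev[, axis]), gf, FUN = max)
    hit <- ok & G > crit_grubbs & abs(dev[, axis]) >= gmax
    if (any(hit)) {
      take <- obs_rows_of_cells(obs, cell_subject[hit], cell_landmark[hit],
                                cell_operator[hit], G[hit])
      flag_rows <- rbind(flag_rows, take)
    }
  }
  if (!is.null(flag_rows)) {
    flag_rows$rule <- "grubbs"
    out$flagged <- flag_rows[c("subject_id", "operator_id", "session_id",
                               "landmark", "rule", "statistic")]
  }

  ## Mandel h (between-operator) -- advisory
  adv <- list()
  crit_h <- mandel_h_critical(pmax(p_c, 3), mandel_alpha)
  for (axis in 1:3) {
    ok <- p_c >= 3 & sd_c[, axis] > 0
    h <- dev[, axis] / sd_c[, axis]
    hit <- ok & abs(h) > crit_h
    if (any(hit)) {
      adv[[length(adv) + 1L]] <- data.frame(
        subject_id = cell_subject[hit], landmark = cell_landmark[hit],
        operator_id = cell_operator[hit], axis = c("x", "y", "z")[axis],
        statistic = "h", value = h[hit], critical = crit_h[hit],
        stringsAsFactors = FALSE)
    }
  }

  ## Mandel k (within-operator spread) -- advisory
  ss <- rowsum(P^2, cell_of_obs) - n_cell * M^2
  has_rep <- n_cell >= 2
  s_cell <- ss
  s_cell[] <- NA_real_
  s_cell[has_rep, ] <- sqrt(pmax(ss[has_rep, , drop = FALSE], 0) /
                              (n_cell[has_rep] - 1))
  rep_per_g <- as.vector(rowsum(as.numeric(has_rep), gf))
  nbar_g <- as.vector(rowsum(ifelse(has_rep, n_cell, 0), gf)) /
    pmax(rep_per_g, 1)
  for (axis in 1:3) {
    s2sum <- as.vector(rowsum(ifelse(has_rep, s_cell[, axis]^2, 0), gf))
    spool_g <- sqrt(s2sum / pmax(rep_per_g, 1))
    spool_c <- spool_g[as.integer(gf)]
    ok <- has_rep & rep_per_g[as.integer(gf)] >= 2 & spool_c > 0
    k <- s_cell[, axis] / spool_c
    kc <- mandel_k_critical(pmax(rep_per_g, 2)[as.integer(gf)],
                            pmax(nbar_g - 1, 1)[as.integer(gf)],
                            mandel_alpha)
    hit <- ok & !is.na(k) & k > kc
    if (any(hit)) {
      adv[[length(adv) + 1L]] <- data.frame(
        subject_id = cell_subject[hit], landmark = cell_landmark[hit],
        operator_id = cell_operator[hit], axis = c("x", "y", "z")[axis],
        statistic = "k", value = k[hit], critical = kc[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (length(adv)) out$advisory <- do.call(rbind, adv)
  out
}

empty_advisory_frame <- function() {
  data.frame(subject_id = character(0), landmark = character(0),
             operator_id = character(0), axis = character(0),
             statistic = character(0), value = numeric(0),
             critical = numeric(0), stringsAsFactors = FALSE)
}

# All observations belonging to the given cells, carrying the statistic.
obs_rows_of_cells <- function(obs, subj, lm, op, stat) {
  ckey <- paste(obs$subject_id, obs$landmark, obs$operator_id, sep = "\r")
  fkey <- paste(subj, lm, op, sep = "\r")
  m <- match(ckey, fkey)
  sel <- !is.na(m)
  data.frame(subject_id = obs$subject_id[sel],
             operator_id = obs$operator_id[sel],
             session_id = obs$session_id[sel],
             landmark = obs$landmark[sel],
             statistic = stat[m[sel]], stringsAsFactors = FALSE)
}

# Two-sided Grubbs critical value for a sample of size n at level alpha.
grubbs_critical <- function(n, alpha) {
  t <- stats::qt(1 - alpha / (2 * n), n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

# Critical value of Mandel's h for p operators (two-sided alpha).
mandel_h_critical <- function(p, alpha) {
  t <- stats::qt(1 - alpha / 2, p - 2)
  (p - 1) * t / sqrt(p * (p - 2 + t^2))
}

# Critical value of Mandel's k for p operators, nu within-cell df.
mandel_k_critical <- function(p, nu, alpha) {
  f <- stats::qf(1 - alpha, nu, nu * (p - 1))
  sqrt(p * f / ((p - 1) + f))
}

#' Apply an outlier report to a dataset
#'
#' Marks every observation flagged by [screen_outliers()] (gross and
#' Grubbs rules) as `outlier_removed`, excluding it from all downstream
#' statistics. Advisory Mandel exceedances are not applied.
#'
#' @param dataset An [annotation_dataset()].
#' @param report An `outlier_report`.
#' @return The dataset with updated flags.
#' @export
apply_outlier_report <- function(dataset, report) {
  stopifnot(inherits(dataset, "annotation_dataset"),
            inherits(report, "outlier_report"))
  fl <- report$flagged
  if (!nrow(fl)) return(dataset)
  obs <- dataset$observations
  key <- paste(obs$subject_id, obs$operator_id, obs$session_id,
               obs$landmark, sep = "\r")
  fkey <- paste(fl$subject_id, fl$operator_id, fl$session_id, fl$landmark,
                sep = "\r")
  dataset$observations$outlier_removed <- obs$outlier_removed |
    key %in% fkey
  dataset
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Outlier report:", nrow(x$flagged), "observation(s) flagged (",
      sum(x$flagged$rule == "gross"), "gross,",
      sum(x$flagged$rule == "grubbs"), "Grubbs ),",
      nrow(x$advisory), "advisory Mandel exceedance(s)\n")
  if (nrow(x$flagged)) print(utils::head(x$flagged, 20), row.names = FALSE)
  invisible(x)
}
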