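#' Configuration for a full analysis run
#'
#' @param input Path to an annotation file (or a directory containing
#'   `dataset.csv` / `dataset.xml`), or an [annotation_dataset()] object.
#' @param dialect `"csv"` or `"xml"`.
#' @param superior_hint 3-vector fixing the superior direction, or `NULL`
#'   for the Menton fallback rule.
#' @param gross_mm,grubbs_alpha,mandel_alpha Outlier-screening thresholds,
#'   see [screen_outliers()].
#' @param reliability_mm Length-2 increasing thresholds (mm) separating
#'   acceptable / useful / caution (fixed at `c(1, 2)` in the clinical
#'   ranking; retained here for transparency and validated).
#' @param output_dir Directory for report files, or `NULL` to skip
#'   writing.
#' @param plots Whether to render Bland-Altman plots (PNG, one per
#'   landmark and axis).
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, dialect = "csv",
                            superior_hint = c(0, 0, 1),
                            gross_mm = 5, grubbs_alpha = 0.01,
                            mandel_alpha = 0.01,
                            reliability_mm = c(1, 2),
                            output_dir = NULL, plots = FALSE,
                            log_level = c("info", "quiet")) {
  if (gross_mm <= 0) stop("gross_mm must be positive")
  if (length(reliability_mm) != 2 || any(reliability_mm <= 0) ||
      diff(reliability_mm) <= 0) {
    stop("reliability_mm must be two strictly increasing positive values")
  }
  structure(list(input = input, dialect = dialect,
                 superior_hint = superior_hint, gross_mm = gross_mm,
                 grubbs_alpha = grubbs_alpha, mandel_alpha = mandel_alpha,
                 reliability_mm = reliability_mm,
                 output_dir = output_dir, plots = plots,
                 log_level = match.arg(log_level)),
            class = "analysis_config")
}

log_info <- function(config, ...) {
  if (identical(config$log_level, "info")) message("[cephrr] ", ...)
}

#' Run the full landmark reliability analysis
#'
#' Executes the pipeline end to end: read annotations, screen and remove
#' outliers, build per-subject mean FH frames, compute the per-landmark,
#' per-axis R&R table, the vertical-measurement R&R tables under both FH
#' planes, the plane-parallelism summary and the Bland-Altman series.
#' When `config$output_dir` is set, writes `rr_table.csv`,
#' `vertical_conventional.csv`, `vertical_novel.csv`, `outliers.csv`,
#' `bland_altman.csv`, `parallelism.json` and `summary.json` (plus PNG
#' plots when `config$plots`).
#'
#' @param config An [analysis_config()] with a non-`NULL` `input`.
#' @return A list of class `analysis_report`: `outliers`
#'   (`outlier_report`), `rr` (`rr_table`), `vertical` (list
#'   `conventional` / `novel`), `parallelism`, `bland_altman` (combined
#'   data frame), `summary` (the content of `summary.json`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dataset <- resolve_input(config)
  log_info(config, "dataset: ", nrow(dataset$observations),
           " observations, ", dataset$design["n_subjects"], " subjects")

  report <- screen_outliers(dataset, gross_mm = config$gross_mm,
                            grubbs_alpha = config$grubbs_alpha,
                            mandel_alpha = config$mandel_alpha)
  if (nrow(report$flagged)) {
    for (i in seq_len(nrow(report$flagged))) {
      f <- report$flagged[i, ]
      log_info(config, "outlier removed (", f$rule, "): ", f$subject_id,
               "/", f$operator_id, "/", f$session_id, "/", f$landmark,
               " statistic ", signif(f$statistic, 4))
    }
  }
  dataset <- apply_outlier_report(dataset, report)

  frames <- withCallingHandlers(
    fh_frames(dataset, superior_hint = config$superior_hint),
    warning = function(w) {
      log_info(config, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!length(frames)) stop("no subject has a constructible FH frame")

  rr <- rr_table(dataset, frames)
  for (s in attr(rr, "skipped")) log_info(config, "stratum skipped: ", s)

  vert <- vertical_rr(dataset, superior_hint = config$superior_hint %||%
                        c(0, 0, 1))
  for (s in attr(vert, "skipped_sessions")) log_info(config, s)

  par <- parallelism(dataset, superior_hint = config$superior_hint %||%
                       c(0, 0, 1))

  ba <- bland_altman_all(dataset, frames)

  summary <- list(
    design = as.list(dataset$design),
    n_observations = nrow(dataset$observations),
    outliers = list(n_flagged = nrow(report$flagged),
                    by_rule = as.list(table(report$flagged$rule)),
                    rules = report$rules),
    rr = list(n_records = nrow(rr),
              classes = as.list(table(rr$reliability_class)),
              worst_ci_repro_mm = max(rr$ci_repro)),
    vertical = list(
      conventional = list(n_records = nrow(vert$conventional),
                          max_ci_repro_mm = max(vert$conventional$ci_repro)),
      novel = list(n_records = nrow(vert$novel),
                   max_ci_repro_mm = max(vert$novel$ci_repro))),
    parallelism = par$summary)

  out <- structure(list(outliers = report, rr = rr, vertical = vert,
                        parallelism = par, bland_altman = ba,
                        summary = summary, frames = frames),
                   class = "analysis_report")
  if (!is.null(config$output_dir)) write_report(out, config)
  out
}

resolve_input <- function(config) {
  input <- config$input
  if (is.null(input)) stop("config$input is required")
  if (inherits(input, "annotation_dataset")) return(input)
  if (dir.exists(input)) {
    candidate <- file.path(input, paste0("dataset.", config$dialect))
    if (!file.exists(candidate)) {
      stop("no ", basename(candidate), " found in directory ", input)
    }
    input <- candidate
  }
  read_annotations(input, dialect = config$dialect)
}

bland_altman_all <- function(dataset, frames) {
  out <- list()
  for (lm in unique(active_observations(dataset)$landmark)) {
    for (axis in c("x", "y", "z")) {
      ser <- tryCatch(bland_altman(dataset, lm, axis, frames),
                      error = function(e) NULL)
      if (is.null(ser)) next
      df <- unclass_df(ser)
      df$landmark <- lm
      df$axis <- axis
      df$limit <- attr(ser, "limits")[2]
      out[[length(out) + 1L]] <- df
    }
  }
  do.call(rbind, out)
}

write_report <- function(report, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$output_dir, f)
  utils::write.csv(unclass_df(report$rr), p("rr_table.csv"),
                   row.names = FALSE)
  utils::write.csv(unclass_df(report$vertical$conventional),
                   p("vertical_conventional.csv"), row.names = FALSE)
  utils::write.csv(unclass_df(report$vertical$novel),
                   p("vertical_novel.csv"), row.names = FALSE)
  utils::write.csv(report$outliers$flagged, p("outliers.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bland_altman, p("bland_altman.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(per_subject = report$parallelism$per_subject,
                            summary = report$parallelism$summary),
                       p("parallelism.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  jsonlite::write_json(report$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$plots)) {
    dir.create(p("bland_altman"), showWarnings = FALSE)
    for (lm in unique(report$bland_altman$landmark)) {
      for (axis in unique(report$bland_altman$axis)) {
        sel <- report$bland_altman$landmark == lm &
          report$bland_altman$axis == axis
        if (!any(sel)) next
        gg <- plot_bland_altman_df(report$bland_altman[sel, ], lm, axis)
        fn <- p(file.path("bland_altman",
                          paste0(gsub("[^A-Za-z0-9]", "_", lm), "_",
                                 axis, ".png")))
        ggplot2::ggsave(fn, gg, width = 6, height = 4, dpi = 120)
      }
    }
  }
  log_info(config, "report written to ", config$output_dir)
  invisible(report)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("cephrr analysis report\n")
  cat("  R&R records:", nrow(x$rr), "; classes:",
      paste(names(table(x$rr$reliability_class)),
            table(x$rr$reliability_class), collapse = ", "), "\n")
  cat("  outliers flagged:", nrow(x$outliers$flagged), "\n")
  s <- x$parallelism$summary
  cat(sprintf("  FH plane angle: %.2f deg (SD %.2f) over %d subjects\n",
              s$mean_abs_angle_deg, s$sd_abs_angle_deg, s$n_subjects))
  invisible(x)
}

#' Validate a summary report against the shipped schema
#'
#' Checks the structure written to `summary.json` against the JSON schema
#' shipped in `inst/schema/summary.schema.json` (a self-contained subset
#' of JSON Schema: object properties, required fields and primitive
#' types).
#'
#' @param summary The parsed summary (a list, as returned in
#'   `report$summary` or read back with `jsonlite::read_json`).
#' @param schema_path Path to the schema; defaults to the shipped one.
#' @return `TRUE` if valid, otherwise an error describing the first
#'   violation.
#' @export
check_summary_schema <- function(summary,
                                 schema_path = system.file(
                                   "schema", "summary.schema.json",
                                   package = "cephrr")) {
  schema <- jsonlite::read_json(schema_path)
  check_node(summary, schema, "$")
  TRUE
}

check_node <- function(x, schema, where) {
  type <- schema$type
  ok <- switch(type,
               object = is.list(x) && (is.null(names(x)) == (length(x) == 0) ||
                                         !is.null(names(x))),
               number = is.numeric(x) && length(x) == 1,
               integer = is.numeric(x) && length(x) == 1 &&
                 x == round(x),
               string = is.character(x) && length(x) == 1,
               array = is.list(x) || is.vector(x),
               TRUE)
  if (!isTRUE(ok)) {
    stop("summary schema violation at ", where, ": expected ", type)
  }
  if (type == "object") {
    for (req in unlist(schema$required)) {
      if (!req %in% names(x)) {
        stop("summary schema violation at ", where,
             ": missing required field '", req, "'")
      }
    }
    for (nm in names(schema$properties)) {
      if (nm %in% names(x)) {
        check_node(x[[nm]], schema$properties[[nm]],
                   paste0(where, ".", nm))
      }
    }
  }
  invisible(TRUE)
}
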