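#' Read landmark annotations from file
#'
#' Reads a landmark annotation dataset from either the CSV dialect (header
#' `subject_id,operator_id,session_id,landmark,x_mm,y_mm,z_mm`, optional
#' trailing `flags` column) or the XML dialect
#' (`<study><subject><operator><session><landmark name x y z/>`).
#' Coordinates are in mm. Unknown landmark names and duplicate
#' (subject, operator, session, landmark) keys are rejected.
#'
#' @param path Path to the file to read.
#' @param dialect `"csv"` or `"xml"`.
#' @param catalog Catalog used for validation; defaults to
#'   [default_catalog()].
#' @return An [annotation_dataset()].
#' @export
read_annotations <- function(path, dialect = c("csv", "xml"),
                             catalog = default_catalog()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  obs <- switch(dialect,
                csv = read_annotations_csv(path),
                xml = read_annotations_xml(path))
  annotation_dataset(obs, catalog = catalog)
}

csv_header <- c("subject_id", "operator_id", "session_id", "landmark",
                "x_mm", "y_mm", "z_mm")

read_annotations_csv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  got <- strsplit(first, ",", fixed = TRUE)[[1]]
  if (length(got) < length(csv_header) ||
      !identical(got[seq_along(csv_header)], csv_header)) {
    stop("malformed CSV header at line 1 of ", path,
         "; expected: ", paste(csv_header, collapse = ","))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character",
                                        operator_id = "character",
                                        session_id = "character",
                                        landmark = "character"))
  for (v in c("x_mm", "y_mm", "z_mm")) {
    tab[[v]] <- suppressWarnings(as.numeric(tab[[v]]))
    bad <- which(is.na(tab[[v]]) & !is_missing_row(tab))
    if (length(bad)) {
      stop("malformed numeric value in column ", v, " at line ",
           bad[1] + 1L, " of ", path)
    }
  }
  obs <- data.frame(subject_id = tab$subject_id,
                    operator_id = tab$operator_id,
                    session_id = tab$session_id,
                    landmark = tab$landmark,
                    x = tab$x_mm, y = tab$y_mm, z = tab$z_mm,
                    stringsAsFactors = FALSE)
  fl <- parse_flags(if ("flags" %in% names(tab)) tab$flags else
                      character(nrow(tab)))
  obs$missing <- fl$missing
  obs$outlier_removed <- fl$outlier_removed
  obs
}

is_missing_row <- function(tab) {
  if (!"flags" %in% names(tab)) return(rep(FALSE, nrow(tab)))
  grepl("missing", tab$flags %||% "")
}

parse_flags <- function(flags) {
  flags[is.na(flags)] <- ""
  list(missing = grepl("\\bmissing\\b", flags),
       outlier_removed = grepl("\\boutlier_removed\\b", flags))
}

format_flags <- function(obs) {
  out <- character(nrow(obs))
  out[obs$missing] <- "missing"
  both <- obs$missing & obs$outlier_removed
  out[obs$outlier_removed & !both] <- "outlier_removed"
  out[both] <- "missing;outlier_removed"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_annotations_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e)))
  if (xml2::xml_name(doc) != "study") {
    stop("malformed XML in ", path, ": root element must be <study>, got <",
         xml2::xml_name(doc), ">")
  }
  lm_nodes <- xml2::xml_find_all(doc,
                                 ".//subject/operator/session/landmark")
  n <- length(lm_nodes)
  attr_of <- function(nodes, a) xml2::xml_attr(nodes, a)
  # xml_find_first keeps one result per input node (xml_parent would
  # deduplicate shared parents)
  ses <- xml2::xml_find_first(lm_nodes, "ancestor::session")
  op  <- xml2::xml_find_first(lm_nodes, "ancestor::operator")
  su  <- xml2::xml_find_first(lm_nodes, "ancestor::subject")
  num_attr <- function(a) {
    v <- suppressWarnings(as.numeric(attr_of(lm_nodes, a)))
    v
  }
  obs <- data.frame(subject_id = attr_of(su, "id"),
                    operator_id = attr_of(op, "id"),
                    session_id = attr_of(ses, "id"),
                    landmark = attr_of(lm_nodes, "name"),
                    x = num_attr("x"), y = num_attr("y"), z = num_attr("z"),
                    stringsAsFactors = FALSE)
  fl <- parse_flags(attr_of(lm_nodes, "flags") %na% character(n))
  obs$missing <- fl$missing
  obs$outlier_removed <- fl$outlier_removed
  bad <- which((is.na(obs$x) | is.na(obs$y) | is.na(obs$z)) & !obs$missing)
  if (length(bad)) {
    stop("malformed <landmark> element #", bad[1], " (name=",
         obs$landmark[bad[1]], ") in ", path,
         ": x/y/z must be numeric")
  }
  if (any(is.na(obs$landmark))) {
    stop("malformed <landmark> element in ", path, ": missing name attribute")
  }
  obs
}

`%na%` <- function(a, b) {
  a[is.na(a)] <- ""
  a
}

#' Write landmark annotations to file
#'
#' Serializes an annotation dataset in the CSV or XML dialect understood by
#' [read_annotations()]. Coordinates are written with nine decimal places
#' (nanometre resolution at mm scale) so that a write/read round trip
#' reproduces positions to better than 1e-9 mm.
#'
#' @param dataset An [annotation_dataset()].
#' @param path Output file path.
#' @param dialect `"csv"` or `"xml"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(dataset, path, dialect = c("csv", "xml")) {
  dialect <- match.arg(dialect)
  validate_dataset(dataset)
  switch(dialect,
         csv = write_annotations_csv(dataset, path),
         xml = write_annotations_xml(dataset, path))
  invisible(path)
}

fmt_mm <- function(x) {
  out <- sprintf("%.9f", x)
  out[is.na(x)] <- "NA"
  out
}

write_annotations_csv <- function(dataset, path) {
  obs <- dataset$observations
  flags <- format_flags(obs)
  header <- paste(c(csv_header, "flags"), collapse = ",")
  lines <- paste(obs$subject_id, obs$operator_id, obs$session_id,
                 obs$landmark, fmt_mm(obs$x), fmt_mm(obs$y), fmt_mm(obs$z),
                 flags, sep = ",")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, lines), con)
}

write_annotations_xml <- function(dataset, path) {
  obs <- dataset$observations
  doc <- xml2::xml_new_root("study")
  flags <- format_flags(obs)
  # nested loops keep the schema self-describing; datasets are small
  for (su in unique(obs$subject_id)) {
    su_node <- xml2::xml_add_child(doc, "subject", id = su)
    o1 <- obs[obs$subject_id == su, , drop = FALSE]
    f1 <- flags[obs$subject_id == su]
    for (op in unique(o1$operator_id)) {
      op_node <- xml2::xml_add_child(su_node, "operator", id = op)
      o2 <- o1[o1$operator_id == op, , drop = FALSE]
      f2 <- f1[o1$operator_id == op]
      for (se in unique(o2$session_id)) {
        se_node <- xml2::xml_add_child(op_node, "session", id = se)
        o3 <- o2[o2$session_id == se, , drop = FALSE]
        f3 <- f2[o2$session_id == se]
        for (i in seq_len(nrow(o3))) {
          nd <- xml2::xml_add_child(se_node, "landmark",
                                    name = o3$landmark[i],
                                    x = fmt_mm(o3$x[i]),
                                    y = fmt_mm(o3$y[i]),
                                    z = fmt_mm(o3$z[i]))
          if (nzchar(f3[i])) xml2::xml_set_attr(nd, "flags", f3[i])
        }
      }
    }
  }
  xml2::write_xml(doc, path)
}
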