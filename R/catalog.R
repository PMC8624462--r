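#' The default 33-landmark cephalometric catalog
#'
#' Returns the catalog of 33 craniofacial landmarks used throughout the
#' package: 15 "conventional" cephalometric landmarks, 6 "foraminal"
#' landmarks located on skull-base and facial foramina, and 12 "dental"
#' landmarks on incisors and first molars (FDI tooth numbering).
#'
#' Bilateral landmarks come in left/right pairs sharing a stem (for example
#' `Or-L` / `Or-R`); midline landmarks carry laterality `"midline"`.
#'
#' @return A data frame of class `landmark_catalog` with columns `name`,
#'   `full_name`, `group` (one of `"conventional"`, `"foraminal"`,
#'   `"dental"`), `laterality` (one of `"left"`, `"right"`, `"midline"`)
#'   and `description`.
#' @examples
#' cat33 <- default_catalog()
#' nrow(cat33)
#' table(cat33$group)
#' @export
default_catalog <- function() {
  conv <- function(name, full, lat, desc) {
    list(name, full, "conventional", lat, desc)
  }
  fora <- function(name, full, lat, desc) {
    list(name, full, "foraminal", lat, desc)
  }
  dent <- function(name, full, lat, desc) {
    list(name, full, "dental", lat, desc)
  }
  rows <- list(
    conv("Na",    "Nasion",               "midline", "Medial and upper point of the frontonasal suture"),
    conv("Or-L",  "Orbitale L",           "left",    "Lowest point of the orbital rim, left"),
    conv("Or-R",  "Orbitale R",           "right",   "Lowest point of the orbital rim, right"),
    conv("ANS",   "Anterior Nasal Spine", "midline", "Medial and most anterior point of the nasal spine"),
    conv("A",     "A Point",              "midline", "Medial and most posterior point of the maxilla"),
    conv("B",     "B Point",              "midline", "Medial and most posterior point of the mandible"),
    conv("Pog",   "Pogonion",             "midline", "Medial and most anterior point of the mandible"),
    conv("Gn",    "Gnathion",             "midline", "Medial midpoint between Pogonion and Menton"),
    conv("Me",    "Menton",               "midline", "Medial and lowest point of the mandible"),
    conv("Go-L",  "Gonion L",             "left",    "Midpoint of the gonial angle, left"),
    conv("Go-R",  "Gonion R",             "right",   "Midpoint of the gonial angle, right"),
    conv("Po-L",  "Porion L",             "left",    "External and uppermost point of the auditory canal, left"),
    conv("Po-R",  "Porion R",             "right",   "External and uppermost point of the auditory canal, right"),
    conv("PNS",   "Posterior Nasal Spine","midline", "Medial and most distal point of the osseous palate"),
    conv("S",     "Sella",                "midline", "Central point of the sella turcica"),
    fora("IF-L",  "Infraorbital Foramen L",       "left",  "External and most distal point of the infraorbital foramen, left"),
    fora("IF-R",  "Infraorbital Foramen R",       "right", "External and most distal point of the infraorbital foramen, right"),
    fora("MF-L",  "Mental Foramen L",             "left",  "External and most mesial point of the mental foramen, left"),
    fora("MF-R",  "Mental Foramen R",             "right", "External and most mesial point of the mental foramen, right"),
    fora("IAF-L", "Internal Acoustic Foramen L",  "left",  "External, most mesial and posterior point of the internal acoustic foramen, left"),
    fora("IAF-R", "Internal Acoustic Foramen R",  "right", "External, most mesial and posterior point of the internal acoustic foramen, right"),
    dent("11E", "11 Edge",     "right", "Midpoint of the incisal edge of tooth 11"),
    dent("21E", "21 Edge",     "left",  "Midpoint of the incisal edge of tooth 21"),
    dent("31E", "31 Edge",     "left",  "Midpoint of the incisal edge of tooth 31"),
    dent("41E", "41 Edge",     "right", "Midpoint of the incisal edge of tooth 41"),
    dent("11A", "11 Apex",     "right", "Root apex of tooth 11"),
    dent("21A", "21 Apex",     "left",  "Root apex of tooth 21"),
    dent("31A", "31 Apex",     "left",  "Root apex of tooth 31"),
    dent("41A", "41 Apex",     "right", "Root apex of tooth 41"),
    dent("16O", "16 Occlusal", "right", "Summit of the mesio-palatal cusp of tooth 16"),
    dent("26O", "26 Occlusal", "left",  "Summit of the mesio-palatal cusp of tooth 26"),
    dent("36O", "36 Occlusal", "left",  "Central fossa of tooth 36"),
    dent("46O", "46 Occlusal", "right", "Central fossa of tooth 46")
  )
  out <- data.frame(
    name        = vapply(rows, `[[`, character(1), 1L),
    full_name   = vapply(rows, `[[`, character(1), 2L),
    group       = vapply(rows, `[[`, character(1), 3L),
    laterality  = vapply(rows, `[[`, character(1), 4L),
    description = vapply(rows, `[[`, character(1), 5L),
    stringsAsFactors = FALSE
  )
  class(out) <- c("landmark_catalog", "data.frame")
  validate_catalog(out)
  out
}

#' Validate a landmark catalog
#'
#' Checks structural invariants of a catalog: required columns, unique
#' names, legal group and laterality values, and that every left landmark
#' has a right partner with the same stem.
#'
#' @param catalog A `landmark_catalog` data frame.
#' @return The catalog, invisibly, if valid; otherwise an error is raised.
#' @export
validate_catalog <- function(catalog) {
  required <- c("name", "full_name", "group", "laterality", "description")
  if (!all(required %in% names(catalog))) {
    stop("catalog is missing columns: ",
         paste(setdiff(required, names(catalog)), collapse = ", "))
  }
  if (anyDuplicated(catalog$name)) {
    stop("duplicate landmark names in catalog: ",
         paste(unique(catalog$name[duplicated(catalog$name)]), collapse = ", "))
  }
  if (!all(catalog$group %in% c("conventional", "foraminal", "dental"))) {
    stop("catalog group must be conventional, foraminal or dental")
  }
  if (!all(catalog$laterality %in% c("left", "right", "midline"))) {
    stop("catalog laterality must be left, right or midline")
  }
  stem <- landmark_stem(catalog$name)
  lefts  <- stem[catalog$laterality == "left"]
  rights <- stem[catalog$laterality == "right"]
  if (!setequal(lefts, rights)) {
    stop("bilateral landmarks must come in matched L/R pairs")
  }
  invisible(catalog)
}

# Stem shared by a bilateral pair: "Or-L" -> "Or"; for dental codes the FDI
# quadrant digit encodes the side, so it is replaced by the arch
# ("11E"/"21E" -> "U1E", "36O"/"46O" -> "L6O").
landmark_stem <- function(name) {
  stem <- sub("-[LR]$", "", name)
  dental <- grepl("^[1-4][0-9][A-Z]$", name)
  arch <- ifelse(substr(name[dental], 1, 1) %in% c("1", "2"), "U", "L")
  stem[dental] <- paste0(arch, substring(name[dental], 2))
  stem
}

#' @export
print.landmark_catalog <- function(x, ...) {
  cat("Landmark catalog:", nrow(x), "landmarks (",
      sum(x$group == "conventional"), "conventional,",
      sum(x$group == "foraminal"), "foraminal,",
      sum(x$group == "dental"), "dental )\n")
  print.data.frame(x[, c("name", "group", "laterality", "full_name")],
                   row.names = FALSE, ...)
  invisible(x)
}

#' Export a catalog as JSON
#'
#' @param catalog A `landmark_catalog`.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(catalog, path) {
  validate_catalog(catalog)
  jsonlite::write_json(unclass_df(catalog), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

unclass_df <- function(x) {
  class(x) <- "data.frame"
  x
}
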