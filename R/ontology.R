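#' The default gastric histology class ontology
#'
#' Returns the built-in vocabulary of annotation classes used throughout the
#' package: 16 invasive-carcinoma codes, the two dysplasia grades (GINH,
#' GINL), ulceration markers (fibrin F, granulation tissue GT) and
#' non-neoplastic mucosal classes. Each class carries its display-color
#' family (carcinoma red, dysplasia/ulceration blue, non-neoplastic green),
#' its Lauren family and its grade class.
#'
#' The grade-class and Lauren assignments of individual codes are
#' conventions, not measurements; both are plain columns of the returned
#' tibble and can be edited before passing the ontology on (for example,
#' whether high-grade papillary carcinoma PACG2 counts as a high-grade class
#' is a reporting choice left to the caller; the default keeps it low).
#'
#' @return A tibble of class `gm_ontology` with columns `code`, `group`
#'   (one of `invasive_carcinoma`, `hg_dysplasia`, `lg_dysplasia`,
#'   `non_neoplastic`, `ulceration_marker`), `display_color`,
#'   `lauren_family` (`intestinal`, `diffuse`, `indeterminate`, `none`),
#'   `grade_class` (`low`, `high`, `none`) and `who_family` (the family bin
#'   used when folding subtype codes into WHO histotypes).
#' @examples
#' ont <- gastric_ontology()
#' dplyr::count(ont, group)
#' @export
gastric_ontology <- function() {
  carcinoma <- tibble::tribble(
    ~code,      ~lauren_family,  ~grade_class, ~who_family,
    "TACG1",    "intestinal",    "low",        "TAC",
    "TACG2",    "intestinal",    "low",        "TAC",
    "TACG3",    "intestinal",    "high",       "TAC",
    "PACG1",    "intestinal",    "low",        "PAC",
    "PACG2",    "intestinal",    "low",        "PAC",
    "MPAC",     "intestinal",    "high",       "MPAC",
    "PCC",      "diffuse",       "high",       "PCC",
    "PCC-NOS",  "diffuse",       "high",       "PCC",
    "MAC1",     "indeterminate", "low",        "MAC",
    "MAC2",     "indeterminate", "high",       "MAC",
    "ACLS",     "indeterminate", "high",       "ACLS",
    "HAC",      "indeterminate", "high",       "HAC",
    "ACFG",     "indeterminate", "high",       "ACFG",
    "SCC",      "indeterminate", "high",       "SCC",
    "NDC",      "indeterminate", "high",       "NDC",
    "NED",      "indeterminate", "high",       "NEC"
  )
  carcinoma$group <- "invasive_carcinoma"

  other <- tibble::tribble(
    ~code, ~group,              ~lauren_family, ~grade_class, ~who_family,
    "GINH", "hg_dysplasia",      "none",         "high",       NA,
    "GINL", "lg_dysplasia",      "none",         "low",        NA,
    "F",    "ulceration_marker", "none",         "none",       NA,
    "GT",   "ulceration_marker", "none",         "none",       NA,
    "NG",   "non_neoplastic",    "none",         "none",       NA,
    "IM",   "non_neoplastic",    "none",         "none",       NA,
    "LT",   "non_neoplastic",    "none",         "none",       NA,
    "CG",   "non_neoplastic",    "none",         "none",       NA,
    "FP",   "non_neoplastic",    "none",         "none",       NA
  )

  ont <- dplyr::bind_rows(carcinoma, other)
  ont$display_color <- group_color(ont$group)
  ont <- dplyr::select(
    ont, "code", "group", "display_color", "lauren_family",
    "grade_class", "who_family"
  )
  attr(ont, "version") <- "gastromorph-default-1"
  class(ont) <- c("gm_ontology", class(ont))
  validate_ontology(ont)
}

group_color <- function(group) {
  dplyr::case_match(
    group,
    "invasive_carcinoma" ~ "red",
    c("hg_dysplasia", "lg_dysplasia", "ulceration_marker") ~ "blue",
    "non_neoplastic" ~ "green",
    .default = NA_character_
  )
}

ontology_groups <- c(
  "invasive_carcinoma", "hg_dysplasia", "lg_dysplasia",
  "non_neoplastic", "ulceration_marker"
)

#' Validate a class ontology
#'
#' Checks code uniqueness, the group vocabulary and the group-to-color
#' mapping (carcinoma red, dysplasia and ulceration blue, non-neoplastic
#' green). Called by [gastric_ontology()] and [load_ontology()]; useful
#' directly after editing an ontology by hand.
#'
#' @param ontology A tibble with at least `code`, `group`, `display_color`,
#'   `lauren_family`, `grade_class` columns.
#' @return The ontology, invisibly classed as `gm_ontology`, or an error.
#' @export
validate_ontology <- function(ontology) {
  req <- c("code", "group", "display_color", "lauren_family", "grade_class")
  missing <- setdiff(req, names(ontology))
  if (length(missing) > 0) {
    stop("ontology is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(ontology) == 0) stop("ontology defines no classes")
  dup <- ontology$code[duplicated(ontology$code)]
  if (length(dup) > 0) {
    stop("duplicate class code(s) in ontology: ",
         paste(unique(dup), collapse = ", "))
  }
  bad_group <- setdiff(unique(ontology$group), ontology_groups)
  if (length(bad_group) > 0) {
    stop("unknown ontology group(s): ", paste(bad_group, collapse = ", "))
  }
  expected <- group_color(ontology$group)
  off <- ontology$display_color != expected
  if (any(off)) {
    stop("display_color inconsistent with group for code(s): ",
         paste(ontology$code[off], collapse = ", "))
  }
  bad_lf <- setdiff(unique(ontology$lauren_family),
                    c("intestinal", "diffuse", "indeterminate", "none"))
  if (length(bad_lf) > 0) {
    stop("unknown lauren_family value(s): ", paste(bad_lf, collapse = ", "))
  }
  bad_gc <- setdiff(unique(ontology$grade_class), c("low", "high", "none"))
  if (length(bad_gc) > 0) {
    stop("unknown grade_class value(s): ", paste(bad_gc, collapse = ", "))
  }
  if (!inherits(ontology, "gm_ontology")) {
    class(ontology) <- c("gm_ontology", class(ontology))
  }
  invisible(ontology)
}

#' Load a class ontology from file or use the default
#'
#' Reads a JSON or YAML ontology definition (an array of objects with the
#' [gastric_ontology()] columns) and validates it. With no path the built-in
#' default ontology is returned.
#'
#' @param path Optional path to a `.json`, `.yaml` or `.yml` ontology file.
#' @return A validated `gm_ontology` tibble.
#' @examples
#' ont <- load_ontology()
#' nrow(ont)
#' @export
load_ontology <- function(path = NULL) {
  if (is.null(path)) return(gastric_ontology())
  if (!file.exists(path)) stop("ontology file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported ontology format: .", ext)
  )
  ont <- tibble::as_tibble(
    if (is.data.frame(raw)) raw else dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  )
  if (!"display_color" %in% names(ont) && "group" %in% names(ont)) {
    ont$display_color <- group_color(ont$group)
  }
  if (!"who_family" %in% names(ont)) ont$who_family <- NA_character_
  out <- validate_ontology(ont)
  attr(out, "version") <- paste0("file:", basename(path))
  out
}

#' Write an ontology to a JSON file
#'
#' @param ontology A `gm_ontology` tibble.
#' @param path Output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  validate_ontology(ontology)
  jsonlite::write_json(as.data.frame(ontology), path, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# codes belonging to a group (helper used across modules)
codes_in_group <- function(ontology, group) {
  ontology$code[ontology$group %in% group]
}

# codes considered high grade among invasive carcinoma
high_grade_codes <- function(ontology) {
  ontology$code[ontology$group == "invasive_carcinoma" &
                  ontology$grade_class == "high"]
}
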