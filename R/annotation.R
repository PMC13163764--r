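#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' Construct a slide annotation
#'
#' A slide annotation bundles the slide identifier, the pixel dimensions of
#' the scanned area, and a set of class-labelled polygons. Coordinates are
#' 0-based continuous pixel coordinates: pixel `(i, j)` is the half-open
#' cell `[i, i+1) x [j, j+1)`, so a slide of width `w` spans `[0, w]`.
#'
#' @param slide_id Character scalar.
#' @param width_px,height_px Positive integer slide dimensions in pixels.
#' @param polygons A tibble with columns `polygon_id`, `class_code`, `x`,
#'   `y` (one row per vertex, vertex order preserved within `polygon_id`),
#'   or a list of lists with fields `class_code` and `vertices` (an n x 2
#'   matrix).
#' @param ontology Ontology used to check class codes; default
#'   [gastric_ontology()].
#' @return A `gm_annotation` object: a list with `slide_id`, `width_px`,
#'   `height_px` and the vertex tibble `polygons`.
#' @examples
#' poly <- tibble::tibble(polygon_id = 1L, class_code = "NG",
#'                        x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
#' ann <- slide_annotation("s1", 64, 64, poly)
#' @export
slide_annotation <- function(slide_id, width_px, height_px, polygons,
                             ontology = gastric_ontology()) {
  if (!is.data.frame(polygons)) {
    polygons <- purrr::imap_dfr(polygons, function(p, i) {
      v <- p$vertices
      tibble::tibble(polygon_id = as.integer(i), class_code = p$class_code,
                     x = v[, 1], y = v[, 2])
    })
  }
  polygons <- tibble::as_tibble(polygons)
  if (nrow(polygons) > 0) {
    polygons$polygon_id <- as.integer(polygons$polygon_id)
  } else {
    polygons <- tibble::tibble(polygon_id = integer(), class_code = character(),
                               x = double(), y = double())
  }
  ann <- structure(
    list(slide_id = as.character(slide_id),
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         polygons = polygons),
    class = "gm_annotation"
  )
  validate_annotation(ann, ontology)
}

#' @export
print.gm_annotation <- function(x, ...) {
  cat(sprintf("<gm_annotation> slide %s (%d x %d px), %d polygon(s)\n",
              x$slide_id, x$width_px, x$height_px,
              dplyr::n_distinct(x$polygons$polygon_id)))
  invisible(x)
}

#' Validate a slide annotation
#'
#' Checks polygon vertex counts (>= 3), coordinate bounds against the slide
#' dimensions, and class-code membership in the ontology.
#'
#' @inheritParams slide_annotation
#' @param annotation A `gm_annotation` object.
#' @return The annotation, invisibly, or an error.
#' @export
validate_annotation <- function(annotation, ontology = gastric_ontology()) {
  stopifnot(inherits(annotation, "gm_annotation"))
  if (annotation$width_px < 1 || annotation$height_px < 1) {
    stop("slide dimensions must be positive")
  }
  p <- annotation$polygons
  if (nrow(p) > 0) {
    nv <- table(p$polygon_id)
    if (any(nv < 3)) {
      stop("polygon(s) with fewer than 3 vertices: ",
           paste(names(nv)[nv < 3], collapse = ", "))
    }
    unknown <- setdiff(unique(p$class_code), ontology$code)
    if (length(unknown) > 0) {
      stop("class code(s) not in ontology: ", paste(unknown, collapse = ", "))
    }
    if (any(p$x < 0 | p$x > annotation$width_px |
              p$y < 0 | p$y > annotation$height_px)) {
      stop("polygon vertex outside slide bounds [0, ", annotation$width_px,
           "] x [0, ", annotation$height_px, "]")
    }
  }
  invisible(annotation)
}

#' Read an ASAP-style annotation XML file
#'
#' Parses the ASAP dialect (`Annotations/Annotation` elements with
#' `Coordinates/Coordinate` children carrying `X`, `Y`, `Order` attributes).
#' The class code of each polygon is taken from the `PartOfGroup` attribute,
#' falling back to `Name` when `PartOfGroup` is absent or `"None"`. ASAP
#' files carry no slide dimensions, so these are read from a JSON sidecar
#' (fields `slide_id`, `width_px`, `height_px`), by default at
#' `<path without .xml>.json`.
#'
#' @param path Path to the annotation XML.
#' @param sidecar Path to the JSON sidecar with slide dimensions.
#' @param ontology Ontology used to check class codes.
#' @return A `gm_annotation` object.
#' @export
read_annotation_xml <- function(path, sidecar = sidecar_path(path),
                                ontology = gastric_ontology()) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (!file.exists(sidecar)) stop("slide-dimension sidecar not found: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  for (f in c("slide_id", "width_px", "height_px")) {
    if (is.null(meta[[f]])) stop("sidecar missing field: ", f)
  }
  doc <- xml2::read_xml(path)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  polys <- purrr::imap_dfr(anns, function(a, i) {
    code <- xml2::xml_attr(a, "PartOfGroup")
    if (is.na(code) || identical(code, "None") || code == "") {
      code <- xml2::xml_attr(a, "Name")
    }
    coords <- xml2::xml_find_all(a, ".//Coordinate")
    if (length(coords) < 3) {
      stop("annotation ", i, " has fewer than 3 coordinates")
    }
    ord <- as.numeric(xml2::xml_attr(coords, "Order"))
    x <- as.numeric(xml2::xml_attr(coords, "X"))
    y <- as.numeric(xml2::xml_attr(coords, "Y"))
    if (!anyNA(ord)) {
      x <- x[order(ord)]
      y <- y[order(ord)]
    }
    tibble::tibble(polygon_id = i, class_code = code, x = x, y = y)
  })
  slide_annotation(meta$slide_id, meta$width_px, meta$height_px, polys,
                   ontology = ontology)
}

sidecar_path <- function(path) sub("\\.xml$", ".json", path)

#' Write an annotation as ASAP-style XML (plus dimension sidecar)
#'
#' Emits an XML file that [read_annotation_xml()] reads back to an equal
#' annotation, and a JSON sidecar holding the slide dimensions.
#'
#' @param annotation A `gm_annotation` object.
#' @param path Output XML path.
#' @param sidecar Output sidecar path; default `<path without .xml>.json`.
#' @param ontology Ontology used to validate before writing.
#' @return `path`, invisibly.
#' @export
write_annotation_xml <- function(annotation, path,
                                 sidecar = sidecar_path(path),
                                 ontology = gastric_ontology()) {
  validate_annotation(annotation, ontology)
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  polys <- split(annotation$polygons, annotation$polygons$polygon_id)
  for (p in polys) {
    a <- xml2::xml_add_child(anns, "Annotation",
                             Name = paste0("Annotation ", p$polygon_id[1]),
                             Type = "Polygon",
                             PartOfGroup = p$class_code[1])
    cs <- xml2::xml_add_child(a, "Coordinates")
    for (k in seq_len(nrow(p))) {
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(k - 1),
                          X = format(p$x[k], digits = 15),
                          Y = format(p$y[k], digits = 15))
    }
  }
  groups <- xml2::xml_add_child(doc, "AnnotationGroups")
  for (code in unique(annotation$polygons$class_code)) {
    xml2::xml_add_child(groups, "Group", Name = code, PartOfGroup = "None")
  }
  xml2::write_xml(doc, path)
  jsonlite::write_json(
    list(slide_id = annotation$slide_id,
         width_px = annotation$width_px, height_px = annotation$height_px),
    sidecar, auto_unbox = TRUE
  )
  invisible(path)
}

#' Shoelace area of a polygon
#'
#' Area of a simple polygon from its vertex list via the shoelace formula;
#' non-negative regardless of vertex orientation. Self-intersecting input is
#' not detected: the returned value is then the signed even-odd area, whose
#' absolute value can undercount the covered region.
#'
#' @param x,y Numeric vertex coordinates (at least 3 vertices), or `x` may
#'   be an n x 2 matrix / data frame with columns `x`, `y`.
#' @return Area in square pixels.
#' @examples
#' polygon_area(c(0, 1, 1, 0), c(0, 0, 1, 1)) # 1
#' @export
polygon_area <- function(x, y = NULL) {
  if (is.null(y)) {
    if (is.data.frame(x)) { y <- x$y; x <- x$x } else { y <- x[, 2]; x <- x[, 1] }
  }
  n <- length(x)
  if (n < 3) stop("polygon needs at least 3 vertices")
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# perimeter in pixels, used in rasterization error bounds
polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(sqrt((x - x[j])^2 + (y - y[j])^2))
}
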