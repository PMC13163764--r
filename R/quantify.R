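# Rasterization, tiling, exclusion and composition.
#
# The label mask is an integer matrix (rows = y, cols = x) with 0 for
# unannotated pixels and k for the k-th class of the ontology. A pixel
# belongs to a polygon when its center (i + 0.5, j + 0.5) lies inside it
# under the even-odd rule; overlapping polygons are resolved
# last-drawn-wins in file order.

UNANNOTATED <- "unannotated"

#' Rasterize a slide annotation to a label mask
#'
#' Assigns every pixel of the slide the class of the polygon containing its
#' center (even-odd rule), or leaves it unannotated. Polygons are painted in
#' file order, so where polygons overlap the last one wins. Deterministic.
#'
#' @param annotation A `gm_annotation` object.
#' @param ontology Ontology supplying the class index; default
#'   [gastric_ontology()].
#' @return An integer matrix of dimension `height_px` x `width_px`; entry 0
#'   means unannotated, entry `k` refers to `ontology$code[k]`. The ontology
#'   codes are attached as attribute `codes`.
#' @export
rasterize_annotation <- function(annotation, ontology = gastric_ontology()) {
  validate_annotation(annotation, ontology)
  h <- annotation$height_px
  w <- annotation$width_px
  mask <- matrix(0L, nrow = h, ncol = w)
  polys <- annotation$polygons
  if (nrow(polys) > 0) {
    for (pid in unique(polys$polygon_id)) {
      p <- polys[polys$polygon_id == pid, ]
      k <- match(p$class_code[1], ontology$code)
      mask <- paint_polygon(mask, p$x, p$y, k)
    }
  }
  attr(mask, "codes") <- ontology$code
  attr(mask, "slide_id") <- annotation$slide_id
  mask
}

# linear indices of the pixels whose centers fall inside the polygon
# (even-odd rule, vectorized crossing test restricted to the bounding box)
polygon_cells <- function(h, w, px, py) {
  lo_c <- max(1L, floor(min(px) + 0.5) + 1L)
  hi_c <- min(w, ceiling(max(px) + 0.5))
  lo_r <- max(1L, floor(min(py) + 0.5) + 1L)
  hi_r <- min(h, ceiling(max(py) + 0.5))
  if (lo_c > hi_c || lo_r > hi_r) return(integer(0))
  ci <- lo_c:hi_c
  ri <- lo_r:hi_r
  cx <- rep(ci - 0.5, each = length(ri))
  cy <- rep(ri - 0.5, times = length(ci))
  inside <- rep(FALSE, length(cx))
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > cy) != (py[j] > cy))
    if (any(crosses)) {
      xin <- (px[j] - px[i]) * (cy[crosses] - py[i]) / (py[j] - py[i]) + px[i]
      hit <- inside[crosses]
      inside[crosses] <- xor(hit, cx[crosses] < xin)
    }
    j <- i
  }
  rows <- rep(ri, times = length(ci))[inside]
  cols <- rep(ci, each = length(ri))[inside]
  (cols - 1L) * h + rows
}

# paint the polygon's pixels onto the mask (last-drawn-wins)
paint_polygon <- function(mask, px, py, value) {
  idx <- polygon_cells(nrow(mask), ncol(mask), px, py)
  mask[idx] <- as.integer(value)
  mask
}

#' Tile a label mask into square slices
#'
#' Cuts the mask into a lattice of `tile_size` x `tile_size` slices
#' (default 256). Border tiles keep their true, smaller pixel budget so the
#' per-tile counts conserve the mask totals exactly.
#'
#' @param mask Label mask from [rasterize_annotation()].
#' @param tile_size Slice edge length in pixels (>= 1).
#' @return A tibble of class `gm_tiles` in long form: `row`, `col` (1-based
#'   tile indices), `class_code` (including `"unannotated"`) and `n_px`.
#'   Zero-count combinations are omitted. Attributes `tile_size`, `n_rows`,
#'   `n_cols`, `slide_id` describe the lattice.
#' @export
tile_slide <- function(mask, tile_size = 256) {
  if (length(tile_size) != 1 || is.na(tile_size) || tile_size < 1) {
    stop("tile_size must be a positive integer")
  }
  tile_size <- as.integer(tile_size)
  codes <- attr(mask, "codes")
  h <- nrow(mask); w <- ncol(mask)
  n_rows <- ceiling(h / tile_size)
  n_cols <- ceiling(w / tile_size)
  tr <- (seq_len(h) - 1L) %/% tile_size            # 0-based tile row per pixel row
  tc <- (seq_len(w) - 1L) %/% tile_size
  K <- length(codes)
  # combined index: tile id * (K+1) + label
  tile_of <- outer(tr, tc * n_rows, "+")           # 0-based tile id per pixel
  idx <- tile_of * (K + 1L) + mask + 1L
  counts <- tabulate(idx, nbins = n_rows * n_cols * (K + 1L))
  tiles <- tibble::tibble(
    row = rep(rep(seq_len(n_rows), times = n_cols), each = K + 1L),
    col = rep(seq_len(n_cols), each = n_rows * (K + 1L)),
    class_code = rep(c(UNANNOTATED, codes), times = n_rows * n_cols),
    n_px = counts
  )
  tiles <- tiles[tiles$n_px > 0, ]
  structure(tiles,
            tile_size = tile_size, n_rows = n_rows, n_cols = n_cols,
            slide_id = attr(mask, "slide_id"), codes = codes,
            class = c("gm_tiles", class(tiles)))
}

#' Label tiles and apply the unannotated-area exclusion rule
#'
#' A tile is excluded exactly when its unannotated fraction strictly exceeds
#' `max_unannotated_frac` (default 0.10, the more-than-10% rule). Retained
#' tiles are labelled by their majority annotated class; ties are broken by
#' ontology order (first-listed class wins). An optional per-tile veto list
#' models exclusions that required human judgment (annotations inconsistent
#' with the underlying histology).
#'
#' @param tiles A `gm_tiles` tibble from [tile_slide()].
#' @param max_unannotated_frac Exclusion threshold in `[0, 1]`.
#' @param ontology Ontology giving the tie-break order.
#' @param purity Optional minimum majority-class fraction (of annotated
#'   pixels) for a label to be assigned; below it the tile label is `NA`.
#' @param veto Optional tibble with columns `row`, `col`: tiles to exclude
#'   regardless of their unannotated fraction.
#' @return A tibble with one row per tile: `row`, `col`, `n_px`,
#'   `unannotated_px`, `unannotated_frac`, `label`, `excluded`. Lattice
#'   attributes are carried over.
#' @export
apply_exclusion <- function(tiles, max_unannotated_frac = 0.10,
                            ontology = gastric_ontology(), purity = NULL,
                            veto = NULL) {
  if (max_unannotated_frac < 0 || max_unannotated_frac > 1) {
    stop("max_unannotated_frac must lie in [0, 1]")
  }
  ord <- stats::setNames(seq_along(ontology$code), ontology$code)
  majority_label <- function(cc, np) {
    ann <- cc != UNANNOTATED
    if (!any(ann)) return(NA_character_)
    cc <- cc[ann]; np <- np[ann]
    lab <- cc[np == max(np)]
    lab <- lab[which.min(ord[lab])]
    if (!is.null(purity) && max(np) / sum(np) < purity) NA_character_ else lab
  }
  per_tile <- tiles |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(
      tile_px = sum(.data$n_px),
      unannotated_px = sum(.data$n_px[.data$class_code == UNANNOTATED]),
      label = majority_label(.data$class_code, .data$n_px),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_px = .data$tile_px,
      unannotated_frac = .data$unannotated_px / .data$n_px,
      excluded = .data$unannotated_frac > max_unannotated_frac
    )
  if (!is.null(veto) && nrow(veto) > 0) {
    key <- paste(per_tile$row, per_tile$col)
    per_tile$excluded <- per_tile$excluded | key %in% paste(veto$row, veto$col)
  }
  per_tile <- dplyr::select(per_tile, "row", "col", "n_px", "unannotated_px",
                            "unannotated_frac", "label", "excluded")
  for (a in c("tile_size", "n_rows", "n_cols", "slide_id", "codes")) {
    attr(per_tile, a) <- attr(tiles, a)
  }
  per_tile
}

#' Compose per-slide class pixel counts
#'
#' Sums per-class pixel counts into a slide composition, either over the
#' retained tiles of a tile lattice or from a pre-tabulated per-class count
#' table (e.g. read from CSV). The composition always carries an
#' `"unannotated"` row (possibly zero).
#'
#' @param x A `gm_tiles` tibble (long counts), or a data frame with columns
#'   `class_code` and `pixel_count` (optionally `slide_id`).
#' @param exclusion Optional per-tile tibble from [apply_exclusion()]; when
#'   supplied, only tiles with `excluded == FALSE` contribute.
#' @param slide_id Slide identifier for the output; defaults to the lattice
#'   attribute or the table's `slide_id` column.
#' @return A tibble of class `gm_composition`: `slide_id`, `class_code`,
#'   `pixel_count`, one row per observed class plus the unannotated row.
#' @export
compose <- function(x, exclusion = NULL, slide_id = NULL) {
  if (inherits(x, "gm_tiles")) {
    tiles <- x
    if (!is.null(exclusion)) {
      keep <- exclusion[!exclusion$excluded, c("row", "col")]
      tiles <- dplyr::semi_join(tiles, keep, by = c("row", "col"))
    }
    comp <- tiles |>
      dplyr::group_by(class_code = .data$class_code) |>
      dplyr::summarise(pixel_count = sum(.data$n_px), .groups = "drop")
    sid <- slide_id %||% attr(x, "slide_id") %||% "slide"
  } else {
    comp <- tibble::as_tibble(x)
    if (!all(c("class_code", "pixel_count") %in% names(comp))) {
      stop("count table needs columns class_code and pixel_count")
    }
    if (any(is.na(comp$pixel_count)) || any(comp$pixel_count < 0)) {
      stop("pixel counts must be non-negative")
    }
    sid <- slide_id %||% (if ("slide_id" %in% names(comp)) comp$slide_id[1] else "slide")
    comp <- comp |>
      dplyr::group_by(class_code = .data$class_code) |>
      dplyr::summarise(pixel_count = sum(.data$pixel_count), .groups = "drop")
  }
  if (!UNANNOTATED %in% comp$class_code) {
    comp <- dplyr::bind_rows(
      comp, tibble::tibble(class_code = UNANNOTATED, pixel_count = 0)
    )
  }
  comp <- dplyr::mutate(comp, slide_id = sid, .before = 1)
  class(comp) <- c("gm_composition", class(comp))
  comp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotated pixel total of a composition
annotated_px <- function(comp) {
  sum(comp$pixel_count[comp$class_code != UNANNOTATED])
}

#' Per-class fractions of the annotated area
#'
#' @param comp A `gm_composition` tibble (single slide or several; fractions
#'   are computed within each `slide_id`).
#' @return The composition with a `fraction` column: class pixels over all
#'   annotated pixels of the slide. The unannotated row gets fraction `NA`.
#' @export
composition_fractions <- function(comp) {
  comp |>
    dplyr::group_by(.data$slide_id) |>
    dplyr::mutate(
      fraction = dplyr::if_else(
        .data$class_code == UNANNOTATED, NA_real_,
        .data$pixel_count / sum(.data$pixel_count[.data$class_code != UNANNOTATED])
      )
    ) |>
    dplyr::ungroup()
}

#' Tumor-fraction adequacy for molecular testing
#'
#' Molecular assays need the tumor-to-nontumor ratio to exceed a minimum;
#' the conventional requirement is a tumor fraction above 20% of the
#' annotated tissue. Adequacy uses a strict inequality: a fraction exactly
#' at the threshold is inadequate.
#'
#' @param comp A `gm_composition` tibble (one or more slides).
#' @param min_tumor_frac Threshold fraction, default 0.20.
#' @param ontology Ontology defining the invasive-carcinoma class group.
#' @return A tibble with `slide_id`, `tumor_fraction`, `adequate`.
#' @export
molecular_adequacy <- function(comp, min_tumor_frac = 0.20,
                               ontology = gastric_ontology()) {
  inv <- codes_in_group(ontology, "invasive_carcinoma")
  out <- comp |>
    dplyr::group_by(.data$slide_id) |>
    dplyr::summarise(
      annotated = sum(.data$pixel_count[.data$class_code != UNANNOTATED]),
      tumor = sum(.data$pixel_count[.data$class_code %in% inv]),
      .groups = "drop"
    )
  if (any(out$annotated == 0)) {
    stop("composition with zero annotated pixels: ",
         paste(out$slide_id[out$annotated == 0], collapse = ", "))
  }
  out |>
    dplyr::mutate(tumor_fraction = .data$tumor / .data$annotated,
                  adequate = .data$tumor_fraction > min_tumor_frac) |>
    dplyr::select("slide_id", "tumor_fraction", "adequate")
}

#' Read / write composition CSV files
#'
#' The composition CSV has one row per class per slide with columns
#' `slide_id`, `class_code`, `pixel_count` (bit-exact integer counts,
#' including an `"unannotated"` row).
#'
#' @param path CSV path.
#' @return `read_composition_csv()`: a `gm_composition` tibble (possibly
#'   several slides); `write_composition_csv()`: `path`, invisibly.
#' @export
read_composition_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    slide_id = readr::col_character(),
    class_code = readr::col_character(),
    pixel_count = readr::col_double()
  ))
  out <- df |>
    dplyr::group_by(.data$slide_id) |>
    dplyr::group_modify(~ compose(.x, slide_id = .y$slide_id)[-1]) |>
    dplyr::ungroup()
  class(out) <- c("gm_composition", class(out))
  out
}

#' @rdname read_composition_csv
#' @param comp A `gm_composition` tibble.
#' @export
write_composition_csv <- function(comp, path) {
  readr::write_csv(
    dplyr::select(comp, "slide_id", "class_code", "pixel_count"), path
  )
  invisible(path)
}

# round half up to `digits` decimals (reporting convention for percents)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
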