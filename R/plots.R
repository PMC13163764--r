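# ggplot2 views of the result types.

gm_group_palette <- c(
  invasive_carcinoma = "#c0392b", hg_dysplasia = "#2e6fb7",
  lg_dysplasia = "#7fb3e0", ulceration_marker = "#16417c",
  non_neoplastic = "#2e8b57", unannotated = "grey80"
)

#' Bar chart of a slide composition
#'
#' Annotated-area fractions per class, colored by ontology group (carcinoma
#' red, dysplasia/ulceration blue, non-neoplastic green).
#'
#' @param comp A `gm_composition` tibble.
#' @param ontology Class ontology.
#' @return A ggplot object.
#' @export
plot_composition <- function(comp, ontology = gastric_ontology()) {
  df <- composition_fractions(comp)
  df <- df[df$class_code != UNANNOTATED & df$pixel_count > 0, ]
  df$group <- ontology$group[match(df$class_code, ontology$code)]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$class_code, -.data$fraction),
    y = .data$fraction, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = gm_group_palette) +
    ggplot2::facet_wrap(ggplot2::vars(.data$slide_id), scales = "free_x") +
    ggplot2::labs(x = "class", y = "fraction of annotated area",
                  fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tile-lattice map
#'
#' Draws a tile lattice colored by first-level group, marking tiles removed
#' by the outlier filter.
#'
#' @param lattice A tibble with `row`, `col`, `label` and optionally
#'   `level1`, `ignored`.
#' @param ontology Class ontology.
#' @return A ggplot object.
#' @export
plot_tile_lattice <- function(lattice, ontology = gastric_ontology()) {
  lattice <- tibble::as_tibble(lattice)
  if (!"level1" %in% names(lattice)) {
    lattice$level1 <- level1_triage(lattice$label, ontology)
  }
  p <- ggplot2::ggplot(lattice, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data$level1)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(
      cancer = "#c0392b", other_pathology = "#2e6fb7", normal = "#2e8b57"),
      na.value = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if ("ignored" %in% names(lattice) && any(lattice$ignored)) {
    p <- p + ggplot2::geom_point(
      data = lattice[lattice$ignored, ],
      ggplot2::aes(x = .data$col, y = .data$row),
      shape = 4, size = 2, inherit.aes = FALSE)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier curve plot
#'
#' @param object A `gm_km` object.
#' @param ... Unused.
#' @return A ggplot object with one step curve per group.
#' @export
autoplot.gm_km <- function(object, ...) {
  td <- tidy(object)
  start <- td |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(start, td[, c("group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Threshold-sweep plot
#'
#' Log-rank p-value against the high-grade-fraction threshold, with the
#' minimal-p threshold highlighted.
#'
#' @param object A `gm_sweep` tibble from [hg_threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gm_sweep <- function(object, ...) {
  df <- object[object$evaluable, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$p)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(data = df[df$is_best, ], color = "#c0392b", size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "high-grade component threshold (%)",
                  y = "log-rank p-value") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
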