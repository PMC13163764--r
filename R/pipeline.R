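# Stage runners: reproducible wrappers that read the on-disk formats, run
# one pipeline stage, write CSV outputs plus a manifest JSON capturing the
# full configuration, seed and package version.

write_manifest <- function(out_dir, stage, config) {
  manifest <- list(
    stage = stage,
    package = as.character(utils::packageVersion("gastromorph")),
    config = config,
    config_hash = rlang::hash(config)
  )
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Quantify a slide annotation into tile and composition tables
#'
#' Reads an ASAP-style annotation XML (with its dimension sidecar),
#' rasterizes it, tiles the mask, applies the unannotated-area exclusion
#' rule and writes the per-tile table, the slide composition CSV and a run
#' manifest. Deterministic: rerunning with the same inputs reproduces the
#' outputs byte for byte.
#'
#' @param annotation_xml Path to the annotation XML; the sidecar is
#'   expected at `<path without .xml>.json`.
#' @param out_dir Output directory (created if missing).
#' @param tile_size Slice edge length, default 256.
#' @param max_unannotated_frac Tile exclusion threshold, default 0.10.
#' @param ontology Class ontology.
#' @return Invisibly, a list with the `composition` and `tiles` tibbles and
#'   the output paths.
#' @export
run_quantify <- function(annotation_xml, out_dir, tile_size = 256,
                         max_unannotated_frac = 0.10,
                         ontology = gastric_ontology()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_annotation_xml(annotation_xml, ontology = ontology)
  mask <- rasterize_annotation(ann, ontology)
  tiles <- tile_slide(mask, tile_size)
  per_tile <- apply_exclusion(tiles, max_unannotated_frac, ontology)
  comp <- compose(tiles, exclusion = per_tile)
  comp_path <- file.path(out_dir, paste0(ann$slide_id, "_composition.csv"))
  tile_path <- file.path(out_dir, paste0(ann$slide_id, "_tiles.csv"))
  write_composition_csv(comp, comp_path)
  readr::write_csv(per_tile, tile_path)
  write_manifest(out_dir, "quantify", list(
    annotation_xml = annotation_xml, tile_size = tile_size,
    max_unannotated_frac = max_unannotated_frac,
    ontology_version = attr(ontology, "version")
  ))
  invisible(list(composition = comp, tiles = per_tile,
                 paths = c(composition = comp_path, tiles = tile_path)))
}

#' Classify slide compositions into callsets
#'
#' Reads a composition CSV (one or many slides), runs the full rule engine
#' and writes the callset CSV (one row per slide, exactly one ICD-10 code
#' each) plus a manifest.
#'
#' @param composition_csv Path to a composition CSV
#'   (see [write_composition_csv()]).
#' @param out_dir Output directory.
#' @param ... Passed to [classify_slides()] (thresholds, modes).
#' @param ontology Class ontology.
#' @return Invisibly, the callset tibble and its path.
#' @export
run_classify <- function(composition_csv, out_dir, ...,
                         ontology = gastric_ontology()) {
  if (!file.exists(composition_csv)) {
    stop("composition file not found: ", composition_csv)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comp <- read_composition_csv(composition_csv)
  calls <- classify_slides(comp, ..., ontology = ontology)
  path <- file.path(out_dir, "callset.csv")
  readr::write_csv(calls, path)
  write_manifest(out_dir, "classify", list(
    composition_csv = composition_csv,
    ontology_version = attr(ontology, "version"),
    options = list(...)
  ))
  invisible(list(callset = calls, path = path))
}

#' Score a cohort and run the survival analyses
#'
#' Reads a cohort CSV (columns `patient_id`, `age`, `hg_fraction`,
#' `ulceration_present`, `metaplasia_present`, `dysplasia_present`,
#' `time`, `event`), computes the prognostic score and tiers, fits
#' Kaplan-Meier curves by two-tier risk group, runs the tier log-rank test
#' and the 99-point high-grade threshold sweep, and writes all tables plus
#' a manifest.
#'
#' @param cohort_csv Path to the cohort CSV.
#' @param out_dir Output directory.
#' @param hg_threshold High-grade criterion cut-point, default 0.70.
#' @return Invisibly, a list with `scores`, `km`, `logrank`, `sweep` and
#'   the output paths.
#' @export
run_survival <- function(cohort_csv, out_dir, hg_threshold = 0.70) {
  if (!file.exists(cohort_csv)) stop("cohort file not found: ", cohort_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- readr::read_csv(cohort_csv, show_col_types = FALSE)
  if (nrow(cohort) == 0) stop("empty cohort")
  scores <- compute_score(cohort, hg_cut = hg_threshold)
  km <- km_fit(scores, group = "tier2")
  lr <- logrank_test(scores, group = "tier2")
  sweep <- hg_threshold_sweep(scores)
  score_path <- file.path(out_dir, "scores.csv")
  km_path <- file.path(out_dir, "km_curves.csv")
  sweep_path <- file.path(out_dir, "threshold_sweep.csv")
  lr_path <- file.path(out_dir, "logrank.csv")
  readr::write_csv(scores, score_path)
  readr::write_csv(tidy(km), km_path)
  readr::write_csv(glance(lr), lr_path)
  readr::write_csv(sweep, sweep_path)
  write_manifest(out_dir, "survival", list(
    cohort_csv = cohort_csv, hg_threshold = hg_threshold
  ))
  invisible(list(scores = scores, km = km, logrank = lr, sweep = sweep,
                 paths = c(scores = score_path, km = km_path,
                           logrank = lr_path, sweep = sweep_path)))
}

#' Bundled reference annotation pixel totals
#'
#' Aggregate pixel-count tables for a 970-slide gastric biopsy annotation
#' cohort: per-group totals (non-neoplastic, invasive carcinoma, high- and
#' low-grade dysplasia, plus the unannotated remainder of the scanned
#' area) and the per-subtype totals of the invasive-carcinoma area. These
#' tables ship with the package as worked-example inputs for the
#' composition arithmetic.
#'
#' @param which `"groups"` or `"tumor_subtypes"`.
#' @return A tibble; `groups` has columns `group`, `pixel_count`;
#'   `tumor_subtypes` has `who_code`, `pixel_count`.
#' @export
reference_pixel_totals <- function(which = c("groups", "tumor_subtypes")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("reference_cohort_", which, ".csv"),
                   package = "gastromorph")
  readr::read_csv(f, show_col_types = FALSE)
}
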