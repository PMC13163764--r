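# Rule-based diagnosis from slide compositions: ICD-10 assignment, grading,
# WHO histotype (including the Carneiro 90% poorly-cohesive rule), Lauren
# type, and the Table-1-style presence features.

# split a composition into named per-slide count vectors (annotated classes)
comp_counts <- function(comp) {
  comp <- comp[comp$class_code != UNANNOTATED, ]
  split(stats::setNames(comp$pixel_count, comp$class_code), comp$slide_id)
}

check_annotated <- function(counts, slide_id) {
  if (length(counts) == 0 || sum(counts) == 0) {
    stop("composition has no annotated pixels (slide ", slide_id, ")")
  }
}

#' Assign an ICD-10 code from a slide composition
#'
#' Applies the diagnostic precedence: any invasive-carcinoma class with
#' fraction strictly above `min_invasive_frac` gives C16.9 (malignant
#' neoplasm of stomach); otherwise any high-grade dysplasia (GINH) gives
#' D00.2 (carcinoma in situ); otherwise any low-grade dysplasia (GINL)
#' gives D13.1 (benign neoplasm); otherwise K29.7 (gastritis, unspecified).
#' With the default `min_invasive_frac = 0`, a single tumor pixel forces
#' C16.9, mirroring the diagnostic rule that even one tumor-bearing slice
#' determines the final code.
#'
#' @param comp A `gm_composition` tibble (one or more slides).
#' @param min_invasive_frac Invasive fraction (of annotated area) that must
#'   be strictly exceeded to call C16.9; default 0.
#' @param ontology Ontology defining the class groups.
#' @return A tibble `slide_id`, `icd10`.
#' @export
assign_icd10 <- function(comp, min_invasive_frac = 0,
                         ontology = gastric_ontology()) {
  inv <- codes_in_group(ontology, "invasive_carcinoma")
  by_slide <- comp_counts(comp)
  icd <- purrr::imap_chr(by_slide, function(counts, sid) {
    check_annotated(counts, sid)
    total <- sum(counts)
    inv_frac <- sum(counts[names(counts) %in% inv]) / total
    if (inv_frac > min_invasive_frac) return("C16.9")
    if (sum(counts[names(counts) == "GINH"]) > 0) return("D00.2")
    if (sum(counts[names(counts) == "GINL"]) > 0) return("D13.1")
    "K29.7"
  })
  tibble::tibble(slide_id = names(by_slide), icd10 = unname(icd))
}

#' Tumor grade from the high-grade component fraction
#'
#' Computes the high-grade fraction of the invasive tumor area
#' (high-grade-class pixels over all invasive pixels, with the high-grade
#' class set taken from the ontology's `grade_class` column) and calls the
#' grade. In `"who"` mode any high-grade component at all makes the tumor
#' high grade (a predominantly low-grade tumor with even a focal high-grade
#' component is graded high); in `"prognostic"` mode the tumor is high grade
#' only when the fraction strictly exceeds `threshold` (default 0.70, the
#' prognostically validated cut-point).
#'
#' @param comp A `gm_composition` tibble; every slide must contain invasive
#'   carcinoma pixels.
#' @param mode `"who"` or `"prognostic"`.
#' @param threshold High-grade fraction cut-point for prognostic mode.
#' @param ontology Ontology defining class groups and grade classes.
#' @return A tibble `slide_id`, `hg_fraction`, `grade`.
#' @export
grade_call <- function(comp, mode = c("who", "prognostic"), threshold = 0.70,
                       ontology = gastric_ontology()) {
  mode <- match.arg(mode)
  inv <- codes_in_group(ontology, "invasive_carcinoma")
  hg <- high_grade_codes(ontology)
  by_slide <- comp_counts(comp)
  out <- purrr::imap_dfr(by_slide, function(counts, sid) {
    inv_px <- sum(counts[names(counts) %in% inv])
    if (inv_px == 0) stop("no invasive carcinoma pixels (slide ", sid, ")")
    hgf <- sum(counts[names(counts) %in% hg]) / inv_px
    grade <- if (mode == "who") {
      if (hgf > 0) "high" else "low"
    } else {
      if (hgf > threshold) "high" else "low"
    }
    tibble::tibble(slide_id = sid, hg_fraction = hgf, grade = grade)
  })
  out
}

#' Subclassify poorly cohesive carcinoma (Carneiro consensus)
#'
#' Within the poorly-cohesive family (signet-ring cell class `PCC` plus
#' non-signet-ring class `PCC-NOS`): a share of at least 90% signet-ring
#' cells gives `PCC-SRC`; at least 90% non-signet-ring poorly cohesive
#' cells gives `PCC-NOS`; any other mixture is `PCC-combined`. The 90%
#' boundary belongs to the pure subtype (`>=`).
#'
#' @param comp A `gm_composition` tibble; every slide must have positive
#'   poorly-cohesive-family pixels.
#' @param src_min Purity threshold, default 0.90.
#' @return A tibble `slide_id`, `src_fraction`, `pcc_subtype`.
#' @export
pcc_subclassify <- function(comp, src_min = 0.90) {
  by_slide <- comp_counts(comp)
  purrr::imap_dfr(by_slide, function(counts, sid) {
    src <- sum(counts[names(counts) == "PCC"])
    nos <- sum(counts[names(counts) == "PCC-NOS"])
    fam <- src + nos
    if (fam == 0) stop("no poorly-cohesive-family pixels (slide ", sid, ")")
    f <- src / fam
    sub <- if (f >= src_min) "PCC-SRC"
           else if (1 - f >= src_min) "PCC-NOS"
           else "PCC-combined"
    tibble::tibble(slide_id = sid, src_fraction = f, pcc_subtype = sub)
  })
}

# fold invasive counts into WHO family bins; returns named vector of pixels
who_family_counts <- function(counts, ontology) {
  inv <- ontology[ontology$group == "invasive_carcinoma", ]
  counts <- counts[names(counts) %in% inv$code]
  fam <- inv$who_family[match(names(counts), inv$code)]
  tapply(counts, fam, sum)
}

# code for a single winning family, applying grade suffixes and the
# poorly-cohesive refinement
family_code <- function(family, counts, ontology, src_min = 0.90) {
  inv <- ontology[ontology$group == "invasive_carcinoma", ]
  if (family %in% c("TAC", "PAC")) {
    members <- inv[inv$who_family == family, ]
    hg_px <- sum(counts[names(counts) %in% members$code[members$grade_class == "high"]])
    lg_px <- sum(counts[names(counts) %in% members$code[members$grade_class == "low"]])
    return(paste0(family, if (hg_px > lg_px) "-HG" else "-LG"))
  }
  if (family == "PCC") {
    src <- sum(counts[names(counts) == "PCC"])
    nos <- sum(counts[names(counts) == "PCC-NOS"])
    f <- src / (src + nos)
    return(if (f >= src_min) "PCC-SRC"
           else if (1 - f >= src_min) "PCC-NOS"
           else "PCC-combined")
  }
  family
}

#' WHO histotype from a slide composition
#'
#' Folds the invasive-carcinoma class counts into WHO family bins (tubular
#' TAC, papillary PAC, poorly cohesive PCC, mucinous MAC, micropapillary
#' MPAC, and the single-code families ACLS, HAC, ACFG, SCC, NDC, NEC). In
#' `"who"` mode the slide receives the single family code when every other
#' family stays strictly below `minor_component_min` of the invasive area,
#' and `"Mixed"` otherwise. In `"predominant"` mode the family with the
#' largest share wins outright (mixed tumors are by construction excluded).
#' Tubular and papillary codes carry a grade suffix (`-LG`/`-HG`) from the
#' dominant grade bin within the family; poorly cohesive results are
#' refined by [pcc_subclassify()].
#'
#' @inheritParams assign_icd10
#' @param mode `"who"` or `"predominant"`.
#' @param minor_component_min Fraction below which a minority family is
#'   ignored in `"who"` mode; default 0.10.
#' @return A tibble `slide_id`, `who_histotype`, `dominant_family`,
#'   `dominant_fraction`.
#' @export
who_histotype <- function(comp, mode = c("who", "predominant"),
                          minor_component_min = 0.10,
                          ontology = gastric_ontology()) {
  mode <- match.arg(mode)
  by_slide <- comp_counts(comp)
  purrr::imap_dfr(by_slide, function(counts, sid) {
    fam <- who_family_counts(counts, ontology)
    if (length(fam) == 0 || sum(fam) == 0) {
      stop("no invasive carcinoma pixels (slide ", sid, ")")
    }
    frac <- fam / sum(fam)
    top <- names(frac)[which.max(frac)]
    code <- if (mode == "predominant") {
      family_code(top, counts, ontology)
    } else {
      if (all(frac[names(frac) != top] < minor_component_min)) {
        family_code(top, counts, ontology)
      } else "Mixed"
    }
    tibble::tibble(slide_id = sid, who_histotype = code,
                   dominant_family = top, dominant_fraction = unname(frac[top]))
  })
}

#' Lauren type from a slide composition
#'
#' Maps the invasive-carcinoma area onto the Lauren families defined in the
#' ontology (default: tubular/papillary/micropapillary intestinal; poorly
#' cohesive diffuse; mucinous and rare types indeterminate). The slide is
#' `intestinal` or `diffuse` when that family reaches the dominance
#' threshold, `mixed` when both intestinal and diffuse reach the minor
#' threshold, and `indeterminate` otherwise.
#'
#' @inheritParams assign_icd10
#' @param dominance Fraction of the invasive area a family needs to claim
#'   the slide outright; default 0.90.
#' @param minor_component_min Fraction both families need for `mixed`;
#'   default 0.10.
#' @return A tibble `slide_id`, `lauren`, `intestinal_fraction`,
#'   `diffuse_fraction`.
#' @export
lauren_map <- function(comp, dominance = 0.90, minor_component_min = 0.10,
                       ontology = gastric_ontology()) {
  inv <- ontology[ontology$group == "invasive_carcinoma", ]
  by_slide <- comp_counts(comp)
  purrr::imap_dfr(by_slide, function(counts, sid) {
    counts <- counts[names(counts) %in% inv$code]
    if (sum(counts) == 0) stop("no carcinoma pixels (slide ", sid, ")")
    fam <- inv$lauren_family[match(names(counts), inv$code)]
    tot <- sum(counts)
    fi <- sum(counts[fam == "intestinal"]) / tot
    fd <- sum(counts[fam == "diffuse"]) / tot
    lauren <- if (fi >= dominance) "intestinal"
              else if (fd >= dominance) "diffuse"
              else if (fi >= minor_component_min && fd >= minor_component_min) "mixed"
              else "indeterminate"
    tibble::tibble(slide_id = sid, lauren = lauren,
                   intestinal_fraction = fi, diffuse_fraction = fd)
  })
}

#' Presence features of the adjacent mucosa
#'
#' Dichotomizes the accessory histology of a slide at a presence threshold
#' (default 1% of the annotated area, strict inequality): dysplasia
#' (GINH + GINL), intestinal metaplasia (IM), ulceration (fibrin F +
#' granulation tissue GT), normal glands (NG) and lymphoid aggregates (LT).
#'
#' @inheritParams assign_icd10
#' @param presence_threshold Fraction of annotated area that must be
#'   strictly exceeded; default 0.01.
#' @return A tibble `slide_id`, `dysplasia_present`, `metaplasia_present`,
#'   `ulceration_present`, `normal_mucosa_present`, `lymphoid_present`.
#' @export
extract_features <- function(comp, presence_threshold = 0.01,
                             ontology = gastric_ontology()) {
  by_slide <- comp_counts(comp)
  purrr::imap_dfr(by_slide, function(counts, sid) {
    check_annotated(counts, sid)
    tot <- sum(counts)
    frac_of <- function(codes) sum(counts[names(counts) %in% codes]) / tot
    tibble::tibble(
      slide_id = sid,
      dysplasia_present = frac_of(c("GINH", "GINL")) > presence_threshold,
      metaplasia_present = frac_of("IM") > presence_threshold,
      ulceration_present = frac_of(c("F", "GT")) > presence_threshold,
      normal_mucosa_present = frac_of("NG") > presence_threshold,
      lymphoid_present = frac_of("LT") > presence_threshold
    )
  })
}

#' Full per-slide callset
#'
#' Runs the whole rule engine on one or more slide compositions and returns
#' one row per slide: ICD-10 code, and — for slides with invasive carcinoma
#' — WHO histotype, Lauren type, grade and high-grade fraction, plus the
#' presence features. Slides without invasive carcinoma get `NA` for the
#' carcinoma-only calls (and `hg_fraction` 0 for the benign codes).
#'
#' @inheritParams assign_icd10
#' @param grade_mode,who_mode,hg_threshold,minor_component_min,presence_threshold
#'   Passed to [grade_call()], [who_histotype()], [extract_features()].
#' @return A tibble of class `gm_callset`, one row per slide.
#' @examples
#' comp <- compose(tibble::tibble(
#'   class_code = c("TACG1", "NG"), pixel_count = c(7000, 3000)
#' ), slide_id = "s1")
#' classify_slides(comp)
#' @export
classify_slides <- function(comp, grade_mode = "prognostic",
                            who_mode = "who", hg_threshold = 0.70,
                            minor_component_min = 0.10,
                            presence_threshold = 0.01,
                            min_invasive_frac = 0,
                            ontology = gastric_ontology()) {
  icd <- assign_icd10(comp, min_invasive_frac, ontology)
  feats <- extract_features(comp, presence_threshold, ontology)
  inv <- codes_in_group(ontology, "invasive_carcinoma")
  has_inv <- comp |>
    dplyr::filter(.data$class_code %in% inv, .data$pixel_count > 0) |>
    dplyr::distinct(.data$slide_id)
  out <- dplyr::left_join(icd, feats, by = "slide_id")
  if (nrow(has_inv) > 0) {
    sub <- comp[comp$slide_id %in% has_inv$slide_id, ]
    calls <- grade_call(sub, mode = grade_mode, threshold = hg_threshold,
                        ontology = ontology) |>
      dplyr::left_join(
        who_histotype(sub, mode = who_mode,
                      minor_component_min = minor_component_min,
                      ontology = ontology),
        by = "slide_id") |>
      dplyr::left_join(lauren_map(sub, ontology = ontology), by = "slide_id")
    out <- dplyr::left_join(out, calls[, c("slide_id", "hg_fraction", "grade",
                                           "who_histotype", "lauren")],
                            by = "slide_id")
  } else {
    out$hg_fraction <- NA_real_
    out$grade <- NA_character_
    out$who_histotype <- NA_character_
    out$lauren <- NA_character_
  }
  out <- out |>
    dplyr::mutate(hg_fraction = dplyr::if_else(
      .data$icd10 %in% c("D13.1", "K29.7") & is.na(.data$hg_fraction),
      0, .data$hg_fraction)) |>
    dplyr::select("slide_id", "icd10", "who_histotype", "lauren", "grade",
                  "hg_fraction", dplyr::ends_with("_present"))
  class(out) <- c("gm_callset", class(out))
  out
}
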