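# Five-criterion prognostic index for gastric carcinoma biopsies and its
# two- and three-tier risk stratifications. One point each for: age over
# 65 years; high-grade component exceeding 70% of the tumor area; tumor
# ulceration (>1% fibrin or granulation tissue); absence of intestinal
# metaplasia in the adjacent mucosa; absence of dysplasia in the adjacent
# mucosa. Three-tier: low 0-2, intermediate 3, high 4-5. Two-tier: low
# 0-3, high 4-5.

#' Compute the five-criterion prognostic score for a patient cohort
#'
#' Takes one row per patient with the raw features and returns the per-
#' criterion points, the 0-5 total and both tier assignments. All five
#' features are required; missing values are an error, never imputed.
#' Boundaries are strict: age exactly 65 and a high-grade fraction exactly
#' at the threshold score no point.
#'
#' @param features A data frame with columns `patient_id`, `age` (years),
#'   `hg_fraction` (high-grade share of tumor area, in `[0, 1]`),
#'   `ulceration_present`, `metaplasia_present`, `dysplasia_present`
#'   (logical, typically from [extract_features()]).
#' @param age_cut Age that must be strictly exceeded; default 65.
#' @param hg_cut High-grade fraction that must be strictly exceeded;
#'   default 0.70.
#' @return A tibble with the input identifiers plus `pt_age`, `pt_hg`,
#'   `pt_ulceration`, `pt_no_metaplasia`, `pt_no_dysplasia`, `score`,
#'   `tier2` (`low`/`high`) and `tier3` (`low`/`intermediate`/`high`).
#' @examples
#' compute_score(tibble::tibble(
#'   patient_id = "p1", age = 70, hg_fraction = 0.8,
#'   ulceration_present = TRUE, metaplasia_present = FALSE,
#'   dysplasia_present = FALSE))
#' @export
compute_score <- function(features, age_cut = 65, hg_cut = 0.70) {
  features <- tibble::as_tibble(features)
  req <- c("patient_id", "age", "hg_fraction", "ulceration_present",
           "metaplasia_present", "dysplasia_present")
  missing_col <- setdiff(req, names(features))
  if (length(missing_col) > 0) {
    stop("missing feature column(s): ", paste(missing_col, collapse = ", "))
  }
  bad <- !stats::complete.cases(features[req])
  if (any(bad)) {
    stop("missing feature value(s) for patient(s): ",
         paste(features$patient_id[bad], collapse = ", "))
  }
  if (any(features$age < 0)) stop("age must be non-negative")
  if (any(features$hg_fraction < 0 | features$hg_fraction > 1)) {
    stop("hg_fraction must lie in [0, 1]")
  }
  out <- features |>
    dplyr::mutate(
      pt_age = as.integer(.data$age > age_cut),
      pt_hg = as.integer(.data$hg_fraction > hg_cut),
      pt_ulceration = as.integer(.data$ulceration_present),
      pt_no_metaplasia = as.integer(!.data$metaplasia_present),
      pt_no_dysplasia = as.integer(!.data$dysplasia_present),
      score = .data$pt_age + .data$pt_hg + .data$pt_ulceration +
        .data$pt_no_metaplasia + .data$pt_no_dysplasia
    )
  tiers <- stratify(out$score)
  out$tier2 <- tiers$tier2
  out$tier3 <- tiers$tier3
  out
}

#' Risk tiers for a prognostic score total
#'
#' Three-tier system: low risk 0-2 points, intermediate risk 3, high risk
#' 4-5. Two-tier system: low risk 0-3, high risk 4-5 (the two-tier low
#' group is the union of the three-tier low and intermediate groups).
#'
#' @param total Integer vector of score totals in `0..5`.
#' @return A tibble `total`, `tier2`, `tier3` (factors ordered from low to
#'   high risk).
#' @export
stratify <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 5) ||
        any(total != floor(total))) {
    stop("score totals must be integers in 0..5")
  }
  tibble::tibble(
    total = as.integer(total),
    tier2 = factor(ifelse(total <= 3, "low", "high"),
                   levels = c("low", "high")),
    tier3 = factor(dplyr::case_when(total <= 2 ~ "low",
                                    total == 3 ~ "intermediate",
                                    TRUE ~ "high"),
                   levels = c("low", "intermediate", "high"))
  )
}
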