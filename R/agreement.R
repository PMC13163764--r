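# Agreement statistics between raters (pathologist, expert panel,
# automated caller): diagnostic code consolidation, confusion matrices,
# sensitivity/specificity, Cohen's kappa, Yates-corrected chi-square.

icd10_codes <- c("C16.9", "D00.2", "D13.1", "K29.7")

#' Consolidate ICD-10 codes into binary diagnostic groups
#'
#' Two consolidation schemes: `c16_vs_rest` treats only invasive carcinoma
#' (C16.9) as positive; `malignant_vs_benign` pools invasive and in situ
#' carcinoma (C16.9 + D00.2) against the benign mucosal-change group
#' (D13.1 + K29.7).
#'
#' @param labels Character vector of the four ICD-10 codes.
#' @param scheme `"c16_vs_rest"` or `"malignant_vs_benign"`.
#' @return A factor with levels `positive`, `negative`.
#' @export
consolidate_codes <- function(labels,
                              scheme = c("c16_vs_rest",
                                         "malignant_vs_benign")) {
  scheme <- match.arg(scheme)
  unknown <- setdiff(unique(labels), icd10_codes)
  if (length(unknown) > 0) {
    stop("unknown ICD-10 code(s): ", paste(unknown, collapse = ", "))
  }
  pos <- if (scheme == "c16_vs_rest") "C16.9" else c("C16.9", "D00.2")
  factor(ifelse(labels %in% pos, "positive", "negative"),
         levels = c("positive", "negative"))
}

#' Confusion matrix between reference and comparison labels
#'
#' Rows are the reference standard (by convention the expert-panel label),
#' columns the comparison rater.
#'
#' @param reference,comparison Label vectors of equal length.
#' @param levels Optional common level order; default the union of values.
#' @return An integer matrix with named dimnames `reference`, `comparison`.
#' @export
confusion_matrix <- function(reference, comparison, levels = NULL) {
  if (length(reference) != length(comparison)) {
    stop("reference and comparison must have equal length")
  }
  lv <- levels %||% union(unique(as.character(reference)),
                          unique(as.character(comparison)))
  tab <- table(reference = factor(reference, lv),
               comparison = factor(comparison, lv))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(reference = lv, comparison = lv))
  m
}

#' Sensitivity and specificity of a 2x2 confusion matrix
#'
#' The first level is the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), both in percent rounded half-up to one
#' decimal (the reporting convention used throughout the package).
#'
#' @param cm A 2x2 matrix, rows = reference, columns = comparison, with the
#'   positive class first.
#' @return A tibble `sensitivity`, `specificity` (percent).
#' @export
sens_spec <- function(cm) {
  if (!all(dim(cm) == c(2, 2))) stop("need a 2x2 confusion matrix")
  if (any(rowSums(cm) == 0)) stop("empty reference class")
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  tibble::tibble(
    sensitivity = round_half_up(100 * tp / (tp + fn), 1),
    specificity = round_half_up(100 * tn / (tn + fp), 1)
  )
}

#' Cohen's kappa with a large-sample test of zero agreement
#'
#' Chance-corrected agreement kappa = (po - pe) / (1 - pe), where po is
#' the observed agreement and pe the expected agreement from the row and
#' column marginals. The p-value tests H0: kappa = 0 with the large-sample
#' normal approximation (null standard error from the marginals). The
#' degenerate case po = pe = 1 (all mass in one diagonal cell) is defined
#' as kappa = 1.
#'
#' @param cm A square confusion matrix of counts.
#' @return A tibble `kappa`, `std_error` (null SE), `statistic` (z),
#'   `p_value`, `n`.
#' @export
cohens_kappa <- function(cm) {
  if (nrow(cm) != ncol(cm)) stop("kappa needs a square matrix")
  n <- sum(cm)
  if (n < 1) stop("empty matrix")
  p <- cm / n
  po <- sum(diag(p))
  pr <- rowSums(p); pc <- colSums(p)
  pe <- sum(pr * pc)
  if (pe == 1) {
    kappa <- if (po == 1) 1 else 0
    return(tibble::tibble(kappa = kappa, std_error = NA_real_,
                          statistic = NA_real_, p_value = NA_real_, n = n))
  }
  kappa <- (po - pe) / (1 - pe)
  # null (kappa = 0) standard error, Fleiss-Cohen-Everitt form
  se0 <- sqrt((pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2))
  z <- kappa / se0
  tibble::tibble(kappa = kappa, std_error = se0, statistic = z,
                 p_value = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Continuity-corrected chi-square statistic
#' `n (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped at zero when
#' the correction overshoots (|ad - bc| < n/2); p-value from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param tab A 2x2 matrix of non-negative counts.
#' @return A tibble `statistic`, `df`, `p_value`, `n`.
#' @export
chi_square_yates <- function(tab) {
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  if (n < 1) stop("empty table")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("zero marginal in 2x2 table")
  num <- max(abs(a * d - b * c) - n / 2, 0)
  stat <- n * num^2 / prod(marg)
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE), n = n)
}

#' Agreement report between two raters over ICD-10 codes
#'
#' For each consolidation scheme, consolidates both label vectors, forms
#' the confusion matrix against the reference standard and reports Cohen's
#' kappa with its p-value plus sensitivity and specificity — the shape of a
#' rater-vs-rater agreement table.
#'
#' @param reference,comparison ICD-10 label vectors; `reference` is the
#'   decisive standard (e.g. the expert panel).
#' @param schemes Consolidation schemes to report.
#' @return A tibble with one row per scheme: `scheme`, `kappa`, `p_value`,
#'   `sensitivity`, `specificity`, `n`.
#' @export
agreement_report <- function(reference, comparison,
                             schemes = c("c16_vs_rest",
                                         "malignant_vs_benign")) {
  purrr::map_dfr(schemes, function(sc) {
    ref <- consolidate_codes(reference, sc)
    cmp <- consolidate_codes(comparison, sc)
    cm <- confusion_matrix(ref, cmp, levels = c("positive", "negative"))
    k <- cohens_kappa(cm)
    ss <- sens_spec(cm)
    tibble::tibble(scheme = sc, kappa = k$kappa, p_value = k$p_value,
                   sensitivity = ss$sensitivity,
                   specificity = ss$specificity, n = k$n)
  })
}
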