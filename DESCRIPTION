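Package: gastromorph
Title: Quantitative Annotation Analysis and Prognostic Scoring for Gastric Biopsy Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying polygon annotations on gastric biopsy
    whole-slide images and turning the resulting class-area compositions into
    diagnoses and prognoses. Rasterizes ASAP-style XML polygon annotations to
    label masks, tiles slides into 256x256 slices with an unannotated-area
    exclusion rule, and records exact per-class pixel compositions. A rule
    engine maps compositions to WHO histotype, Lauren type, tumor grade and
    one of four ICD-10 codes (C16.9, D00.2, D13.1, K29.7), including the
    Carneiro 90 percent subclassification of poorly cohesive carcinoma and a
    molecular-adequacy check on tumor fraction. A three-level slice
    aggregation scheme with isolated-tumor-slice outlier filtering emulates
    ensemble classification over tile lattices. A five-criterion prognostic
    index stratifies patients into risk tiers, with Kaplan-Meier, log-rank,
    restricted-mean survival and a high-grade threshold sweep, plus
    agreement statistics (Cohen's kappa, Yates-corrected chi-square,
    sensitivity and specificity under diagnostic code consolidation).
    Synthetic generators for annotated slides, noisy tile lattices and
    survival cohorts make every stage testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    truncnorm,
    utils,
    xml2,
    yaml
Suggests:
    e1071,
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
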