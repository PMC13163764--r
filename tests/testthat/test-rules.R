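test_that("ICD-10 precedence follows the diagnostic rules", {
  expect_equal(assign_icd10(make_comp(c(PCC = 5, NG = 95)))$icd10, "C16.9")
  expect_equal(assign_icd10(make_comp(c(GINH = 10, NG = 90)))$icd10, "D00.2")
  expect_equal(assign_icd10(make_comp(c(GINL = 10, NG = 90)))$icd10, "D13.1")
  expect_equal(assign_icd10(make_comp(c(NG = 100)))$icd10, "K29.7")
  # GINH outranks GINL; invasive outranks both
  expect_equal(assign_icd10(make_comp(c(GINH = 1, GINL = 50, NG = 49)))$icd10,
               "D00.2")
  expect_equal(assign_icd10(make_comp(c(TACG1 = 1, GINH = 50, NG = 49)))$icd10,
               "C16.9")
  # min_invasive_frac gates the carcinoma call
  expect_equal(assign_icd10(make_comp(c(PCC = 5, NG = 95)),
                            min_invasive_frac = 0.10)$icd10, "K29.7")
  expect_error(assign_icd10(make_comp(c(NG = 0))), "no annotated")
})

test_that("ICD-10 assignment is invariant to class-row order", {
  withr::with_seed(9, {
    ont <- gastric_ontology()
    for (i in 1:20) {
      counts <- stats::setNames(rpois(6, 40), sample(ont$code, 6))
      counts <- counts[counts > 0]
      if (length(counts) == 0 || sum(counts) == 0) next
      comp <- make_comp(counts)
      perm <- comp[sample(nrow(comp)), ]
      class(perm) <- class(comp)
      expect_equal(assign_icd10(perm)$icd10, assign_icd10(comp)$icd10)
    }
  })
})

test_that("grade calls distinguish WHO (any high grade) from prognostic (>70%)", {
  c80 <- make_comp(c(TACG3 = 80, TACG1 = 20))
  c05 <- make_comp(c(TACG3 = 5, TACG1 = 95))
  c00 <- make_comp(c(TACG1 = 100))
  expect_equal(grade_call(c80, "prognostic")$grade, "high")
  expect_equal(grade_call(c05, "prognostic")$grade, "low")
  expect_equal(grade_call(c05, "who")$grade, "high")
  expect_equal(grade_call(c00, "who")$grade, "low")
  expect_equal(grade_call(c00, "prognostic")$grade, "low")
  # boundary: exactly 70% is NOT high in prognostic mode (strict >)
  expect_equal(grade_call(make_comp(c(TACG3 = 70, TACG1 = 30)),
                          "prognostic")$grade, "low")
  # non-tumor classes do not enter the denominator
  g <- grade_call(make_comp(c(TACG3 = 10, NG = 1000)), "prognostic")
  expect_equal(g$hg_fraction, 1)
  expect_error(grade_call(make_comp(c(NG = 100))), "invasive")
  # who severity >= prognostic severity for random compositions
  withr::with_seed(14, {
    for (i in 1:20) {
      comp <- make_comp(c(TACG3 = rpois(1, 30), TACG1 = rpois(1, 30),
                          NG = 10) + 1)
      who <- grade_call(comp, "who")$grade
      prog <- grade_call(comp, "prognostic")$grade
      expect_true(who == "high" | prog == "low")
    }
  })
})

test_that("poorly cohesive carcinoma subclassification uses the 90% rule", {
  expect_equal(pcc_subclassify(make_comp(c(PCC = 92, `PCC-NOS` = 8)))$pcc_subtype,
               "PCC-SRC")
  expect_equal(pcc_subclassify(make_comp(c(PCC = 60, `PCC-NOS` = 40)))$pcc_subtype,
               "PCC-combined")
  expect_equal(pcc_subclassify(make_comp(c(`PCC-NOS` = 100)))$pcc_subtype,
               "PCC-NOS")
  # boundary 0.90 goes to the pure subtype
  expect_equal(pcc_subclassify(make_comp(c(PCC = 90, `PCC-NOS` = 10)))$pcc_subtype,
               "PCC-SRC")
  expect_equal(pcc_subclassify(make_comp(c(PCC = 10, `PCC-NOS` = 90)))$pcc_subtype,
               "PCC-NOS")
  expect_error(pcc_subclassify(make_comp(c(NG = 10))), "poorly-cohesive")
  # partition: exactly one subtype for any positive family composition
  withr::with_seed(2, {
    for (i in 1:25) {
      src <- rpois(1, 20); nos <- rpois(1, 20)
      if (src + nos == 0) next
      out <- pcc_subclassify(make_comp(c(PCC = src, `PCC-NOS` = nos) + c(0, 0)))
      expect_true(out$pcc_subtype %in% c("PCC-SRC", "PCC-NOS", "PCC-combined"))
    }
  })
})

test_that("WHO histotype folds families and flags mixed tumors", {
  expect_equal(who_histotype(make_comp(c(TACG1 = 100)), "who")$who_histotype,
               "TAC-LG")
  expect_equal(who_histotype(make_comp(c(TACG1 = 100)), "predominant")$who_histotype,
               "TAC-LG")
  mix <- make_comp(c(TACG1 = 55, PCC = 45))
  expect_equal(who_histotype(mix, "who")$who_histotype, "Mixed")
  expect_equal(who_histotype(mix, "predominant")$who_histotype, "TAC-LG")
  # PCC family pure at 95% SRC share
  pcc <- make_comp(c(PCC = 95, `PCC-NOS` = 5))
  expect_equal(who_histotype(pcc, "who")$who_histotype, "PCC-SRC")
  # grade suffix follows the dominant grade bin
  expect_equal(who_histotype(make_comp(c(TACG3 = 80, TACG1 = 20)),
                             "who")$who_histotype, "TAC-HG")
  # a minority family below 10% does not make the tumor mixed
  expect_equal(who_histotype(make_comp(c(TACG1 = 95, PCC = 5)),
                             "who")$who_histotype, "TAC-LG")
  expect_error(who_histotype(make_comp(c(NG = 5))), "invasive")
  # predominant mode is scale invariant
  comp1 <- make_comp(c(TACG1 = 3, PCC = 2, MAC1 = 1))
  comp2 <- make_comp(c(TACG1 = 300, PCC = 200, MAC1 = 100))
  expect_equal(who_histotype(comp1, "predominant")$who_histotype,
               who_histotype(comp2, "predominant")$who_histotype)
})

test_that("Lauren mapping uses the family table with dominance thresholds", {
  expect_equal(lauren_map(make_comp(c(TACG1 = 100)))$lauren, "intestinal")
  expect_equal(lauren_map(make_comp(c(PCC = 100)))$lauren, "diffuse")
  expect_equal(lauren_map(make_comp(c(TACG1 = 50, PCC = 50)))$lauren, "mixed")
  expect_equal(lauren_map(make_comp(c(MAC1 = 100)))$lauren, "indeterminate")
  expect_error(lauren_map(make_comp(c(NG = 10))), "carcinoma")
})

test_that("presence features dichotomize at a strict 1% threshold", {
  f <- extract_features(make_comp(c(IM = 2, NG = 98)))
  expect_true(f$metaplasia_present)
  # fibrin + granulation tissue sum to 0.9% -> no ulceration flag
  f2 <- extract_features(make_comp(c(F = 5, GT = 4, NG = 991)))
  expect_false(f2$ulceration_present)
  f3 <- extract_features(make_comp(c(F = 6, GT = 5, NG = 989)))
  expect_true(f3$ulceration_present)
  f4 <- extract_features(make_comp(c(TACG1 = 100)))
  expect_false(any(unlist(f4[-1])))
})

test_that("classify_slides produces one coherent callset row per slide", {
  comp <- dplyr::bind_rows(
    make_comp(c(TACG1 = 7000, NG = 3000), "carc"),
    make_comp(c(GINH = 50, NG = 950), "insitu"),
    make_comp(c(NG = 1000), "benign")
  )
  class(comp) <- c("gm_composition", class(tibble::tibble()))
  calls <- classify_slides(comp)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$icd10[calls$slide_id == "carc"], "C16.9")
  expect_equal(calls$icd10[calls$slide_id == "insitu"], "D00.2")
  expect_equal(calls$icd10[calls$slide_id == "benign"], "K29.7")
  expect_true(is.na(calls$who_histotype[calls$slide_id == "benign"]))
  expect_equal(calls$hg_fraction[calls$slide_id == "benign"], 0)
  expect_equal(calls$who_histotype[calls$slide_id == "carc"], "TAC-LG")
})
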