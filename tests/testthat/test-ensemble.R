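make_lattice <- function(labels_mat) {
  tibble::tibble(
    row = rep(seq_len(nrow(labels_mat)), times = ncol(labels_mat)),
    col = rep(seq_len(ncol(labels_mat)), each = nrow(labels_mat)),
    label = as.vector(labels_mat)
  )
}

test_that("first-level triage projects classes onto their groups", {
  expect_equal(level1_triage(c("PCC", "GINL", "NG", "F", "GINH")),
               c("cancer", "other_pathology", "normal", "other_pathology",
                 "other_pathology"))
  expect_error(level1_triage("NOPE"), "NOPE")
})

test_that("isolated tumor tiles are filtered, adjacent pairs retained", {
  m <- matrix("NG", 5, 5)
  m[3, 3] <- "PCC"
  single <- outlier_filter(make_lattice(m))
  expect_true(single$ignored[single$label == "PCC"])
  # the scan code then falls back to the benign call
  expect_equal(aggregate_icd10(single)$icd10, "K29.7")

  m2 <- matrix("NG", 5, 5)
  m2[3, 3] <- "PCC"; m2[4, 4] <- "TACG1"   # 8-adjacent diagonal pair
  pair <- outlier_filter(make_lattice(m2))
  expect_false(any(pair$ignored))
  expect_equal(aggregate_icd10(pair)$icd10, "C16.9")
  # under 4-connectivity the diagonal pair is two singletons
  pair4 <- outlier_filter(make_lattice(m2), connectivity = 4)
  expect_equal(sum(pair4$ignored), 2)

  expect_error(outlier_filter(make_lattice(m), min_component_size = 0), ">= 1")
})

test_that("component removal matches an exhaustive flood-fill oracle", {
  withr::with_seed(31, {
    for (i in 1:6) {
      mat <- matrix(runif(400) < 0.25, 20, 20)
      lm <- matrix(ifelse(mat, "PCC", "NG"), 20, 20)
      for (conn in c(4, 8)) {
        filt <- outlier_filter(make_lattice(lm), min_component_size = 2,
                               connectivity = conn)
        oracle <- oracle_components(mat, conn)
        sizes <- tabulate(oracle)
        n_isolated <- sum(sizes == 1)
        expect_equal(sum(filt$ignored), n_isolated)
        # and the removed tiles are exactly the size-1 component members
        removed <- filt[filt$ignored, c("row", "col")]
        iso_cells <- which(matrix(sizes[pmax(oracle, 1)] == 1 & mat,
                                  20, 20), arr.ind = TRUE)
        expect_setequal(paste(removed$row, removed$col),
                        paste(iso_cells[, 1], iso_cells[, 2]))
      }
    }
  })
})

test_that("package components agree with EBImage labelling on random fields", {
  skip_if_not_installed("EBImage")
  withr::with_seed(8, {
    for (i in 1:5) {
      mat <- matrix(runif(900) < 0.35, 30, 30)
      lm <- matrix(ifelse(mat, "TACG1", "NG"), 30, 30)
      # bwlabel uses 4-connectivity; match it
      filt <- outlier_filter(make_lattice(lm), min_component_size = 3,
                             connectivity = 4)
      eb <- EBImage::bwlabel(mat)
      sizes <- tabulate(eb)
      small_cells <- sum(sizes[eb[mat]] < 3)
      expect_equal(sum(filt$ignored), small_cells)
    }
  })
})

test_that("aggregation equals the rule engine when no filtering occurs", {
  withr::with_seed(12, {
    ont <- gastric_ontology()
    for (i in 1:10) {
      lm <- matrix(sample(c("NG", "PCC", "GINH", "GINL", "IM"), 64,
                          replace = TRUE), 8, 8)
      lat <- make_lattice(lm)
      agg <- aggregate_icd10(outlier_filter(lat, min_component_size = 1))
      comp <- compose(dplyr::count(lat, class_code = label,
                                   name = "pixel_count"))
      expect_equal(agg$icd10, assign_icd10(comp)$icd10)
    }
  })
})

test_that("outlier filtering never adds cancer tiles and is monotone in size", {
  withr::with_seed(77, {
    mat <- matrix(runif(400) < 0.3, 20, 20)
    lat <- make_lattice(matrix(ifelse(mat, "PCC", "NG"), 20, 20))
    f1 <- outlier_filter(lat, min_component_size = 1)
    f2 <- outlier_filter(lat, min_component_size = 2)
    f4 <- outlier_filter(lat, min_component_size = 4)
    retained <- function(f) sum(f$level1 == "cancer" & !f$ignored)
    expect_equal(retained(f1), sum(mat))
    expect_true(retained(f2) <= retained(f1))
    expect_true(retained(f4) <= retained(f2))
  })
})

test_that("false-positive carcinoma calls on benign scans shrink with the filter", {
  # benign scans contaminated with isolated tumor tiles: stronger filtering
  # can only reduce the C16.9 false-positive rate
  rates <- sapply(c(1, 2), function(mcs) {
    calls <- sapply(1:15, function(s) {
      lat <- gen_tile_lattice(c(NG = 0.97, IM = 0.03), 15, 15,
                              contamination_rate = 0.01, seed = 1000 + s)
      filt <- outlier_filter(lat, min_component_size = mcs)
      aggregate_icd10(filt)$icd10
    })
    mean(calls == "C16.9")
  })
  expect_true(rates[2] <= rates[1])
  expect_true(rates[2] < 0.5)  # the filter removes isolated contamination
})

test_that("classifier simulation respects per-class recall and the seed", {
  big <- tibble::tibble(row = 1:1e5, col = 1L, label = "F")
  sim <- simulate_classifier(big, recall = c(F = 0.86), seed = 4)
  acc <- mean(sim$predicted == "F")
  se <- sqrt(0.86 * 0.14 / 1e5)
  expect_lt(abs(acc - 0.86), 3 * se)
  # identity at recall 1, determinism under a fixed seed
  sim1 <- simulate_classifier(big, recall = c(F = 1), seed = 9)
  expect_equal(sim1$predicted, big$label)
  sim_a <- simulate_classifier(big, recall = c(F = 0.5), seed = 11)
  sim_b <- simulate_classifier(big, recall = c(F = 0.5), seed = 11)
  expect_equal(sim_a$predicted, sim_b$predicted)
  expect_error(simulate_classifier(big, recall = c(F = 1.2)), "\\[0, 1\\]")

  # within-group spill keeps errors inside the first-level group
  ng <- tibble::tibble(row = 1:2000, col = 1L, label = "NG")
  simg <- simulate_classifier(ng, recall = c(NG = 0.5),
                              confusion_spill = "within_group", seed = 13)
  expect_true(all(level1_triage(simg$predicted) == "normal"))
  expect_gt(mean(simg$predicted != "NG"), 0.4)
})

test_that("train/validation split honours the 4:1 ratio and the seed", {
  s10 <- dataset_split(paste0("s", 1:10), seed = 3)
  expect_equal(sum(s10$cohort == "train"), 8)
  expect_equal(sum(s10$cohort == "validation"), 2)
  s5 <- dataset_split(paste0("s", 1:5), seed = 3)
  expect_equal(table(s5$cohort)[["train"]], 4)
  expect_equal(dataset_split(paste0("s", 1:10), seed = 3), s10)
  expect_error(dataset_split(character(0)), "no slides")
  # partition is disjoint and exhaustive
  s7 <- dataset_split(paste0("s", 1:7), seed = 1)
  expect_setequal(s7$slide_id, paste0("s", 1:7))
  expect_true(all(s7$cohort %in% c("train", "validation")))
})
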