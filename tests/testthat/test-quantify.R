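test_that("rasterization follows the pixel-center convention", {
  # square with vertices (2,2)-(8,8): centers in [2,8) x [2,8) -> 6x6 pixels
  ann <- slide_annotation("s", 10, 10, rect_poly(1, "NG", 2, 2, 8, 8))
  mask <- rasterize_annotation(ann)
  expect_equal(sum(mask == match("NG", gastric_ontology()$code)), 36)
  expect_equal(sum(mask == 0), 64)

  empty <- slide_annotation("e", 10, 10,
                            tibble::tibble(polygon_id = integer(),
                                           class_code = character(),
                                           x = double(), y = double()))
  expect_true(all(rasterize_annotation(empty) == 0))

  # overlapping polygons: last drawn wins
  both <- slide_annotation("o", 10, 10, dplyr::bind_rows(
    rect_poly(1, "NG", 0, 0, 10, 10), rect_poly(2, "PCC", 0, 0, 10, 10)))
  m2 <- rasterize_annotation(both)
  expect_true(all(m2 == match("PCC", gastric_ontology()$code)))
})

test_that("rasterized counts track the shoelace area within the perimeter bound", {
  withr::with_seed(7, {
    for (i in 1:8) {
      p <- random_star_polygon(14, runif(1, 60, 140), runif(1, 60, 140),
                               20, 55)
      polys <- tibble::tibble(polygon_id = 1, class_code = "PCC",
                              x = p$x, y = p$y)
      ann <- slide_annotation("r", 200, 200, polys)
      mask <- rasterize_annotation(ann)
      count <- sum(mask > 0)
      a <- polygon_area(p$x, p$y)
      per <- sum(sqrt(diff(c(p$x, p$x[1]))^2 + diff(c(p$y, p$y[1]))^2))
      expect_lt(abs(count - a), per + 4)
    }
  })
})

test_that("tiling conserves pixel counts and shapes border tiles correctly", {
  ont <- gastric_ontology()
  # 300x300 with tile 256 -> 2x2 lattice, border tiles 44 px wide
  ann <- slide_annotation("b", 300, 300, rect_poly(1, "NG", 0, 0, 300, 300))
  mask <- rasterize_annotation(ann)
  tiles <- tile_slide(mask, 256)
  expect_equal(attr(tiles, "n_rows"), 2)
  expect_equal(attr(tiles, "n_cols"), 2)
  per_tile <- dplyr::count(tiles, row, col, wt = n_px)
  expect_setequal(per_tile$n, c(256 * 256, 256 * 44, 44 * 256, 44 * 44))

  # 1024x512, tile 256 -> 4 cols x 2 rows
  m <- matrix(0L, 512, 1024); attr(m, "codes") <- ont$code
  t2 <- tile_slide(m, 256)
  expect_equal(attr(t2, "n_rows") * attr(t2, "n_cols"), 8)

  expect_error(tile_slide(mask, 0), "positive")

  # conservation on random masks: per-tile sums equal mask tallies
  withr::with_seed(21, {
    for (i in 1:5) {
      mr <- matrix(sample(0:4, 90 * 70, replace = TRUE), 70, 90)
      attr(mr, "codes") <- ont$code
      tr <- tile_slide(mr, 16)
      recount <- dplyr::count(tr, class_code, wt = n_px)
      direct <- table(factor(c("unannotated", ont$code)[mr + 1L]))
      expect_equal(
        sort(stats::setNames(recount$n, recount$class_code)),
        sort(unclass(c(direct))))
    }
  })
})

test_that("tile exclusion uses a strict 10% rule and majority labels", {
  ont <- gastric_ontology()
  # one 10x10 tile, 15% unannotated -> excluded
  m <- matrix(match("NG", ont$code), 10, 10); m[1, 1:10] <- 0L; m[2, 1:5] <- 0L
  attr(m, "codes") <- ont$code
  ex <- apply_exclusion(tile_slide(m, 10), 0.10)
  expect_true(ex$excluded)

  # exactly 10% unannotated -> retained (strict inequality)
  m2 <- matrix(match("NG", ont$code), 10, 10); m2[1, 1:10] <- 0L
  attr(m2, "codes") <- ont$code
  ex2 <- apply_exclusion(tile_slide(m2, 10), 0.10)
  expect_false(ex2$excluded)
  expect_equal(ex2$label, "NG")

  # tie between two classes broken by ontology order
  k_ng <- match("NG", ont$code); k_pcc <- match("PCC", ont$code)
  m3 <- matrix(c(rep(k_pcc, 50), rep(k_ng, 50)), 10, 10)
  attr(m3, "codes") <- ont$code
  ex3 <- apply_exclusion(tile_slide(m3, 10))
  expect_equal(ex3$label, ont$code[min(k_ng, k_pcc)])

  expect_error(apply_exclusion(tile_slide(m3, 10), 1.5), "\\[0, 1\\]")

  # monotone: raising the threshold never excludes a retained tile
  withr::with_seed(3, {
    mr <- matrix(sample(c(0L, k_ng), 400, replace = TRUE, prob = c(.3, .7)),
                 20, 20)
    attr(mr, "codes") <- ont$code
    tr <- tile_slide(mr, 5)
    e1 <- apply_exclusion(tr, 0.10)
    e2 <- apply_exclusion(tr, 0.30)
    expect_true(all(e2$excluded <= e1$excluded))
  })
})

test_that("composition conserves pixels through rasterize -> tile -> compose", {
  withr::with_seed(5, {
    sl <- gen_slide(c(NG = 0.4, PCC = 0.2, GINH = 0.1), width_px = 256,
                    height_px = 256, seed = 50)
    tiles <- tile_slide(sl$mask, 64)
    comp_all <- compose(tiles)
    # without exclusion the composition equals the generator's ground truth
    gt <- sl$composition
    merged <- dplyr::full_join(comp_all, gt, by = c("slide_id", "class_code"))
    merged[is.na(merged)] <- 0
    expect_equal(merged$pixel_count.x, merged$pixel_count.y)
    # with exclusion: retained + excluded = total, per class
    ex <- apply_exclusion(tiles, 0.10)
    kept <- compose(tiles, exclusion = ex)
    dropped <- compose(tiles, exclusion = dplyr::mutate(ex, excluded = !excluded))
    tot <- dplyr::full_join(kept, dropped, by = c("slide_id", "class_code"))
    tot[is.na(tot)] <- 0
    tot <- dplyr::left_join(tot, comp_all, by = c("slide_id", "class_code"))
    expect_equal(tot$pixel_count.x + tot$pixel_count.y, tot$pixel_count)
  })
})

test_that("compose accepts count tables and rejects negative counts", {
  comp <- compose(tibble::tibble(class_code = c("NG", "PCC"),
                                 pixel_count = c(60, 40)), slide_id = "t")
  fr <- composition_fractions(comp)
  expect_equal(fr$fraction[fr$class_code == "PCC"], 0.4)
  expect_error(compose(tibble::tibble(class_code = "NG", pixel_count = -1)),
               "non-negative")
  f <- withr::local_tempfile(fileext = ".csv")
  write_composition_csv(comp, f)
  expect_equal(sum(read_composition_csv(f)$pixel_count), 100)
})

test_that("molecular adequacy uses a strict 20% tumor-fraction rule", {
  expect_true(molecular_adequacy(make_comp(c(PCC = 29, NG = 71)))$adequate)
  expect_false(molecular_adequacy(make_comp(c(PCC = 20, NG = 80)))$adequate)
  zero <- molecular_adequacy(make_comp(c(NG = 100)))
  expect_equal(zero$tumor_fraction, 0)
  expect_false(zero$adequate)
  expect_error(molecular_adequacy(make_comp(c(NG = 0))), "zero annotated")
})
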