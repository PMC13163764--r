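# Synthetic data generators: annotated slides (random blob polygons over a
# canvas), spatially clustered tile lattices with optional isolated-tile
# contamination, and survival cohorts whose hazard depends on the
# prognostic criteria. All generators are pure functions of their
# arguments plus the seed.

# random convex-ish blob polygon: perturbed ellipse vertices around a center
blob_polygon <- function(cx, cy, r, n_vertices = 12, wobble = 0.25,
                         aspect = stats::runif(1, 0.6, 1.4)) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- r * (1 + stats::runif(n_vertices, -wobble, wobble))
  list(x = cx + rad * cos(ang) * aspect, y = cy + rad * sin(ang) / aspect)
}

#' Generate a synthetic annotated slide
#'
#' Places random convex-ish blob polygons class by class until each class's
#' target area fraction is approximately reached, then reports the exact
#' rasterized ground truth. Because the returned composition is computed
#' from the final mask (last-drawn-wins, same convention as
#' [rasterize_annotation()]), running the generated annotation back through
#' rasterize/tile/compose reproduces the ground-truth counts exactly.
#'
#' @param targets Named numeric vector of target area fractions per class
#'   code; must be non-negative and sum to at most 1 (the remainder stays
#'   unannotated).
#' @param width_px,height_px Canvas size in pixels.
#' @param seed Integer seed.
#' @param slide_id Identifier for the generated slide.
#' @param mean_blob_px Mean blob area in pixels; default scales with the
#'   canvas so a slide holds tens of blobs.
#' @param ontology Class ontology.
#' @return A list with `annotation` (a `gm_annotation`), `composition`
#'   (the exact ground-truth `gm_composition`) and `mask` (the label
#'   matrix).
#' @examples
#' sl <- gen_slide(c(NG = 0.5, PCC = 0.2), width_px = 128, height_px = 128,
#'                 seed = 1)
#' sl$composition
#' @export
gen_slide <- function(targets, width_px = 1024, height_px = 1024, seed = 1,
                      slide_id = "synthetic", mean_blob_px = NULL,
                      ontology = gastric_ontology()) {
  if (any(targets < 0)) stop("target fractions must be non-negative")
  if (sum(targets) > 1 + 1e-9) stop("target fractions sum to more than 1")
  unknown <- setdiff(names(targets), ontology$code)
  if (length(unknown) > 0) {
    stop("target class(es) not in ontology: ", paste(unknown, collapse = ", "))
  }
  total_px <- as.numeric(width_px) * height_px
  mean_blob_px <- mean_blob_px %||% max(400, total_px / 40)
  with_seed(seed, {
    mask <- matrix(0L, nrow = height_px, ncol = width_px)
    class_px <- integer(nrow(ontology))
    polys <- list()
    pid <- 0L
    # several passes so classes whose area was overwritten get topped up
    for (pass in 1:3) {
      for (code in names(targets)) {
        k <- match(code, ontology$code)
        target_px <- round(targets[[code]] * total_px)
        iter <- 0L
        while (class_px[k] < target_px * 0.99 && iter < 300L) {
          iter <- iter + 1L
          remaining <- target_px - class_px[k]
          area <- min(remaining * 1.05,
                      mean_blob_px * stats::runif(1, 0.5, 1.5))
          r <- sqrt(area / pi)
          # reject placements that would mostly overwrite other classes
          placed <- FALSE
          for (try in 1:20) {
            cx <- stats::runif(1, r, max(r + 1e-6, width_px - r))
            cy <- stats::runif(1, r, max(r + 1e-6, height_px - r))
            # cheap pre-screen: occupancy of the bounding box by other classes
            if (try < 20) {
              rr <- max(1, floor(cy - r)):min(height_px, ceiling(cy + r))
              cc <- max(1, floor(cx - r)):min(width_px, ceiling(cx + r))
              box <- mask[rr, cc]
              if (mean(box != 0L & box != k) > 0.12) next
            }
            b <- blob_polygon(cx, cy, r)
            b$x <- pmin(pmax(b$x, 0), width_px)
            b$y <- pmin(pmax(b$y, 0), height_px)
            idx <- polygon_cells(height_px, width_px, b$x, b$y)
            if (length(idx) == 0) next
            overwrite <- mean(mask[idx] != 0L & mask[idx] != k)
            if (overwrite <= 0.15 || try == 20) {
              old <- mask[idx]
              mask[idx] <- k
              tally <- tabulate(old + 1L, nbins = nrow(ontology) + 1L)[-1]
              class_px <- class_px - tally
              class_px[k] <- class_px[k] + length(idx)
              pid <- pid + 1L
              polys[[pid]] <- tibble::tibble(polygon_id = pid,
                                             class_code = code,
                                             x = b$x, y = b$y)
              placed <- TRUE
              break
            }
          }
          if (!placed) break
        }
      }
      deficit <- vapply(names(targets), function(code) {
        k <- match(code, ontology$code)
        round(targets[[code]] * total_px) - class_px[k]
      }, numeric(1))
      if (all(deficit <= 0.01 * total_px)) break
    }
    attr(mask, "codes") <- ontology$code
    attr(mask, "slide_id") <- slide_id
    ann <- slide_annotation(slide_id, width_px, height_px,
                            dplyr::bind_rows(polys), ontology)
    counts <- tabulate(mask + 1L, nbins = length(ontology$code) + 1L)
    comp <- compose(tibble::tibble(
      class_code = c(UNANNOTATED, ontology$code), pixel_count = counts
    ), slide_id = slide_id)
    comp <- comp[comp$pixel_count > 0 | comp$class_code == UNANNOTATED, ]
    class(comp) <- c("gm_composition", setdiff(class(comp), "gm_composition"))
    list(annotation = ann, composition = comp, mask = mask)
  })
}

#' Generate a spatially clustered tile-label lattice
#'
#' Produces a ground-truth tile lattice in which tumor (and other) classes
#' form connected blocks: a background class fills the grid and the other
#' classes are painted as random discs until their target tile fractions
#' are approximately reached. Optionally, isolated-tile contamination flips
#' tiles whose 8-neighbourhood is tumor-free in the base lattice to a tumor
#' class with probability `contamination_rate` — the failure mode the
#' outlier filter exists to remove.
#'
#' @param fractions Named target tile fractions; the largest entry is the
#'   background class. Must sum to 1 (within rounding).
#' @param n_rows,n_cols Lattice dimensions.
#' @param clustering Mean disc radius in tiles; default 3.
#' @param contamination_rate Per-eligible-tile probability of an isolated
#'   tumor flip; default 0.
#' @param contaminant_class Tumor class used for contamination; default
#'   `"PCC"`.
#' @param seed Integer seed.
#' @param ontology Class ontology.
#' @return A tibble `row`, `col`, `label` with attributes `contaminated`
#'   (tibble of flipped tiles) and `n_eligible` (tiles whose base
#'   neighbourhood was tumor-free).
#' @export
gen_tile_lattice <- function(fractions, n_rows = 40, n_cols = 40,
                             clustering = 3, contamination_rate = 0,
                             contaminant_class = "PCC", seed = 1,
                             ontology = gastric_ontology()) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  unknown <- setdiff(names(fractions), ontology$code)
  if (length(unknown) > 0) {
    stop("class(es) not in ontology: ", paste(unknown, collapse = ", "))
  }
  inv <- codes_in_group(ontology, "invasive_carcinoma")
  with_seed(seed, {
    bg <- names(fractions)[which.max(fractions)]
    grid <- matrix(match(bg, ontology$code), n_rows, n_cols)
    for (code in setdiff(names(fractions), bg)) {
      k <- match(code, ontology$code)
      target <- round(fractions[[code]] * n_rows * n_cols)
      iter <- 0L
      while (sum(grid == k) < target && iter < 200L) {
        iter <- iter + 1L
        r <- max(1, stats::rpois(1, clustering))
        cr <- sample.int(n_rows, 1); cc <- sample.int(n_cols, 1)
        rows <- pmax(1, cr - r):pmin(n_rows, cr + r)
        cols <- pmax(1, cc - r):pmin(n_cols, cc + r)
        cells <- expand.grid(row = rows, col = cols)
        d2 <- (cells$row - cr)^2 + (cells$col - cc)^2
        cells <- cells[d2 <= r^2, ]
        need <- target - sum(grid == k)
        if (nrow(cells) > need) cells <- cells[seq_len(need) , , drop = FALSE]
        grid[cbind(cells$row, cells$col)] <- k
      }
    }
    # eligibility: base 8-neighbourhood (incl. self) contains no tumor tile
    tumor <- matrix(ontology$code[grid] %in% inv, n_rows, n_cols)
    pad <- matrix(FALSE, n_rows + 2, n_cols + 2)
    pad[2:(n_rows + 1), 2:(n_cols + 1)] <- tumor
    near_tumor <- matrix(FALSE, n_rows, n_cols)
    for (dr in -1:1) for (dc in -1:1) {
      near_tumor <- near_tumor |
        pad[(2 + dr):(n_rows + 1 + dr), (2 + dc):(n_cols + 1 + dc)]
    }
    eligible <- which(!near_tumor)
    flips <- eligible[stats::runif(length(eligible)) < contamination_rate]
    kc <- match(contaminant_class, ontology$code)
    grid[flips] <- kc
    lattice <- tibble::tibble(
      row = rep(seq_len(n_rows), times = n_cols),
      col = rep(seq_len(n_cols), each = n_rows),
      label = ontology$code[as.vector(grid)]
    )
    attr(lattice, "contaminated") <- tibble::tibble(
      row = ((flips - 1L) %% n_rows) + 1L,
      col = ((flips - 1L) %/% n_rows) + 1L
    )
    attr(lattice, "n_eligible") <- length(eligible)
    lattice
  })
}

#' Default criterion prevalences for the cohort generator
#'
#' Marginal prevalences of the prognostic criteria in a gastric-carcinoma
#' biopsy cohort: ulceration 28.2%, intestinal metaplasia 18.9%, dysplasia
#' 15.7% (age and the high-grade fraction are drawn from their own
#' distributions rather than as Bernoulli flags).
#'
#' @return Named numeric vector.
#' @export
default_prevalences <- function() {
  c(ulceration = 0.282, metaplasia = 0.189, dysplasia = 0.157)
}

#' Generate a synthetic survival cohort
#'
#' Draws per-patient prognostic features (truncated-normal age, uniform
#' high-grade fraction, Bernoulli ulceration/metaplasia/dysplasia), scores
#' them with [compute_score()], then draws exponential death times whose
#' hazard depends on the chosen risk summary, with administrative censoring
#' at `horizon` months.
#'
#' The default calibration emulates a registry-linked gastric-carcinoma
#' biopsy cohort: ages truncated-normal mean 60, sd 13 on `[18, 93]`;
#' two-tier hazards 0.0285/month (low risk) and 0.0764/month (high risk),
#' i.e. one-year survival 71% vs 40% and 28-month restricted means near
#' 19 vs 11 months; follow-up horizon 28 months.
#'
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param hazard_on `"tier2"` (hazard jumps for the high-risk tier),
#'   `"points"` (log-hazard linear in the score total) or
#'   `"hg_changepoint"` (hazard jumps when `hg_fraction` exceeds
#'   `changepoint`, for threshold-sweep studies).
#' @param baseline_hazard Events per month in the reference group.
#' @param log_hr Log hazard ratio (per tier jump, per point, or per
#'   change-point exceedance).
#' @param changepoint High-grade fraction at which the hazard jumps when
#'   `hazard_on = "hg_changepoint"`; default 0.70.
#' @param horizon Administrative censoring horizon in months.
#' @param age_mean,age_sd,age_range Age distribution parameters.
#' @param prevalences Named vector as in [default_prevalences()].
#' @param weibull_shape Optional Weibull shape; 1 (default) keeps the
#'   exponential model, other values scale the exponential draw to a
#'   Weibull with the same rate parameterization.
#' @return A tibble with one row per patient: features, per-criterion
#'   points, `score`, `tier2`, `tier3`, `time` (months), `event`.
#' @examples
#' co <- gen_cohort(n = 50, seed = 7)
#' table(co$tier2)
#' @export
gen_cohort <- function(n = 142, seed = 1,
                       hazard_on = c("tier2", "points", "hg_changepoint"),
                       baseline_hazard = 0.0285,
                       log_hr = log(0.0764 / 0.0285),
                       changepoint = 0.70, horizon = 28,
                       age_mean = 60, age_sd = 13, age_range = c(18, 93),
                       prevalences = default_prevalences(),
                       weibull_shape = 1) {
  hazard_on <- match.arg(hazard_on)
  if (n < 1) stop("n must be at least 1")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (horizon <= 0) stop("horizon must be positive")
  if (age_sd <= 0) stop("age_sd must be positive")
  with_seed(seed, {
    features <- tibble::tibble(
      patient_id = sprintf("p%04d", seq_len(n)),
      age = truncnorm::rtruncnorm(n, a = age_range[1], b = age_range[2],
                                  mean = age_mean, sd = age_sd),
      hg_fraction = stats::runif(n),
      ulceration_present = stats::runif(n) < prevalences[["ulceration"]],
      metaplasia_present = stats::runif(n) < prevalences[["metaplasia"]],
      dysplasia_present = stats::runif(n) < prevalences[["dysplasia"]]
    )
    scored <- compute_score(features)
    risk <- switch(hazard_on,
      tier2 = as.integer(scored$tier2 == "high"),
      points = scored$score,
      hg_changepoint = as.integer(scored$hg_fraction > changepoint)
    )
    rate <- baseline_hazard * exp(log_hr * risk)
    t_death <- stats::rexp(n, rate = rate)
    if (weibull_shape != 1) t_death <- t_death^(1 / weibull_shape)
    scored$time <- pmin(t_death, horizon)
    scored$event <- as.integer(t_death <= horizon)
    scored
  })
}
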