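# Three-level slice aggregation: group triage of tile labels, removal of
# isolated tumor tiles as outliers, and scan-level ICD-10 assignment from
# the surviving tiles. Tile label sources are pluggable: ground truth from
# the quantification module or the noisy classifier simulator below.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' First-level triage of tile labels
#'
#' Projects fine-grained class labels onto the three first-level groups:
#' invasive-carcinoma classes to `cancer`, dysplasia and ulceration-marker
#' classes to `other_pathology`, non-neoplastic classes to `normal`.
#'
#' @param labels Character vector of class codes (`NA` allowed, passed
#'   through).
#' @param ontology Ontology defining the groups.
#' @return Character vector of `cancer` / `other_pathology` / `normal`.
#' @export
level1_triage <- function(labels, ontology = gastric_ontology()) {
  unknown <- setdiff(stats::na.omit(unique(labels)), ontology$code)
  if (length(unknown) > 0) {
    stop("label(s) not in ontology: ", paste(unknown, collapse = ", "))
  }
  grp <- ontology$group[match(labels, ontology$code)]
  dplyr::case_match(
    grp,
    "invasive_carcinoma" ~ "cancer",
    c("hg_dysplasia", "lg_dysplasia", "ulceration_marker") ~ "other_pathology",
    "non_neoplastic" ~ "normal"
  )
}

# connected-component labelling of a logical matrix (4- or 8-connectivity),
# iterative flood fill; returns an integer matrix, 0 for background
label_components <- function(mat, connectivity = 8) {
  nr <- nrow(mat); nc <- ncol(mat)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), times = 3); dc <- rep(c(-1L, 0L, 1L), each = 3)
    keep <- !(dr == 0 & dc == 0); dr <- dr[keep]; dc <- dc[keep]
  }
  nextlab <- 0L
  for (start in which(mat)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    lab[start] <- nextlab
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      nb_r <- r + dr; nb_c <- cl + dc
      ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[mat[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Remove isolated tumor tiles as outliers
#'
#' Isolated, discrete tiles classified as tumor inflate the false-positive
#' rate of the any-tumor-implies-C16.9 rule, so connected components of
#' cancer tiles smaller than `min_component_size` are flagged as ignored
#' before scan-level code assignment. Ignored tiles are removed from the
#' aggregation denominator, not relabelled. All other tiles pass unchanged.
#'
#' @param lattice A tibble with columns `row`, `col`, `label` (class codes;
#'   `NA` for unlabelled tiles).
#' @param min_component_size Smallest cancer component retained; default 2,
#'   so single isolated tumor tiles are dropped.
#' @param connectivity 4 or 8 (default) neighbourhood.
#' @param ontology Ontology used for the group projection.
#' @return The lattice with `level1` and `ignored` columns added.
#' @export
outlier_filter <- function(lattice, min_component_size = 2, connectivity = 8,
                           ontology = gastric_ontology()) {
  if (min_component_size < 1) stop("min_component_size must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lattice <- tibble::as_tibble(lattice)
  lattice$level1 <- level1_triage(lattice$label, ontology)
  nr <- max(lattice$row); nc <- max(lattice$col)
  cancer <- matrix(FALSE, nr, nc)
  is_cancer <- !is.na(lattice$level1) & lattice$level1 == "cancer"
  cancer[cbind(lattice$row[is_cancer], lattice$col[is_cancer])] <- TRUE
  comp <- label_components(cancer, connectivity)
  sizes <- tabulate(comp)
  lattice$ignored <- FALSE
  if (any(is_cancer)) {
    ids <- comp[cbind(lattice$row[is_cancer], lattice$col[is_cancer])]
    lattice$ignored[is_cancer] <- sizes[ids] < min_component_size
  }
  lattice
}

#' Scan-level ICD-10 code from a filtered tile lattice
#'
#' Builds a tile-count composition from the retained, labelled tiles (one
#' count unit per tile) and delegates to [assign_icd10()]. Tiles flagged as
#' ignored by [outlier_filter()] and unlabelled tiles do not contribute.
#'
#' @param lattice A tibble with `row`, `col`, `label`, and optionally
#'   `ignored` (as produced by [outlier_filter()]).
#' @param min_invasive_frac Passed to [assign_icd10()]; default 0.
#' @param ontology Class ontology.
#' @param slide_id Identifier for the resulting call; default `"scan"`.
#' @return A tibble `slide_id`, `icd10`, `n_tiles_used`.
#' @export
aggregate_icd10 <- function(lattice, min_invasive_frac = 0,
                            ontology = gastric_ontology(),
                            slide_id = "scan") {
  lattice <- tibble::as_tibble(lattice)
  if (!"ignored" %in% names(lattice)) lattice$ignored <- FALSE
  used <- lattice[!lattice$ignored & !is.na(lattice$label), ]
  if (nrow(used) == 0) stop("no retained labelled tiles to aggregate")
  counts <- dplyr::count(used, class_code = .data$label, name = "pixel_count")
  comp <- compose(counts, slide_id = slide_id)
  res <- assign_icd10(comp, min_invasive_frac, ontology)
  res$n_tiles_used <- nrow(used)
  res
}

#' Simulate a noisy tile classifier
#'
#' Emulates a per-class recall profile: each tile keeps its true label with
#' probability `recall[label]` and otherwise receives an error label. With
#' `confusion_spill = "uniform"` the error label is drawn uniformly from
#' the other ontology classes; `"within_group"` draws it uniformly from the
#' other classes of the same first-level group (carcinoma errors stay
#' carcinoma, and so on — the confusion structure slice classifiers mostly
#' exhibit), falling back to uniform for singleton groups; alternatively a
#' named list of probability vectors over codes specifies where each
#' class's errors go. Reproducible
#' under `seed`. The packaged default recall table
#' ([default_recall_table()]) mirrors the accuracy profile a slice
#' classifier realistically attains, with near-chance recall for low-grade
#' dysplasia.
#'
#' @param lattice A tibble with `row`, `col`, `label` (true class codes).
#' @param recall Named numeric vector of per-class recalls in `[0, 1]`;
#'   classes not named keep recall 1.
#' @param confusion_spill `"uniform"` or a named list of named probability
#'   vectors.
#' @param seed Integer seed.
#' @param ontology Class ontology.
#' @return The lattice with a `predicted` column.
#' @export
simulate_classifier <- function(lattice, recall = default_recall_table(),
                                confusion_spill = "uniform", seed = 1,
                                ontology = gastric_ontology()) {
  if (any(recall < 0 | recall > 1)) stop("recalls must lie in [0, 1]")
  lattice <- tibble::as_tibble(lattice)
  codes <- ontology$code
  with_seed(seed, {
    lab <- lattice$label
    r <- ifelse(lab %in% names(recall), recall[lab], 1)
    keep <- stats::runif(length(lab)) < r
    pred <- lab
    wrong <- which(!keep & !is.na(lab))
    grp <- level1_triage(codes, ontology)
    for (i in wrong) {
      if (identical(confusion_spill, "uniform")) {
        pool <- setdiff(codes, lab[i])
        pred[i] <- sample(pool, 1)
      } else if (identical(confusion_spill, "within_group")) {
        g <- grp[match(lab[i], codes)]
        pool <- setdiff(codes[grp == g], lab[i])
        if (length(pool) == 0) pool <- setdiff(codes, lab[i])
        pred[i] <- sample(pool, 1)
      } else {
        p <- confusion_spill[[lab[i]]]
        if (is.null(p)) stop("no confusion_spill entry for class ", lab[i])
        pred[i] <- sample(names(p), 1, prob = p)
      }
    }
    lattice$predicted <- pred
  })
  lattice
}

#' Default per-class recall profile for the classifier simulator
#'
#' High recall for fibrin and the common carcinoma classes, moderate recall
#' for mucinous/intermediate classes, poor recall for dysplasia (high-grade
#' 0.53, low-grade 0.05), matching the accuracy spread a slice classifier
#' exhibits across frequent and rare classes.
#'
#' @return Named numeric vector of recalls.
#' @export
default_recall_table <- function() {
  c(F = 0.86, NG = 0.80, IM = 0.78, LT = 0.70, GT = 0.70, CG = 0.70,
    FP = 0.70,
    TACG3 = 0.91, PACG1 = 0.88, PCC = 0.87, TACG1 = 0.84,
    MAC1 = 0.71, MAC2 = 0.66, `PCC-NOS` = 0.70, TACG2 = 0.68,
    PACG2 = 0.60, MPAC = 0.50, ACLS = 0.50, HAC = 0.50, ACFG = 0.50,
    SCC = 0.50, NDC = 0.50, NED = 0.50,
    GINH = 0.53, GINL = 0.05)
}

#' Split slides into training and validation cohorts
#'
#' Random, seed-reproducible partition at a fixed ratio (default 4:1). The
#' realized sizes are within one slide of the exact ratio.
#'
#' @param slides Character vector (or any vector) of slide identifiers.
#' @param ratio Length-2 numeric `c(train, validation)` weights.
#' @param seed Integer seed.
#' @return A tibble `slide_id`, `cohort` (`"train"` / `"validation"`).
#' @export
dataset_split <- function(slides, ratio = c(4, 1), seed = 1) {
  n <- length(slides)
  if (n == 0) stop("no slides to split")
  n_val <- max(1L, round(n * ratio[2] / sum(ratio)))
  if (n_val >= n) n_val <- n - 1L
  with_seed(seed, {
    val <- sample(seq_len(n), n_val)
    tibble::tibble(
      slide_id = as.character(slides),
      cohort = ifelse(seq_len(n) %in% val, "validation", "train")
    )
  })
}
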