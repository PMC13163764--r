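# Survival analysis layer: Kaplan-Meier fits, restricted mean survival,
# two-group log-rank tests and the high-grade threshold sweep. Estimation
# is delegated to the survival package; this layer supplies the tidy
# interface, the restricted-mean step integration and the sweep logic.

check_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  req <- c("time", "event")
  missing_col <- setdiff(req, names(cohort))
  if (length(missing_col) > 0) {
    stop("cohort needs column(s): ", paste(missing_col, collapse = ", "))
  }
  if (nrow(cohort) == 0) stop("empty cohort")
  if (any(is.na(cohort$time)) || any(cohort$time < 0)) {
    stop("times must be non-negative")
  }
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0/1")
  cohort
}

#' Kaplan-Meier product-limit fit
#'
#' Fits the product-limit estimator to a cohort, overall or within groups.
#' Censored observations reduce the risk set without introducing steps;
#' ties at event times use the standard simultaneous-risk-set convention.
#'
#' @param cohort A data frame with columns `time` (months), `event` (1 =
#'   death, 0 = censored) and optionally the grouping column.
#' @param group Name of the grouping column, or `NULL` for a single curve.
#' @return A `gm_km` object wrapping the fit; use [tidy()] for the step
#'   table, [glance()] for per-group summaries, [survival_at()] and
#'   [restricted_mean()] for functionals, and [autoplot()] to draw it.
#' @examples
#' km <- km_fit(tibble::tibble(time = c(2, 5, 7, 9), event = c(1, 0, 1, 0)))
#' survival_at(km, 6)
#' @export
km_fit <- function(cohort, group = NULL) {
  cohort <- check_cohort(cohort)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = cohort)
  } else {
    if (!group %in% names(cohort)) stop("no grouping column '", group, "'")
    cohort$.group <- cohort[[group]]
    fit <- survival::survfit(survival::Surv(time, event) ~ .group,
                             data = cohort)
  }
  structure(list(fit = fit, cohort = cohort, group = group),
            class = "gm_km")
}

#' @export
print.gm_km <- function(x, ...) {
  cat("<gm_km> Kaplan-Meier fit",
      if (!is.null(x$group)) paste0(" by '", x$group, "'"), "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname km_fit
#' @param x A `gm_km` object.
#' @param ... Unused.
#' @export
tidy.gm_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  out <- tibble::tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv,
    std_error = s$std.err, conf_low = s$lower, conf_high = s$upper
  )
  out$group <- if (!is.null(x$group)) {
    sub("^\\.group=", "", as.character(s$strata))
  } else "all"
  dplyr::relocate(out, "group")
}

#' @rdname km_fit
#' @export
glance.gm_km <- function(x, ...) {
  td <- tidy(x)
  td |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = max(.data$n_risk), events = sum(.data$n_event),
      rmean = {
        horizon <- max(.data$time)
        km_step_area(.data$time, .data$survival, horizon)
      },
      rmean_horizon = max(.data$time),
      .groups = "drop"
    )
}

# area under the KM step function on [0, horizon]
km_step_area <- function(times, surv, horizon) {
  keep <- times <= horizon
  times <- times[keep]; surv <- surv[keep]
  o <- order(times)
  times <- times[o]; surv <- surv[o]
  edges <- c(0, times, horizon)
  heights <- c(1, surv)
  sum(heights * diff(edges))
}

#' Survival probability at a time point
#'
#' Evaluates the fitted step function at `t` (right-continuous: the value
#' just after any event at `t`).
#'
#' @param km A `gm_km` object.
#' @param t Time point (same unit as the cohort times).
#' @return A tibble `group`, `time`, `survival`.
#' @export
survival_at <- function(km, t) {
  td <- tidy(km)
  td |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      survival = {
        idx <- which(.data$time <= t)
        if (length(idx) == 0) 1 else .data$survival[idx[which.max(.data$time[idx])]]
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(time = t, .before = "survival")
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier step function on `[0, horizon]`, the
#' mean-survival summary that remains well defined under censoring (the
#' unrestricted mean is not, when the curve does not reach zero).
#'
#' @param km A `gm_km` object.
#' @param horizon Positive horizon; default the largest observed time per
#'   group.
#' @return A tibble `group`, `horizon`, `rmean` (months if times are
#'   months).
#' @export
restricted_mean <- function(km, horizon = NULL) {
  if (!is.null(horizon) && horizon <= 0) stop("horizon must be positive")
  td <- tidy(km)
  td |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      horizon = horizon %||% max(.data$time),
      rmean = km_step_area(.data$time, .data$survival,
                           horizon %||% max(.data$time)),
      .groups = "drop"
    )
}

#' Two-group log-rank test
#'
#' Standard unweighted log-rank test (hypergeometric variance, no
#' continuity correction) comparing the survival distributions of two
#' groups; the statistic is chi-square with 1 degree of freedom.
#'
#' @param cohort A data frame with `time`, `event` and the grouping column.
#' @param group Name of the grouping column (exactly two non-empty levels).
#' @return A `gm_logrank` object; `tidy()`/`glance()` give `statistic`,
#'   `df`, `p_value` and group sizes.
#' @export
logrank_test <- function(cohort, group = "group") {
  cohort <- check_cohort(cohort)
  if (!group %in% names(cohort)) stop("no grouping column '", group, "'")
  g <- as.factor(as.character(cohort[[group]]))
  if (nlevels(g) != 2) {
    stop("log-rank test needs exactly two non-empty groups, got ",
         nlevels(g))
  }
  cohort$.group <- g
  sd <- survival::survdiff(survival::Surv(time, event) ~ .group,
                           data = cohort)
  structure(
    list(statistic = unname(sd$chisq), df = 1L,
         p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         n = unname(sd$n), observed = unname(sd$obs),
         expected = unname(sd$exp), groups = levels(g)),
    class = "gm_logrank"
  )
}

#' @export
print.gm_logrank <- function(x, ...) {
  cat(sprintf("<gm_logrank> chisq = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `gm_logrank` object.
#' @param ... Unused.
#' @export
tidy.gm_logrank <- function(x, ...) {
  tibble::tibble(group = x$groups, n = x$n, observed = x$observed,
                 expected = x$expected)
}

#' @rdname logrank_test
#' @export
glance.gm_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' High-grade threshold sweep
#'
#' Decomposes the cohort at every candidate high-grade-fraction cut-point
#' from 1% to 99%: at each threshold patients are dichotomized by
#' `hg_fraction > threshold` and a two-group log-rank test is run. Rows
#' whose dichotomy is degenerate (an empty side) are marked not evaluable
#' rather than raising an error. The evaluable threshold with the smallest
#' p-value is flagged — the data-driven grading cut-point.
#'
#' @param cohort A data frame with `time`, `event`, `hg_fraction` (in
#'   `[0, 1]`).
#' @param thresholds Integer percent thresholds; default `1:99`.
#' @return A tibble of class `gm_sweep` with one row per threshold:
#'   `threshold` (percent), `n_low`, `n_high`, `chisq`, `p`, `evaluable`,
#'   `is_best`.
#' @export
hg_threshold_sweep <- function(cohort, thresholds = 1:99) {
  cohort <- check_cohort(cohort)
  if (!"hg_fraction" %in% names(cohort)) stop("cohort needs hg_fraction")
  if (any(is.na(cohort$hg_fraction))) stop("hg_fraction has missing values")
  out <- purrr::map_dfr(thresholds, function(th) {
    high <- cohort$hg_fraction > th / 100
    n_high <- sum(high); n_low <- sum(!high)
    if (n_high == 0 || n_low == 0) {
      return(tibble::tibble(threshold = th, n_low = n_low, n_high = n_high,
                            chisq = NA_real_, p = NA_real_,
                            evaluable = FALSE))
    }
    cohort$group <- ifelse(high, "high", "low")
    lr <- logrank_test(cohort, "group")
    tibble::tibble(threshold = th, n_low = n_low, n_high = n_high,
                   chisq = lr$statistic, p = lr$p_value, evaluable = TRUE)
  })
  out$is_best <- FALSE
  if (any(out$evaluable)) {
    best <- which(out$p == min(out$p, na.rm = TRUE))[1]
    out$is_best[best] <- TRUE
  }
  class(out) <- c("gm_sweep", class(out))
  out
}
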