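# Shared fixtures and independent oracles used across the suite.

# axis-aligned rectangle polygon rows
rect_poly <- function(id, code, x0, y0, x1, y1) {
  tibble::tibble(polygon_id = id, class_code = code,
                 x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# composition from named pixel counts
make_comp <- function(counts, slide_id = "s1", unannotated = 0) {
  compose(tibble::tibble(class_code = c(names(counts), "unannotated"),
                         pixel_count = c(unname(counts), unannotated)),
          slide_id = slide_id)
}

# brute-force product-limit estimator: S(t) at each distinct event time
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  tibble::tibble(time = ts, survival = out)
}

# log-rank chi-square statistic computed directly from the O-E sums
oracle_logrank_stat <- function(time, event, g) {
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# vectorized permutation null of the log-rank statistic (B permutations of
# the group labels); returns the permuted statistics
perm_logrank_null <- function(time, event, g, B, seed) {
  ts <- sort(unique(time[event == 1]))
  n <- length(time)
  at_risk <- outer(time, ts, ">=") * 1          # n x k
  is_event <- outer(time, ts, "==") * event     # n x k
  d <- colSums(is_event)
  nrisk <- colSums(at_risk)
  withr::with_seed(seed, {
    G <- matrix(0, B, n)
    n1 <- sum(g == 1)
    for (b in seq_len(B)) G[b, sample.int(n, n1)] <- 1
    N1 <- G %*% at_risk                          # B x k
    D1 <- G %*% is_event
    E <- sweep(N1, 2, d / nrisk, "*")
    V <- sweep(N1 * sweep(-N1, 2, nrisk, "+"), 2,
               d * (nrisk - d) / (nrisk^2 * pmax(nrisk - 1, 1)), "*")
    rowSums(D1 - E)^2 / rowSums(V)
  })
}

# exhaustive enumeration of connected components on a logical matrix via
# repeated neighbourhood expansion (independent of the package's flood fill)
oracle_components <- function(mat, connectivity = 8) {
  nr <- nrow(mat); nc <- ncol(mat)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  neigh <- function(r, c) {
    if (connectivity == 4) {
      d <- cbind(c(r - 1, r + 1, r, r), c(c, c, c - 1, c + 1))
    } else {
      d <- as.matrix(expand.grid(r = r + (-1:1), c = c + (-1:1)))
      d <- d[!(d[, 1] == r & d[, 2] == c), ]
    }
    d[d[, 1] >= 1 & d[, 1] <= nr & d[, 2] >= 1 & d[, 2] <= nc, , drop = FALSE]
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mat[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    frontier <- matrix(c(r, c), 1)
    lab[r, c] <- nxt
    while (nrow(frontier) > 0) {
      nxt_frontier <- NULL
      for (i in seq_len(nrow(frontier))) {
        nb <- neigh(frontier[i, 1], frontier[i, 2])
        for (j in seq_len(nrow(nb))) {
          if (mat[nb[j, 1], nb[j, 2]] && lab[nb[j, 1], nb[j, 2]] == 0L) {
            lab[nb[j, 1], nb[j, 2]] <- nxt
            nxt_frontier <- rbind(nxt_frontier, nb[j, , drop = FALSE])
          }
        }
      }
      frontier <- if (is.null(nxt_frontier)) matrix(nrow = 0, ncol = 2) else nxt_frontier
    }
  }
  lab
}

# random simple star-shaped polygon around a center (never self-intersects)
random_star_polygon <- function(n_vertices, cx, cy, rmin, rmax) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, rmin, rmax)
  list(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}
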