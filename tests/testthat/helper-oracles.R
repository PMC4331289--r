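# Independent oracles and shared fixtures for the test suite.
# These deliberately re-derive results through different algorithms than
# the package (winding numbers instead of ray casting, double loops
# instead of cumulative counts) so agreement is informative.

# --- point-in-polygon oracle: winding number + explicit boundary test ---
oracle_point_in_polygon <- function(px, py, rings, eps = 1e-9) {
  on_boundary <- function(x, y) {
    for (ring in rings) {
      for (e in seq_len(nrow(ring) - 1)) {
        ax <- ring[e, 1]; ay <- ring[e, 2]
        bx <- ring[e + 1, 1]; by <- ring[e + 1, 2]
        cross <- (x - ax) * (by - ay) - (y - ay) * (bx - ax)
        seg2 <- (bx - ax)^2 + (by - ay)^2
        if (abs(cross) <= eps * max(1, sqrt(seg2)) &&
            (x - ax) * (bx - ax) + (y - ay) * (by - ay) >= -eps &&
            (x - bx) * (ax - bx) + (y - by) * (ay - by) >= -eps) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  winding <- function(x, y, ring) {
    wn <- 0
    for (e in seq_len(nrow(ring) - 1)) {
      ay <- ring[e, 2]; by <- ring[e + 1, 2]
      is_left <- (ring[e + 1, 1] - ring[e, 1]) * (y - ay) -
        (x - ring[e, 1]) * (by - ay)
      if (ay <= y && by > y && is_left > 0) wn <- wn + 1
      if (ay > y && by <= y && is_left < 0) wn <- wn - 1
    }
    wn
  }
  vapply(seq_along(px), function(i) {
    if (on_boundary(px[i], py[i])) return(TRUE)
    # even-odd over rings via parity of nonzero winding numbers
    hits <- sum(vapply(rings, function(r) winding(px[i], py[i], r) != 0,
                       logical(1)))
    hits %% 2 == 1
  }, logical(1))
}

# Exhaustive zonal statistics: visit every pixel of the scene.
oracle_zonal_means <- function(scene, polygon) {
  d <- dim(scene$bands$Blue)
  g <- scene$geotransform
  sums <- c(Blue = 0, Gree = 0, Red = 0, NIR = 0)
  npx <- 0
  for (r in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      x <- g[1] + (cc - 0.5) * g[3]
      y <- g[2] - (r - 0.5) * g[4]
      if (oracle_point_in_polygon(x, y, polygon)) {
        npx <- npx + 1
        for (b in names(sums)) sums[b] <- sums[b] + scene$bands[[b]][r, cc]
      }
    }
  }
  if (npx == 0) return(NULL)
  sums / npx
}

# --- exhaustive best-split oracle ------------------------------------
# Double loop over every (variable, midpoint) pair; candidates ranked by
# the exact rational score S_L/n_L + S_R/n_R via integer cross
# multiplication, ties to the more balanced children, then the widest
# normalized margin, then earlier variable, then smaller threshold (the
# package's documented rule).
oracle_best_split <- function(features, labels, min_child = 1,
                              scales = NULL) {
  features <- as.data.frame(features)
  y <- as.character(labels)
  n <- length(y)
  classes <- sort(unique(y))
  sq_sum <- function(lab) sum(table(factor(lab, levels = classes))^2)
  S_p <- sq_sum(y)
  best <- NULL
  for (v in seq_along(features)) {
    x <- as.numeric(features[[v]])
    cuts <- sort(unique(x))
    if (length(cuts) < 2) next
    scale_v <- if (!is.null(scales)) scales[[names(features)[v]]] else {
      max(x) - min(x)
    }
    for (ci in seq_len(length(cuts) - 1)) {
      thr <- (cuts[ci] + cuts[ci + 1]) / 2
      left <- x <= thr
      n_L <- sum(left); n_R <- n - n_L
      if (n_L < min_child || n_R < min_child) next
      S_L <- sq_sum(y[left]); S_R <- sq_sum(y[!left])
      a <- S_L * n_R + S_R * n_L
      d <- n_L * n_R
      if (n * a <= S_p * d) next   # no impurity reduction
      cand <- list(a = a, d = d, bal = abs(n_L - n_R),
                   gap = if (scale_v > 0) (cuts[ci + 1] - cuts[ci]) / scale_v else 0,
                   v = v, thr = thr,
                   improvement = (1 - S_p / n^2) -
                     ((n_L / n) * (1 - S_L / n_L^2) +
                      (n_R / n) * (1 - S_R / n_R^2)),
                   variable = names(features)[v])
      if (is.null(best)) { best <- cand; next }
      cmp <- cand$a * best$d - best$a * cand$d
      take <- if (cmp != 0) cmp > 0 else if (cand$bal != best$bal) {
        cand$bal < best$bal
      } else if (cand$gap != best$gap) {
        cand$gap > best$gap
      } else if (cand$v != best$v) cand$v < best$v else cand$thr < best$thr
      if (take) best <- cand
    }
  }
  best
}

# --- shared fixtures -------------------------------------------------
# A memoized default synthetic study: several tests share it.
.study_cache <- new.env(parent = emptyenv())
default_study <- function(seed = 7, noise_scale = 1) {
  key <- paste0("s", seed, "_n", noise_scale)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- make_study(seed = seed, noise_scale = noise_scale)
  }
  .study_cache[[key]]
}

# Small labeled matrix with well separated classes, built directly.
toy_matrix <- function(n_per = 10, k = 3, times = c("T1", "T2"), seed = 1,
                       sd = 0.3) {
  set.seed(seed)
  classes <- LETTERS[seq_len(k)]
  rows <- do.call(rbind, lapply(seq_len(k), function(j) {
    vars <- as.vector(t(outer(times, cropclassr:::SBVI_VARS, paste0)))
    m <- matrix(stats::rnorm(n_per * length(vars), mean = 3 * j, sd = sd),
                n_per, length(vars), dimnames = list(NULL, vars))
    data.frame(parcel_id = sprintf("%s_%02d", classes[j], seq_len(n_per)),
               m, land_use = classes[j],
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  rownames(rows) <- NULL
  structure(rows, times = times,
            class = c("cropclass_matrix", "data.frame"))
}

# Tiny in-memory scene with reproducible DN grids.
toy_scene <- function(nr = 8, nc = 8, seed = 1, time_tag = "T1",
                      origin = c(100, 200), px = 2) {
  set.seed(seed)
  bands <- lapply(c(Blue = 1, Gree = 2, Red = 3, NIR = 4), function(k) {
    matrix(as.numeric(sample(0:1000, nr * nc, replace = TRUE)), nr, nc)
  })
  raster_scene(bands, c(origin[1], origin[2], px, px),
               crs_tag = "toy", time_tag = time_tag)
}
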