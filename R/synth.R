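# Synthetic phenology-driven scene generator.
#
# Each land-use class is modeled as a linear mixture of three ground
# endmembers (green vegetation, bare soil, senescent stubble — plus water
# and built surfaces for the non-vegetative classes) whose vegetation
# cover fraction follows a piecewise-linear seasonal trajectory.  Pixel
# noise is Gaussian, spatially independent, clipped at zero and rounded
# to integer digital numbers.  All numeric profile values are module
# parameters chosen to reproduce the qualitative temporal signatures of
# the cropping systems (winter crops green in spring then stubble from
# early summer; summer crops peaking mid-season; adult orchards
# near-constant; non-vegetation flat and low) — they are fixtures, not
# measurements.

# endmember digital numbers (Blue, Gree, Red, NIR)
EM_VEG     <- c(Blue = 80,  Gree = 150, Red = 60,  NIR = 900)
EM_SOIL    <- c(Blue = 300, Gree = 400, Red = 500, NIR = 600)
EM_STUBBLE <- c(Blue = 350, Gree = 520, Red = 680, NIR = 720)
EM_WATER   <- c(Blue = 250, Gree = 300, Red = 200, NIR = 60)
EM_URBAN   <- c(Blue = 600, Gree = 650, Red = 700, NIR = 750)

# piecewise-linear keyframe lookup on normalized season position u in [0,1]
traj <- function(u, keys) {
  stats::approx(keys[, 1], keys[, 2], xout = u, rule = 2)$y
}

profile_bands <- function(u, v_keys, s_keys = NULL, base_veg = EM_VEG,
                          base_dry = EM_SOIL) {
  v <- traj(u, v_keys)
  s <- if (is.null(s_keys)) rep(0, length(u)) else traj(u, s_keys)
  t(vapply(seq_along(u), function(i) {
    base <- (1 - s[i]) * base_dry + s[i] * EM_STUBBLE
    v[i] * base_veg + (1 - v[i]) * base
  }, numeric(4)))
}

flat_bands <- function(u, em) {
  matrix(rep(em, each = length(u)), nrow = length(u),
         dimnames = list(NULL, names(em)))
}

new_profile <- function(class_label, system, bands, sd, times) {
  colnames(bands) <- c("Blue", "Gree", "Red", "NIR")
  # profiles are quantized to integer digital numbers, so a noise-free
  # scene reproduces them exactly even through the 16-bit raster format
  bands <- round(bands)
  if (any(bands < 0)) stop("profile band means must be non-negative")
  structure(list(class_label = class_label, system = system,
                 bands = bands, sd = sd, times = times),
            class = "phenology_profile")
}

#' NDVI trajectory of a noise-free profile
#'
#' @param profile a `phenology_profile`.
#' @return numeric NDVI per acquisition time.
#' @export
profile_ndvi <- function(profile) {
  b <- profile$bands
  (b[, "NIR"] - b[, "Red"]) / (b[, "NIR"] + b[, "Red"])
}

#' Default phenology profiles
#'
#' Ten land-use classes spanning the label hierarchy: winter crops WHT
#' and OAT; summer crops COT, CRN and SUN (differing in peak timing);
#' adult tree orchards OLV and CIT (near-constant cover); a young tree
#' orchard YTO (sparse constant cover); and the non-vegetative classes
#' CIV (built surfaces) and WAT (water).  The noise-free NDVI
#' trajectories satisfy, by construction: winter crops NDVI(T1) >= 0.6
#' falling to <= 0.25 from mid-season on; summer crops start <= 0.25,
#' peak >= 0.6 away from the series ends, finish <= 0.3; adult orchards
#' have NDVI range <= 0.15; non-vegetation stays <= 0.2 throughout.
#'
#' @param times ordered acquisition tags (at least 3).
#' @param sd common per-pixel Gaussian noise standard deviation in
#'   digital numbers (default 40).
#' @return named list of `phenology_profile`s.
#' @export
default_profiles <- function(times, sd = 40) {
  n <- length(times)
  if (n < 3) stop("need at least 3 acquisition times")
  u <- seq(0, 1, length.out = n)
  kf <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  profs <- list(
    new_profile("WHT", "WIC",
                profile_bands(u, kf(0, 0.85, 0.2, 0.6, 0.35, 0.2, 0.5, 0.02, 1, 0),
                              kf(0, 0, 0.35, 0, 0.5, 1, 1, 1)),
                sd, times),
    new_profile("OAT", "WIC",
                profile_bands(u, kf(0, 0.75, 0.2, 0.4, 0.3, 0.08, 0.45, 0.02, 1, 0),
                              kf(0, 0, 0.3, 0, 0.45, 1, 1, 1)),
                sd, times),
    new_profile("COT", "SUC",
                profile_bands(u, kf(0, 0.05, 0.3, 0.1, 0.5, 0.7, 0.65, 0.95,
                                    0.8, 0.8, 1, 0.25)),
                sd, times),
    new_profile("CRN", "SUC",
                profile_bands(u, kf(0, 0.05, 0.25, 0.2, 0.45, 0.85, 0.6, 0.95,
                                    0.8, 0.3, 1, 0.07),
                              kf(0, 0, 0.7, 0, 0.9, 0.7, 1, 0.8)),
                sd, times),
    new_profile("SUN", "SUC",
                profile_bands(u, kf(0, 0.1, 0.2, 0.5, 0.4, 0.9, 0.55, 0.6,
                                    0.7, 0.15, 1, 0.03),
                              kf(0, 0, 0.6, 0, 0.85, 0.8, 1, 0.8)),
                sd, times),
    new_profile("OLV", "ATO",
                profile_bands(u, kf(0, 0.42, 0.5, 0.48, 1, 0.44)),
                sd, times),
    new_profile("CIT", "ATO",
                profile_bands(u, kf(0, 0.65, 0.5, 0.70, 1, 0.66)),
                sd, times),
    new_profile("YTO", "YTO",
                profile_bands(u, kf(0, 0.18, 0.5, 0.24, 1, 0.2)),
                sd, times),
    new_profile("CIV", "CiWo", flat_bands(u, EM_URBAN), sd, times),
    new_profile("WAT", "WTS", flat_bands(u, EM_WATER), sd, times)
  )
  stats::setNames(profs, vapply(profs, function(p) p$class_label, character(1)))
}

#' Check profiles against their declared seasonal patterns
#'
#' Applies the pattern constraints listed under [default_profiles()] to
#' the noise-free NDVI trajectory of each profile, keyed by its cropping
#' system.
#'
#' @param profiles list of `phenology_profile`s.
#' @return `TRUE` invisibly; stops with the offending class otherwise.
#' @export
validate_profiles <- function(profiles) {
  for (p in profiles) {
    nd <- profile_ndvi(p)
    n <- length(nd)
    mid <- ceiling((n + 1) / 2)
    ok <- switch(p$system,
      WIC = nd[1] >= 0.6 && all(nd[mid:n] <= 0.25),
      SUC = nd[1] <= 0.25 && max(nd) >= 0.6 &&
        !(which.max(nd) %in% c(1L, n)) && nd[n] <= 0.3,
      ATO = diff(range(nd)) <= 0.15,
      YTO = TRUE,
      CiWo = all(nd <= 0.2),
      WTS = all(nd <= 0.2),
      stop("unknown cropping system '", p$system, "'"))
    if (!ok) {
      stop("profile '", p$class_label, "' violates its ", p$system,
           " NDVI pattern constraint")
    }
  }
  invisible(TRUE)
}

#' Lay out rectangular parcels on a pixel grid
#'
#' Non-overlapping axis-aligned parcel blocks separated by a background
#' gap, with class labels assigned round-robin so classes are spread over
#' the scene.
#'
#' @param classes class labels to place.
#' @param n_per_class parcels per class (scalar or vector along
#'   `classes`).
#' @param parcel_px parcel block size in pixels, `c(rows, cols)`; the
#'   default 12 x 12 (576 square map units at the default pixel size)
#'   keeps parcels large enough that pixel averaging suppresses sensor
#'   noise, as it does on real census parcels, while staying cheap to
#'   simulate.
#' @param gap gap between blocks in pixels.
#' @param pixel_size pixel size in map units (default 2, a typical
#'   very-high-resolution satellite ground sample distance).
#' @param origin map coordinates of the north-west raster corner.
#' @return object of class `scene_layout`.
#' @export
scene_layout <- function(classes, n_per_class = 20, parcel_px = c(12, 12),
                         gap = 2, pixel_size = 2,
                         origin = c(500000, 4100000)) {
  n_per_class <- rep_len(n_per_class, length(classes))
  labels <- rep(classes, times = n_per_class)
  # round-robin interleave by class
  ord <- order(stats::ave(seq_along(labels), labels, FUN = seq_along),
               match(labels, classes))
  labels <- labels[ord]
  N <- length(labels)
  ncol_p <- ceiling(sqrt(N))
  nrow_p <- ceiling(N / ncol_p)
  ph <- parcel_px[1]; pw <- parcel_px[2]
  counts <- stats::setNames(integer(length(classes)), classes)
  parcels <- data.frame(id = character(N), class = labels,
                        row0 = integer(N), col0 = integer(N),
                        stringsAsFactors = FALSE)
  for (i in seq_len(N)) {
    counts[labels[i]] <- counts[labels[i]] + 1L
    parcels$id[i] <- sprintf("%s_%03d", labels[i], counts[labels[i]])
    pr <- (i - 1) %/% ncol_p
    pc <- (i - 1) %% ncol_p
    parcels$row0[i] <- gap + pr * (ph + gap) + 1L
    parcels$col0[i] <- gap + pc * (pw + gap) + 1L
  }
  dim <- c(gap + nrow_p * (ph + gap), gap + ncol_p * (pw + gap))
  structure(list(dim = dim, parcels = parcels, parcel_px = c(ph, pw),
                 pixel_size = pixel_size, origin = origin),
            class = "scene_layout")
}

layout_polygons <- function(layout) {
  g <- layout$pixel_size
  ox <- layout$origin[1]; oy <- layout$origin[2]
  ph <- layout$parcel_px[1]; pw <- layout$parcel_px[2]
  lapply(seq_len(nrow(layout$parcels)), function(i) {
    r0 <- layout$parcels$row0[i]; c0 <- layout$parcels$col0[i]
    rect_polygon(ox + (c0 - 1) * g, oy - (r0 - 1 + ph) * g,
                 ox + (c0 - 1 + pw) * g, oy - (r0 - 1) * g)
  })
}

#' Generate synthetic multitemporal scenes
#'
#' Every pixel of a parcel at every acquisition is drawn independently
#' from `Normal(profile mean, sd * noise_scale)`, clipped at zero and
#' rounded to an integer digital number; background pixels follow a bare
#' soil profile.  Deterministic given `seed`.
#'
#' @param profiles list of `phenology_profile`s (e.g.
#'   [default_profiles()]); must cover every layout class.
#' @param layout a [scene_layout()].
#' @param times acquisition tags; must match the profiles' times.
#' @param seed RNG seed.
#' @param noise_scale multiplier on each profile's noise sd (0 gives
#'   noise-free scenes).
#' @return list with `scenes` (list of [raster_scene()]) and `parcels`
#'   (a labeled [parcel_set()]).
#' @export
generate_scenes <- function(profiles, layout, times = NULL, seed = 1L,
                            noise_scale = 1) {
  if (is.null(times)) times <- profiles[[1]]$times
  miss <- setdiff(unique(layout$parcels$class), names(profiles))
  if (length(miss)) {
    stop("layout class(es) without profile: ", paste(miss, collapse = ", "))
  }
  for (p in profiles) {
    if (!identical(p$times, times)) {
      stop("profile '", p$class_label, "' has different times")
    }
  }
  d <- layout$dim
  g <- layout$pixel_size
  crs <- "SYNTH/UTM-like"
  ph <- layout$parcel_px[1]; pw <- layout$parcel_px[2]
  scenes <- with_seed(seed, lapply(seq_along(times), function(ti) {
    bands <- lapply(BAND_NAMES, function(b) {
      mu <- EM_SOIL[[b]]
      m <- matrix(mu, d[1], d[2])
      if (noise_scale > 0) {
        m <- m + matrix(stats::rnorm(d[1] * d[2], 0, 40 * noise_scale),
                        d[1], d[2])
      }
      m
    })
    names(bands) <- BAND_NAMES
    for (i in seq_len(nrow(layout$parcels))) {
      p <- profiles[[layout$parcels$class[i]]]
      rows <- layout$parcels$row0[i]:(layout$parcels$row0[i] + ph - 1)
      cols <- layout$parcels$col0[i]:(layout$parcels$col0[i] + pw - 1)
      for (b in BAND_NAMES) {
        mu <- p$bands[ti, b]
        vals <- matrix(mu, ph, pw)
        if (noise_scale > 0) {
          vals <- vals + matrix(stats::rnorm(ph * pw, 0, p$sd * noise_scale),
                                ph, pw)
        }
        bands[[b]][rows, cols] <- vals
      }
    }
    bands <- lapply(bands, function(m) pmin(pmax(round(m), 0), DN_MAX))
    raster_scene(bands, c(layout$origin[1], layout$origin[2], g, g),
                 crs_tag = crs, time_tag = times[ti])
  }))
  parcels <- parcel_set(layout$parcels$id, layout_polygons(layout),
                        labels = layout$parcels$class, crs_tag = crs)
  list(scenes = scenes, parcels = parcels)
}

# Stratified largest-remainder train/test allocation; returns logical
# "in training set" per row of `labels`, seeded shuffle within class.
stratified_split <- function(labels, train_fraction, seed) {
  N <- length(labels)
  target <- ceiling(train_fraction * N)
  classes <- unique(labels)
  quota <- vapply(classes, function(cl) sum(labels == cl) * train_fraction,
                  numeric(1))
  base <- floor(quota)
  rem <- target - sum(base)
  if (rem > 0) {
    extra <- order(-(quota - base), seq_along(classes))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sizes <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  base <- pmin(pmax(base, 1), sizes - 1)
  train <- logical(N)
  with_seed(seed, {
    for (j in seq_along(classes)) {
      idx <- sample(which(labels == classes[j]))
      train[idx[seq_len(base[j])]] <- TRUE
    }
  })
  train
}

#' Generate a complete synthetic study
#'
#' Generates scenes and labeled parcels, extracts per-parcel features
#' through the standard extraction path, and splits the parcels into
#' training and testing matrices, stratified by class (largest-remainder
#' allocation, so a 50% fraction of an odd total yields the ceil/floor
#' split).
#'
#' @param profiles list of `phenology_profile`s
#'   (default [default_profiles()] over `times`).
#' @param n_parcels_per_class scalar or per-class vector (default 20).
#' @param times acquisition tags (default `T1 ... T7`).
#' @param seed RNG seed driving both pixel noise and the split.
#' @param train_fraction fraction of parcels used for training
#'   (default 0.5).
#' @param noise_scale pixel noise multiplier.
#' @param vi_mode see [extract_sbvi()].
#' @return list with `train` and `test` (`cropclass_matrix`), `records`
#'   (all SBVI records), `scenes`, `parcels`, and `split` (named logical:
#'   parcel in training set).
#' @export
make_study <- function(profiles = NULL, n_parcels_per_class = 20,
                       times = paste0("T", 1:7), seed = 1L,
                       train_fraction = 0.5, noise_scale = 1,
                       vi_mode = "per_pixel") {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (is.null(profiles)) profiles <- default_profiles(times)
  classes <- vapply(profiles, function(p) p$class_label, character(1))
  n_per <- rep_len(n_parcels_per_class, length(classes))
  if (any(n_per < 2)) stop("every class needs at least 2 parcels")
  layout <- scene_layout(classes, n_per)
  sim <- generate_scenes(profiles, layout, times, seed = seed,
                         noise_scale = noise_scale)
  records <- extract_sbvi(sim$scenes, sim$parcels, vi_mode = vi_mode)
  mat <- build_matrix(records)
  train <- stratified_split(mat$land_use, train_fraction, seed = seed + 1L)
  split_matrix <- function(rows) {
    structure(mat[rows, , drop = FALSE], times = attr(mat, "times"),
              class = c("cropclass_matrix", "data.frame"))
  }
  list(train = split_matrix(train), test = split_matrix(!train),
       records = records, scenes = sim$scenes, parcels = sim$parcels,
       split = stats::setNames(train, mat$parcel_id))
}
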