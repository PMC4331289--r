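# Raster scenes, parcel vectors and parcel -> pixel resolution.
#
# The environment targeted here stores each acquisition as a 4-sample
# 16-bit TIFF (digital numbers 0..65535) accompanied by an ESRI world file
# (<path>.tfw) carrying the affine geotransform and a <path>.prj sidecar
# carrying an opaque CRS tag.  Grids are north-up: row 1 is the northern
# edge, map extents are half-open [origin, origin + size * n).

BAND_NAMES <- c("Blue", "Gree", "Red", "NIR")
DN_MAX <- 65535L

#' Construct a raster scene
#'
#' One multispectral acquisition: four aligned band grids of non-negative
#' digital numbers plus a geotransform and an ordinal time tag.
#'
#' @param bands named list of numeric matrices `Blue`, `Gree`, `Red`,
#'   `NIR` (alias `Green` accepted), all of identical dimension.
#' @param geotransform numeric vector `c(origin_x, origin_y, pixel_size_x,
#'   pixel_size_y)`; the origin is the north-west corner, pixel sizes are
#'   strictly positive, orientation is north-up.
#' @param crs_tag opaque CRS string; scenes and parcels are only ever
#'   compared for tag equality, never reprojected.
#' @param time_tag ordinal acquisition label, e.g. `"T1"`.
#' @return an object of class `raster_scene`.
#' @export
raster_scene <- function(bands, geotransform, crs_tag = "", time_tag = "T1") {
  names(bands)[names(bands) == "Green"] <- "Gree"
  missing <- setdiff(BAND_NAMES, names(bands))
  if (length(missing)) {
    stop("missing band(s): ", paste(missing, collapse = ", "))
  }
  bands <- bands[BAND_NAMES]
  dims <- lapply(bands, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all four band grids must have identical shape")
  }
  for (b in BAND_NAMES) {
    v <- bands[[b]]
    if (!is.numeric(v)) stop("band ", b, " is not numeric")
    if (anyNA(v) || any(v < 0)) {
      stop("band ", b, " contains NA or negative digital numbers")
    }
  }
  geotransform <- as.numeric(geotransform)
  if (length(geotransform) != 4 || anyNA(geotransform)) {
    stop("geotransform must be c(origin_x, origin_y, pixel_size_x, pixel_size_y)")
  }
  if (geotransform[3] <= 0 || geotransform[4] <= 0) {
    stop("pixel sizes must be strictly positive")
  }
  names(geotransform) <- c("origin_x", "origin_y", "pixel_size_x", "pixel_size_y")
  structure(
    list(bands = bands, geotransform = geotransform,
         crs_tag = as.character(crs_tag), time_tag = as.character(time_tag)),
    class = "raster_scene"
  )
}

#' @export
print.raster_scene <- function(x, ...) {
  d <- dim(x$bands$Blue)
  cat(sprintf("<raster_scene %s: %d x %d px, 4 bands, pixel %g x %g, crs '%s'>\n",
              x$time_tag, d[1], d[2],
              x$geotransform[3], x$geotransform[4], x$crs_tag))
  invisible(x)
}

scene_dim <- function(scene) dim(scene$bands$Blue)

# Map coordinates of pixel centers for 1-based (row, col).
pixel_center <- function(scene, row, col) {
  g <- scene$geotransform
  cbind(x = g[1] + (col - 0.5) * g[3],
        y = g[2] - (row - 0.5) * g[4])
}

#' Write a raster scene to disk
#'
#' Bands are stored as a 4-sample 16-bit TIFF (digital numbers must lie in
#' 0..65535 and are rounded to integers), the geotransform as an ESRI world
#' file `<path>.tfw` and the CRS tag as `<path>.prj`.  The written grids
#' round-trip bit-identically through [read_raster()].
#'
#' @param scene a [raster_scene()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(scene, path) {
  stopifnot(inherits(scene, "raster_scene"))
  d <- scene_dim(scene)
  arr <- array(0, dim = c(d[1], d[2], 4))
  for (k in seq_along(BAND_NAMES)) {
    dn <- round(scene$bands[[BAND_NAMES[k]]])
    if (any(dn < 0) || any(dn > DN_MAX)) {
      stop("digital numbers outside 0..", DN_MAX, " in band ", BAND_NAMES[k])
    }
    arr[, , k] <- dn / DN_MAX
  }
  suppressWarnings(tiff::writeTIFF(arr, path, bits.per.sample = 16L))
  g <- scene$geotransform
  # World file: pixel size, rotations (0), negative y size, center of the
  # upper-left pixel.
  writeLines(num17(c(g[3], 0, 0, -g[4], g[1] + g[3] / 2, g[2] - g[4] / 2)),
             paste0(path, ".tfw"))
  writeLines(scene$crs_tag, paste0(path, ".prj"))
  invisible(path)
}

#' Read a raster scene from disk
#'
#' @param path TIFF path written by [write_raster()] (or any >= 4-sample
#'   TIFF with world-file sidecar).
#' @param time_tag ordinal acquisition label to attach.
#' @param band_order roles of the first four samples, default
#'   `c("Blue", "Gree", "Red", "NIR")` (`"Green"` accepted as alias).
#' @return a [raster_scene()].
#' @export
read_raster <- function(path, time_tag = "T1",
                        band_order = c("Blue", "Gree", "Red", "NIR")) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  band_order[band_order == "Green"] <- "Gree"
  if (!setequal(band_order, BAND_NAMES) || length(band_order) != 4) {
    stop("band_order must be a permutation of Blue, Gree (Green), Red, NIR")
  }
  arr <- tryCatch(suppressWarnings(tiff::readTIFF(path)),
                  error = function(e) stop("unreadable raster '", path, "': ",
                                           conditionMessage(e)))
  if (length(dim(arr)) != 3 || dim(arr)[3] < 4) {
    nb <- if (length(dim(arr)) == 3) dim(arr)[3] else 1L
    stop("expected 4 bands in '", path, "', found ", nb)
  }
  tfw <- paste0(path, ".tfw")
  if (!file.exists(tfw)) stop("missing world file for '", path, "'")
  w <- suppressWarnings(as.numeric(readLines(tfw, warn = FALSE)))
  if (length(w) < 6 || anyNA(w[1:6])) {
    stop("unreadable geotransform in '", tfw, "'")
  }
  if (w[2] != 0 || w[3] != 0 || w[1] <= 0 || w[4] >= 0) {
    stop("only north-up, unrotated rasters are supported ('", tfw, "')")
  }
  prj <- paste0(path, ".prj")
  crs <- if (file.exists(prj)) paste(readLines(prj, warn = FALSE), collapse = " ") else ""
  bands <- stats::setNames(vector("list", 4), band_order)
  for (k in 1:4) bands[[band_order[k]]] <- round(arr[, , k] * DN_MAX)
  raster_scene(bands,
               c(w[5] - w[1] / 2, w[6] - w[4] / 2, w[1], -w[4]),
               crs_tag = crs, time_tag = time_tag)
}

ring_area <- function(ring) {
  # Shoelace; ring closed (first row == last row).
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Construct a parcel set
#'
#' @param ids character vector of unique parcel identifiers.
#' @param polygons list (one element per parcel) of lists of rings; each
#'   ring is an n x 2 matrix of map coordinates with first vertex repeated
#'   last (closed).  The first ring is the outer boundary; further rings
#'   are holes (even-odd rule).
#' @param labels optional character vector of land-use codes (`NA` for
#'   unidentified parcels).
#' @param crs_tag opaque CRS string, compared for equality with scenes.
#' @return an object of class `parcel_set`.
#' @export
parcel_set <- function(ids, polygons, labels = NULL, crs_tag = "") {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate parcel id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(polygons) != length(ids)) stop("ids and polygons differ in length")
  bad <- character()
  for (i in seq_along(polygons)) {
    rings <- polygons[[i]]
    ok <- length(rings) >= 1
    if (ok) {
      for (r in rings) {
        if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 4 ||
            anyNA(r) || any(!is.finite(r)) ||
            !isTRUE(all.equal(r[1, ], r[nrow(r), ]))) {
          ok <- FALSE
        }
      }
    }
    if (ok && abs(ring_area(rings[[1]])) <= 0) ok <- FALSE
    if (!ok) bad <- c(bad, ids[i])
  }
  if (length(bad)) {
    stop("invalid polygon(s) (unclosed, degenerate or zero area) for parcel id(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(labels)) labels <- rep(NA_character_, length(ids))
  structure(
    list(ids = ids, polygons = polygons, labels = as.character(labels),
         crs_tag = as.character(crs_tag)),
    class = "parcel_set"
  )
}

#' @export
length.parcel_set <- function(x) length(x$ids)

#' @export
print.parcel_set <- function(x, ...) {
  cat(sprintf("<parcel_set: %d parcels, %d labeled, crs '%s'>\n",
              length(x$ids), sum(!is.na(x$labels)), x$crs_tag))
  invisible(x)
}

#' Read parcels from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features.  Multi
#' polygons are flattened to one ring list per parcel (even-odd rule).
#'
#' @param path GeoJSON file.
#' @param id_field property holding the unique parcel id
#'   (default `"parcel_id"`).
#' @param label_field property holding the land-use label, if present
#'   (default `"land_use"`).
#' @return a [parcel_set()].
#' @export
read_parcels <- function(path, id_field = "parcel_id", label_field = "land_use") {
  if (!file.exists(path)) stop("parcel file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("'", path, "' is not a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  if (!length(feats)) {
    return(parcel_set(character(), list(),
                      crs_tag = gj$crs$properties$name %||% ""))
  }
  as_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) as.numeric(p[1:2])))
    colnames(m) <- c("x", "y")
    m
  }
  ids <- character(length(feats))
  labels <- rep(NA_character_, length(feats))
  polys <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties[[id_field]]
    if (is.null(id)) stop("feature ", i, " lacks id property '", id_field, "'")
    ids[i] <- as.character(id)
    lab <- f$properties[[label_field]]
    if (!is.null(lab) && !identical(lab, "")) labels[i] <- as.character(lab)
    g <- f$geometry
    polys[[i]] <- switch(
      g$type %||% "",
      Polygon = lapply(g$coordinates, as_ring),
      MultiPolygon = unlist(lapply(g$coordinates,
                                   function(pg) lapply(pg, as_ring)),
                            recursive = FALSE),
      stop("feature '", ids[i], "' has unsupported geometry type '",
           g$type %||% "none", "'")
    )
  }
  parcel_set(ids, polys, labels, crs_tag = gj$crs$properties$name %||% "")
}

#' Write parcels to a GeoJSON file
#'
#' @param parcels a [parcel_set()].
#' @param path output file.
#' @param id_field,label_field property names to write.
#' @return `path`, invisibly.
#' @export
write_parcels <- function(parcels, path,
                          id_field = "parcel_id", label_field = "land_use") {
  stopifnot(inherits(parcels, "parcel_set"))
  feat <- function(i) {
    props <- stats::setNames(list(jsonlite::unbox(parcels$ids[i])), id_field)
    if (!is.na(parcels$labels[i])) {
      props[[label_field]] <- jsonlite::unbox(parcels$labels[i])
    }
    rings <- lapply(parcels$polygons[[i]], function(r) {
      lapply(seq_len(nrow(r)), function(j) c(r[j, 1], r[j, 2]))
    })
    list(type = jsonlite::unbox("Feature"),
         properties = props,
         geometry = list(type = jsonlite::unbox("Polygon"),
                         coordinates = rings))
  }
  obj <- list(type = jsonlite::unbox("FeatureCollection"),
              crs = list(type = jsonlite::unbox("name"),
                         properties = list(name = jsonlite::unbox(parcels$crs_tag))),
              features = lapply(seq_along(parcels$ids), feat))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

# Closed point-in-polygon: TRUE when (px, py) is strictly inside under the
# even-odd rule, or lies exactly on any ring edge (boundary counts as
# inside).  Vectorized over points.
point_in_polygon <- function(px, py, rings, eps = 1e-9) {
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  scale <- max(1, abs(px), abs(py))
  tol <- eps * scale
  for (ring in rings) {
    n <- nrow(ring)
    x1 <- ring[-n, 1]; y1 <- ring[-n, 2]
    x2 <- ring[-1, 1]; y2 <- ring[-1, 2]
    for (e in seq_len(n - 1)) {
      dx <- x2[e] - x1[e]; dy <- y2[e] - y1[e]
      # on-segment test: collinear and within the segment's extent
      cross <- (px - x1[e]) * dy - (py - y1[e]) * dx
      dot <- (px - x1[e]) * dx + (py - y1[e]) * dy
      len2 <- dx * dx + dy * dy
      on <- abs(cross) <= tol * max(1, sqrt(len2)) & dot >= -tol & dot <= len2 + tol
      boundary <- boundary | on
      # even-odd ray cast (horizontal ray towards +x), half-open in y
      crosses <- ((y1[e] > py) != (y2[e] > py))
      if (any(crosses)) {
        xi <- x1[e] + (py - y1[e]) / (y2[e] - y1[e]) * dx
        inside <- xor(inside, crosses & (px < xi))
      }
    }
  }
  inside | boundary
}

# Minimum distance from points to any ring edge.
dist_to_boundary <- function(px, py, rings) {
  d <- rep(Inf, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    for (e in seq_len(n - 1)) {
      x1 <- ring[e, 1]; y1 <- ring[e, 2]
      x2 <- ring[e + 1, 1]; y2 <- ring[e + 1, 2]
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      t <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2)) else 0
      d <- pmin(d, sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2))
    }
  }
  d
}

#' Pixels whose centers fall inside a polygon
#'
#' Membership is decided by the pixel CENTER: a center strictly inside the
#' polygon (even-odd rule over all rings), or exactly on a boundary edge,
#' belongs to the parcel.  No partial-pixel weighting is applied.
#'
#' @param scene a [raster_scene()] providing the grid and geotransform.
#' @param polygon list of closed rings (n x 2 matrices), as stored in a
#'   [parcel_set()].
#' @param crs_tag CRS tag of the polygon; must equal the scene's tag when
#'   both are non-empty (no reprojection is ever attempted).
#' @param buffer non-positive number of map units by which to shrink the
#'   parcel (centers closer than `-buffer` to the boundary are discarded);
#'   a guard against mixed boundary pixels.  Default 0.
#' @return integer matrix with columns `row`, `col` (1-based, row 1 at the
#'   northern edge); zero rows when the polygon misses the raster.
#' @export
parcel_pixel_indices <- function(scene, polygon, crs_tag = NULL, buffer = 0) {
  stopifnot(inherits(scene, "raster_scene"))
  if (!is.null(crs_tag) && nzchar(crs_tag) && nzchar(scene$crs_tag) &&
      !identical(crs_tag, scene$crs_tag)) {
    stop("CRS mismatch: scene '", scene$crs_tag, "' vs parcels '", crs_tag, "'")
  }
  if (buffer > 0) stop("buffer must be <= 0 (parcels are only ever shrunk)")
  d <- scene_dim(scene)
  g <- scene$geotransform
  allx <- unlist(lapply(polygon, function(r) r[, 1]))
  ally <- unlist(lapply(polygon, function(r) r[, 2]))
  # candidate rows/cols from the polygon bounding box
  c0 <- max(1L, 1L + floor((min(allx) - g[1]) / g[3] - 0.5))
  c1 <- min(d[2], 1L + ceiling((max(allx) - g[1]) / g[3] + 0.5))
  r0 <- max(1L, 1L + floor((g[2] - max(ally)) / g[4] - 0.5))
  r1 <- min(d[1], 1L + ceiling((g[2] - min(ally)) / g[4] + 0.5))
  empty <- matrix(integer(), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (c0 > c1 || r0 > r1) return(empty)
  rows <- r0:r1; cols <- c0:c1
  grid <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  ctr <- pixel_center(scene, grid$row, grid$col)
  keep <- point_in_polygon(ctr[, 1], ctr[, 2], polygon)
  if (buffer < 0 && any(keep)) {
    keep[keep] <- dist_to_boundary(ctr[keep, 1], ctr[keep, 2], polygon) >= -buffer
  }
  if (!any(keep)) return(empty)
  out <- cbind(row = as.integer(grid$row[keep]), col = as.integer(grid$col[keep]))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Axis-aligned rectangle as a closed ring (helper used by the synthetic
# layout and convenient for tests).
#' Rectangle polygon helper
#'
#' @param xmin,ymin,xmax,ymax rectangle extent in map coordinates.
#' @return a one-ring polygon (list holding a closed 5 x 2 matrix).
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  list(cbind(x = c(xmin, xmax, xmax, xmin, xmin),
             y = c(ymin, ymin, ymax, ymax, ymin)))
}
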