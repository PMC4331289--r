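# Per-parcel feature extraction: band means, vegetation indices, the
# per-parcel SBVI table and the parcels x (7 features x n times) matrix
# fed to the decision tree.

SBVI_VARS <- c("Blue", "Gree", "Red", "NIR", "NDVI", "Stu", "BG")

# Parse-time aliases for variable tokens.
canonicalize_var <- function(v) {
  v[v == "Green"] <- "Gree"
  v[v == "STU"] <- "Stu"
  v[v == "B/G"] <- "BG"
  v
}

#' Vegetation indices from band values
#'
#' NDVI = (NIR - Red) / (NIR + Red); stubble index Stu = Red / Green;
#' BG = Blue / Green.  A ratio with zero denominator yields `NA`.
#'
#' @param blue,gree,red,nir finite, non-negative digital numbers
#'   (vectorized).
#' @return list with numeric components `ndvi`, `stu`, `bg`.
#' @export
#' @examples
#' compute_vi(50, 100, 100, 300) # ndvi 0.5, stu 1, bg 0.5
compute_vi <- function(blue, gree, red, nir) {
  vals <- c(blue, gree, red, nir)
  if (anyNA(vals) || any(!is.finite(vals))) stop("band values must be finite")
  if (any(vals < 0)) stop("band values must be non-negative")
  ndvi <- ifelse(nir + red == 0, NA_real_, (nir - red) / (nir + red))
  stu <- ifelse(gree == 0, NA_real_, red / gree)
  bg <- ifelse(gree == 0, NA_real_, blue / gree)
  list(ndvi = ndvi, stu = stu, bg = bg)
}

new_sbvi <- function(parcel_id, tab, label = NA_character_) {
  structure(tab, parcel_id = parcel_id, label = label,
            class = c("sbvi_record", "data.frame"))
}

#' Extract per-parcel band means and vegetation indices
#'
#' For every parcel and every acquisition, the arithmetic mean digital
#' number of the member pixels (pixel-center membership, see
#' [parcel_pixel_indices()]) is computed for the four bands, along with
#' NDVI, Stu and B/G.
#'
#' @param series list of [raster_scene()]s sharing grid shape,
#'   geotransform and CRS tag, with unique time tags in series order.
#' @param parcels a [parcel_set()].
#' @param vi_mode `"per_pixel"` (default): the index is computed for each
#'   member pixel and averaged over the parcel, respecting the
#'   nonlinearity of NDVI; `"from_means"`: the index is computed from the
#'   parcel band means.
#' @param buffer non-positive parcel shrink in map units (see
#'   [parcel_pixel_indices()]).
#' @return named list (by parcel id) of `sbvi_record` data frames with
#'   columns `time`, `Blue`, `Gree`, `Red`, `NIR`, `NDVI`, `Stu`, `BG`,
#'   `pixel_count`.  Parcels covering no pixel are excluded; their ids are
#'   kept in the `"dropped"` attribute and reported via a warning.
#' @export
extract_sbvi <- function(series, parcels, vi_mode = c("per_pixel", "from_means"),
                         buffer = 0) {
  vi_mode <- match.arg(vi_mode)
  stopifnot(length(series) >= 1, inherits(parcels, "parcel_set"))
  ref <- series[[1]]
  tags <- vapply(series, function(s) s$time_tag, character(1))
  if (anyDuplicated(tags)) stop("duplicate time tags in series")
  for (s in series) {
    if (!identical(scene_dim(s), scene_dim(ref)) ||
        !isTRUE(all.equal(s$geotransform, ref$geotransform)) ||
        !identical(s$crs_tag, ref$crs_tag)) {
      stop("misaligned series: scene '", s$time_tag,
           "' differs in grid, geotransform or CRS")
    }
  }
  out <- list()
  dropped <- character()
  for (i in seq_along(parcels$ids)) {
    idx <- parcel_pixel_indices(ref, parcels$polygons[[i]],
                                crs_tag = parcels$crs_tag, buffer = buffer)
    if (nrow(idx) == 0) {
      dropped <- c(dropped, parcels$ids[i])
      next
    }
    lin <- idx[, "row"] + (idx[, "col"] - 1L) * scene_dim(ref)[1]
    rows <- lapply(series, function(s) {
      px <- lapply(s$bands, function(b) b[lin])
      means <- vapply(px, mean, numeric(1))
      vi <- if (vi_mode == "per_pixel") {
        v <- compute_vi(px$Blue, px$Gree, px$Red, px$NIR)
        # pixels whose ratio is undefined (zero denominator) are skipped,
        # as in standard zonal statistics; all-undefined stays missing
        lapply(v, function(z) {
          m <- mean(z, na.rm = TRUE)
          if (is.nan(m)) NA_real_ else m
        })
      } else {
        compute_vi(means["Blue"], means["Gree"], means["Red"], means["NIR"])
      }
      data.frame(time = s$time_tag,
                 Blue = means[["Blue"]], Gree = means[["Gree"]],
                 Red = means[["Red"]], NIR = means[["NIR"]],
                 NDVI = as.numeric(vi$ndvi), Stu = as.numeric(vi$stu),
                 BG = as.numeric(vi$bg),
                 pixel_count = nrow(idx), stringsAsFactors = FALSE)
    })
    out[[parcels$ids[i]]] <- new_sbvi(parcels$ids[i], do.call(rbind, rows),
                                      label = parcels$labels[i])
  }
  if (length(dropped)) {
    warning("parcel(s) with no covered pixel excluded: ",
            paste(dropped, collapse = ", "))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Flatten an SBVI record to named feature values
#'
#' @param record an `sbvi_record` from [extract_sbvi()].
#' @return named numeric vector `T1Blue, T1Gree, ..., TnBG` (time-major).
#' @export
sbvi_features <- function(record) {
  vals <- unlist(lapply(seq_len(nrow(record)), function(i) {
    stats::setNames(as.numeric(record[i, SBVI_VARS]),
                    paste0(record$time[i], SBVI_VARS))
  }))
  vals
}

#' Write / read a per-parcel SBVI file
#'
#' Tab-delimited, one row per acquisition, columns `time`, the four band
#' means, the three indices and `pixel_count`; filename
#' `<parcel_id>.sbvi`.
#'
#' @param record an `sbvi_record`.
#' @param dir output directory.
#' @return the written path, invisibly.
#' @export
write_sbvi <- function(record, dir) {
  path <- file.path(dir, paste0(attr(record, "parcel_id"), ".sbvi"))
  tab <- as.data.frame(record)
  for (v in c(SBVI_VARS)) tab[[v]] <- num17(tab[[v]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sbvi
#' @param path an `.sbvi` file written by `write_sbvi`.
#' @export
read_sbvi <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- c("time", canonicalize_var(names(tab)[-1]))
  new_sbvi(sub("\\.sbvi$", "", basename(path)), tab)
}

#' Assemble the decision-tree matrix
#'
#' Builds the parcels x (7 features x n times) table, columns ordered
#' time-major (`T1Blue ... T1BG, T2Blue, ...`), with one `land_use` label
#' column.
#'
#' @param records list of `sbvi_record`s from [extract_sbvi()].
#' @param labels optional named character vector (parcel id -> land use);
#'   when `NULL`, labels attached to the records are used.  Parcels with
#'   no label get the sentinel `"UNKNOWN"`.
#' @param times_subset subset of the available time tags to keep
#'   (default: all, in record order).
#' @return a data frame of class `cropclass_matrix` with columns
#'   `parcel_id`, the features, `land_use`; attribute `times` holds the
#'   time tags used.  Parcels with any missing feature are dropped with a
#'   warning.
#' @export
build_matrix <- function(records, labels = NULL, times_subset = NULL) {
  stopifnot(length(records) >= 1)
  all_times <- records[[1]]$time
  if (is.null(times_subset)) times_subset <- all_times
  if (!length(times_subset)) stop("times_subset must be non-empty")
  if (!all(times_subset %in% all_times)) {
    stop("times_subset not in series: ",
         paste(setdiff(times_subset, all_times), collapse = ", "))
  }
  cols <- as.vector(t(outer(times_subset, SBVI_VARS, paste0)))
  ids <- vapply(records, function(r) attr(r, "parcel_id"), character(1))
  feats <- t(vapply(records, function(r) {
    sbvi_features(r[match(times_subset, r$time), , drop = FALSE])
  }, numeric(length(cols))))
  colnames(feats) <- cols
  lab <- if (is.null(labels)) {
    vapply(records, function(r) attr(r, "label") %||% NA_character_, character(1))
  } else {
    as.character(labels[ids])
  }
  lab[is.na(lab)] <- "UNKNOWN"
  complete <- stats::complete.cases(feats)
  if (!any(complete)) stop("no complete parcels")
  if (any(!complete)) {
    warning("parcel(s) with missing features dropped: ",
            paste(ids[!complete], collapse = ", "))
  }
  out <- data.frame(parcel_id = ids[complete], feats[complete, , drop = FALSE],
                    land_use = lab[complete],
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, times = times_subset,
            class = c("cropclass_matrix", "data.frame"))
}

#' Feature column names of a matrix
#'
#' @param matrix a `cropclass_matrix`.
#' @return character vector of feature columns (excludes `parcel_id` and
#'   `land_use`).
#' @export
feature_columns <- function(matrix) {
  setdiff(names(matrix), c("parcel_id", "land_use"))
}

#' Restrict a matrix to a subset of acquisition times
#'
#' @param matrix a `cropclass_matrix`.
#' @param times subset of `attr(matrix, "times")`.
#' @return a `cropclass_matrix` with the corresponding feature columns.
#' @export
subset_times <- function(matrix, times) {
  have <- attr(matrix, "times")
  if (!length(times) || !all(times %in% have)) {
    stop("times not present in matrix: ",
         paste(setdiff(times, have), collapse = ", "))
  }
  cols <- as.vector(t(outer(times, SBVI_VARS, paste0)))
  out <- matrix[c("parcel_id", cols, "land_use")]
  structure(out, times = times, class = c("cropclass_matrix", "data.frame"))
}

#' Write / read the matrix-data file
#'
#' Tab-delimited text, UTF-8, '.' decimal separator, header row of column
#' names, one row per parcel.  Thresholds are printed with 17 significant
#' digits so write -> read round-trips exactly.  On read, header aliases
#' (`Green` -> `Gree`, `B/G` -> `BG`, `STU` -> `Stu`) are canonicalized.
#'
#' @param matrix a `cropclass_matrix`.
#' @param path output / input file.
#' @return `write_matrix`: `path` invisibly; `read_matrix`: a
#'   `cropclass_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  tab <- as.data.frame(matrix)
  for (v in feature_columns(matrix)) tab[[v]] <- num17(tab[[v]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty matrix file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 3 || header[1] != "parcel_id" ||
      header[length(header)] != "land_use") {
    stop("malformed header in '", path,
         "': expected parcel_id, features..., land_use")
  }
  fc <- header[-c(1, length(header))]
  m <- regmatches(fc, regexec("^(T[0-9]+)(.+)$", fc))
  bad <- vapply(m, length, integer(1)) == 0
  vars <- vapply(m, function(g) if (length(g)) canonicalize_var(g[3]) else "",
                 character(1))
  if (any(bad) || !all(vars %in% SBVI_VARS)) {
    stop("unknown feature column(s) in '", path, "': ",
         paste(fc[bad | !(vars %in% SBVI_VARS)], collapse = ", "))
  }
  fc <- paste0(vapply(m, `[`, character(1), 2), vars)
  nc <- length(header)
  rows <- cells[-1]
  widths <- vapply(rows, length, integer(1))
  if (any(widths != nc)) {
    stop("ragged row at line ", which(widths != nc)[1] + 1, " in '", path, "'")
  }
  ids <- vapply(rows, `[`, character(1), 1)
  lab <- vapply(rows, `[`, character(1), nc)
  feats <- matrix(NA_real_, length(rows), nc - 2,
                  dimnames = list(NULL, fc))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][2:(nc - 1)]))
    if (anyNA(v)) {
      stop("non-numeric feature at line ", i + 1, " (parcel '", ids[i],
           "') in '", path, "'")
    }
    feats[i, ] <- v
  }
  if (anyDuplicated(ids)) {
    stop("duplicate parcel id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  times <- unique(vapply(m, `[`, character(1), 2))
  out <- data.frame(parcel_id = ids, feats, land_use = lab,
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, times = times, class = c("cropclass_matrix", "data.frame"))
}
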