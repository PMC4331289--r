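# Vegetation indices, SBVI extraction and the matrix-data file.

test_that("vegetation indices follow their defining ratios", {
  vi <- compute_vi(50, 100, 100, 300)
  expect_equal(vi$ndvi, 0.5)
  expect_equal(vi$stu, 1.0)
  expect_equal(vi$bg, 0.5)
  expect_equal(compute_vi(10, 20, 70, 70)$ndvi, 0)      # nir == red
  expect_true(is.na(compute_vi(10, 20, 0, 0)$ndvi))     # 0/0 sentinel
  expect_true(is.na(compute_vi(10, 0, 5, 9)$stu))
  expect_error(compute_vi(-1, 2, 3, 4), "non-negative")
  expect_error(compute_vi(1, 2, Inf, 4), "finite")
})

test_that("NDVI increases strictly with NIR at fixed red", {
  nirs <- seq(10, 1000, by = 15)
  for (red in c(5, 120, 430)) {
    nd <- compute_vi(rep(1, length(nirs)), rep(1, length(nirs)),
                     rep(red, length(nirs)), nirs)$ndvi
    expect_true(all(diff(nd) > 0))
  }
})

test_that("extracted band means match a brute-force per-pixel oracle", {
  scenes <- lapply(1:2, function(k) toy_scene(nr = 30, nc = 30, seed = k,
                                              time_tag = paste0("T", k),
                                              origin = c(0, 60)))
  set.seed(21)
  polys <- lapply(1:20, function(i) {
    x0 <- runif(1, 0, 45); y0 <- runif(1, 0, 45)
    rect_polygon(x0, y0, x0 + runif(1, 3, 14), y0 + runif(1, 3, 14))
  })
  ps <- parcel_set(sprintf("p%02d", 1:20), polys, crs_tag = "toy")
  recs <- suppressWarnings(extract_sbvi(scenes, ps, vi_mode = "from_means"))
  for (id in names(recs)) {
    poly <- polys[[match(id, ps$ids)]]
    for (k in 1:2) {
      oracle <- oracle_zonal_means(scenes[[k]], poly)
      row <- recs[[id]][k, ]
      for (b in c("Blue", "Gree", "Red", "NIR")) {
        expect_equal(row[[b]], oracle[[b]], tolerance = 1e-9)
      }
      expect_equal(row$NDVI, (oracle[["NIR"]] - oracle[["Red"]]) /
                     (oracle[["NIR"]] + oracle[["Red"]]), tolerance = 1e-9)
    }
    # band means bounded by member pixel extremes
    expect_true(all(row[c("Blue", "Gree", "Red", "NIR")] >= 0))
  }
})

test_that("per-pixel and from-means VI modes differ as documented", {
  s <- toy_scene(nr = 10, nc = 10, origin = c(0, 20))
  ps <- parcel_set("p1", list(rect_polygon(0, 10, 10, 20)), crs_tag = "toy")
  rp <- extract_sbvi(list(s), ps, vi_mode = "per_pixel")[["p1"]]
  rm <- extract_sbvi(list(s), ps, vi_mode = "from_means")[["p1"]]
  expect_identical(rp$Blue, rm$Blue)                 # means agree
  expect_false(isTRUE(all.equal(rp$NDVI, rm$NDVI)))  # nonlinear index differs
  # a constant scene makes both modes exact and equal
  const <- raster_scene(list(Blue = matrix(50, 4, 4), Gree = matrix(100, 4, 4),
                             Red = matrix(100, 4, 4), NIR = matrix(300, 4, 4)),
                        c(0, 8, 2, 2), crs_tag = "toy")
  pc <- parcel_set("q", list(rect_polygon(0, 0, 8, 8)), crs_tag = "toy")
  r <- extract_sbvi(list(const), pc)[["q"]]
  expect_equal(r$NDVI, 0.5)
  expect_equal(r$Blue, 50)
  expect_equal(r$pixel_count, 16)
})

test_that("misaligned series and off-raster parcels are handled", {
  s1 <- toy_scene(nr = 10, nc = 10, time_tag = "T1", origin = c(0, 20))
  s2 <- toy_scene(nr = 12, nc = 10, time_tag = "T2", origin = c(0, 20))
  ps <- parcel_set("p1", list(rect_polygon(0, 10, 10, 20)), crs_tag = "toy")
  expect_error(extract_sbvi(list(s1, s2), ps), "misaligned")
  far <- parcel_set(c("in", "out"),
                    list(rect_polygon(0, 10, 10, 20),
                         rect_polygon(500, 500, 510, 510)), crs_tag = "toy")
  expect_warning(recs <- extract_sbvi(list(s1), far), "out")
  expect_identical(names(recs), "in")
  expect_identical(attr(recs, "dropped"), "out")
})

test_that("matrix assembly is time-major with label column and subsets", {
  st <- default_study()
  mat <- build_matrix(st$records)
  expect_equal(length(feature_columns(mat)), 49)   # 7 variables x 7 times
  expect_identical(feature_columns(mat)[1:8],
                   c("T1Blue", "T1Gree", "T1Red", "T1NIR", "T1NDVI",
                     "T1Stu", "T1BG", "T2Blue"))
  expect_identical(names(mat)[ncol(mat)], "land_use")
  sub <- build_matrix(st$records, times_subset = c("T2", "T5"))
  expect_equal(length(feature_columns(sub)), 14)
  # restriction consistency: A-union-B restricted to A equals A directly
  expect_equal(subset_times(mat, c("T2", "T5")), sub, ignore_attr = TRUE)
  expect_error(build_matrix(st$records, times_subset = "T9"), "T9")
  expect_error(build_matrix(st$records, times_subset = character()), "non-empty")
})

test_that("matrix file round-trips and rejects malformed content", {
  st <- default_study()
  mat <- build_matrix(st$records)
  d <- withr::local_tempdir()
  f <- file.path(d, "matrix.tsv")
  write_matrix(mat, f)
  back <- read_matrix(f)
  expect_equal(as.data.frame(back), as.data.frame(mat))
  expect_identical(attr(back, "times"), attr(mat, "times"))

  # header alias B/G and Green are canonicalized
  lines <- readLines(f)
  lines[1] <- gsub("T1BG", "T1B/G", gsub("T2Gree", "T2Green", lines[1]))
  writeLines(lines, f)
  expect_identical(feature_columns(read_matrix(f)), feature_columns(mat))

  writeLines(c("parcel_id\tT1Blue\tland_use", "p1\tabc\tWHT"), f)
  expect_error(read_matrix(f), "non-numeric feature at line 2")
  writeLines(c("parcel_id\tT1Blue\tland_use", "p1\t1"), f)
  expect_error(read_matrix(f), "ragged row at line 2")
  writeLines(c("parcel_id\tT1Bogus\tland_use", "p1\t1\tWHT"), f)
  expect_error(read_matrix(f), "T1Bogus")
})

test_that("sbvi files round-trip per parcel", {
  st <- default_study()
  rec <- st$records[[1]]
  d <- withr::local_tempdir()
  p <- write_sbvi(rec, d)
  expect_identical(basename(p), paste0(attr(rec, "parcel_id"), ".sbvi"))
  back <- read_sbvi(p)
  expect_equal(as.data.frame(back), as.data.frame(rec), ignore_attr = TRUE)
  expect_identical(attr(back, "parcel_id"), attr(rec, "parcel_id"))
})
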