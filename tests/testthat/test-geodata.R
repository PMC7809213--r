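test_that("stack write/read round-trips values, names, transform and mask", {
  mask <- matrix(FALSE, 30, 30); mask[2:5, 8:12] <- TRUE
  st <- gen_climate_stack(30, 30, c("bio4", "bio12", "bio15"), 3, seed = 2,
                          mask = mask)
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_identical(band_names(back), band_names(st))
  expect_identical(back$mask, st$mask)
  expect_equal(unclass(back$transform), unclass(st$transform), tolerance = 1e-12)
  for (b in band_names(st)) {
    expect_lt(max(abs(back$bands[[b]] - st$bands[[b]]), na.rm = TRUE), 1e-6)
  }
})

test_that("single-band files round-trip and bad metadata is rejected", {
  st <- gen_climate_stack(10, 10, "solo", 1, seed = 1)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "solo.tif")
  write_stack(st, path)
  expect_identical(band_names(read_stack(path)), "solo")
  # missing sidecar names the file
  file.remove(paste0(path, ".json"))
  expect_error(read_stack(path), "band-name metadata missing.*solo.tif")
  # duplicate band names in the metadata are rejected
  st2 <- gen_climate_stack(10, 10, c("a", "b"), 1, seed = 1)
  p2 <- file.path(dir, "dup.tif")
  write_stack(st2, p2)
  meta <- jsonlite::read_json(paste0(p2, ".json"), simplifyVector = TRUE)
  meta$band_names <- c("a", "a")
  jsonlite::write_json(meta, paste0(p2, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(read_stack(p2), "duplicate band name")
})

test_that("points map to exactly one cell, with shared edges owned once", {
  tr <- grid_transform(0, 4, 1, 1)
  # interior point, vertical shared edge, horizontal shared edge, corners
  p <- point_to_cell(tr, 4, 4, c(0.5, 1, 0.5, 0, 4), c(3.5, 3.5, 3, 4, 4))
  expect_identical(p$row, c(1L, 1L, 2L, 1L, NA))   # lon 4 is outside [0,4)
  expect_identical(p$col, c(1L, 2L, 1L, 1L, NA))
  # southern edge is exclusive
  expect_true(is.na(point_to_cell(tr, 4, 4, 0.5, 0)$row))
})

test_that("thinning keeps one record per pixel, first in input order", {
  st <- tiny_stack()
  tr <- st$transform
  lon1 <- cell_center_lon(tr, 5); lat1 <- cell_center_lat(tr, 5)
  occ <- occurrence_set(c(lon1, lon1 + tr$dx / 4, lon1 + 2 * tr$dx),
                        c(lat1, lat1 - tr$dy / 4, lat1),
                        c("native", "invaded", "native"))
  thin <- thin_occurrences(occ, st)
  expect_identical(nrow(thin), 2L)
  expect_identical(thin$region_tag[1], "native")  # first duplicate survives
  # identity on all-distinct cells, and idempotence
  distinct <- occurrence_set(cell_center_lon(tr, c(1, 3, 7)),
                             cell_center_lat(tr, c(2, 4, 9)),
                             rep("native", 3))
  expect_equal(thin_occurrences(distinct, st), distinct)
  expect_equal(thin_occurrences(thin, st), thin)
  expect_identical(nrow(thin_occurrences(occ[0, ], st)), 0L)
})

test_that("thinning drops records on nodata cells", {
  mask <- matrix(FALSE, 30, 30); mask[10, 10] <- TRUE
  st <- gen_climate_stack(30, 30, "b", 2, seed = 3, mask = mask)
  occ <- occurrence_set(cell_center_lon(st$transform, c(10, 11)),
                        cell_center_lat(st$transform, c(10, 10)),
                        c("native", "native"))
  expect_identical(nrow(thin_occurrences(occ, st)), 1L)
})

test_that("occurrence CSV round-trips and requires the standard header", {
  occ <- occurrence_set(c(1.5, -3.2), c(40.1, 42.7), c("native", "europe_analogue"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "occ.csv")
  write_occurrences(occ, path)
  expect_equal(read_occurrences(path), occ)
  writeLines("x,y\n1,2", file.path(dir, "bad.csv"))
  expect_error(read_occurrences(file.path(dir, "bad.csv")), "lon")
})

test_that("background sampling is uniform, seeded and bounded by availability", {
  st <- tiny_stack()
  b1 <- sample_background(st, 50, seed = 4)
  b2 <- sample_background(st, 50, seed = 4)
  expect_identical(b1$cells, b2$cells)
  expect_identical(nrow(unique(b1$cells)), 50L)
  # exhaustive draw returns every valid cell
  mask <- matrix(TRUE, 30, 30); mask[1:5, 1:5] <- FALSE
  st2 <- gen_climate_stack(30, 30, "b", 2, seed = 1, mask = mask)
  all25 <- sample_background(st2, 25, seed = 1)
  expect_identical(nrow(unique(all25$cells)), 25L)
  expect_true(all(!st2$mask[cbind(all25$cells$row, all25$cells$col)]))
  expect_error(sample_background(st2, 26, seed = 1), "only 25 valid cells")
})

test_that("per-cell inclusion frequencies are uniform over repeated draws", {
  mask <- matrix(TRUE, 30, 30); mask[1:10, 1:10] <- FALSE  # 100 eligible cells
  st <- gen_climate_stack(30, 30, "b", 2, seed = 1, mask = mask)
  counts <- numeric(900)
  for (i in 1:1000) {
    bs <- sample_background(st, 10, seed = i)
    idx <- (bs$cells$col - 1) * 30 + bs$cells$row
    counts[idx] <- counts[idx] + 1
  }
  eligible <- which(!mask)
  expect_gt(stats::chisq.test(counts[eligible])$p.value, 0.01)
})

test_that("cropping follows the closed cell-center rule", {
  st <- gen_climate_stack(180, 360, "b", 0, seed = 1)  # global 1-degree grid
  gm <- grid_map(st$bands$b, st$transform)
  full <- crop(gm, focal_window(-180, 180, -90, 90))
  expect_equal(full$values, gm$values)
  # the study's focal window: enumerate half-degree centers directly
  win <- focal_window(-20, 50, 27.5, 70)
  lat_centers <- seq(89.5, -89.5, by = -1)
  lon_centers <- seq(-179.5, 179.5, by = 1)
  n_rows <- sum(lat_centers >= 27.5 & lat_centers <= 70)
  n_cols <- sum(lon_centers >= -20 & lon_centers <= 50)
  expect_identical(n_cols, 70L)
  cropped <- crop(gm, win)
  expect_identical(dim(cropped$values), c(n_rows, n_cols))
  # idempotence
  twice <- crop(cropped, win)
  expect_equal(twice$values, cropped$values)
  expect_equal(unclass(twice$transform), unclass(cropped$transform))
  # one-cell window
  one <- crop(gm, focal_window(0.4, 0.6, 0.4, 0.6))
  expect_identical(dim(one$values), c(1L, 1L))
  expect_error(crop(gm, focal_window(200, 210, 0, 1)), "no cell centers")
})

test_that("agreement statistics match direct enumeration on a 4-cell row", {
  tr <- grid_transform(0, 1, 1, 1)
  gm <- grid_map(matrix(c(0, 1, 0.96, 0.5), 1, 4), tr)
  s <- area_stats(gm, weighting = "cell_count")
  expect_equal(s$frac_unanimous_suitable, 0.25)
  expect_equal(s$frac_unanimous_unsuitable, 0.25)
  expect_equal(s$frac_high_agreement, 0.75)
  # cos-latitude weighting equals cell-count weighting on one latitude row
  s2 <- area_stats(gm, weighting = "cos_latitude")
  expect_equal(s2$frac_high_agreement, s$frac_high_agreement)
  expect_equal(s2$frac_unanimous_suitable, s$frac_unanimous_suitable)
})

test_that("agreement statistics handle degenerate consensus values", {
  tr <- grid_transform(0, 2, 1, 1)
  zeros <- area_stats(grid_map(matrix(0, 2, 3), tr), weighting = "cell_count")
  expect_equal(unlist(zeros[3:5], use.names = FALSE), c(0, 1, 1))
  half <- area_stats(grid_map(matrix(0.5, 2, 3), tr), weighting = "cell_count")
  expect_equal(unlist(half[3:5], use.names = FALSE), c(0, 0, 0))
  expect_error(area_stats(grid_map(matrix(NA_real_, 2, 2), tr)), "nodata")
})

test_that("high agreement always contains both unanimity classes", {
  tr <- grid_transform(0, 5, 1, 1)
  for (seed in 1:10) {
    v <- withr::with_seed(seed, matrix(sample(0:8, 25, TRUE) / 8, 5, 5))
    s <- area_stats(grid_map(v, tr), weighting = "cell_count")
    expect_gte(s$frac_high_agreement + 1e-12,
               s$frac_unanimous_suitable + s$frac_unanimous_unsuitable)
  }
})
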