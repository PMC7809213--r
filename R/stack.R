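#' Affine georeference for a north-up grid in geographic coordinates
#'
#' @param xmin western edge (degrees longitude).
#' @param ymax northern edge (degrees latitude).
#' @param dx,dy cell size in degrees (both positive; row 1 is northernmost).
#' @return A `grid_transform` object.
#' @export
grid_transform <- function(xmin, ymax, dx, dy) {
  if (!(dx > 0 && dy > 0)) stopf("cell size must be positive (dx=%g, dy=%g)", dx, dy)
  structure(list(xmin = xmin, ymax = ymax, dx = dx, dy = dy),
            class = "grid_transform")
}

#' @export
format.grid_transform <- function(x, ...) {
  sprintf("grid_transform: origin (%g, %g), cell %g x %g deg", x$xmin, x$ymax, x$dx, x$dy)
}

#' @export
print.grid_transform <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Longitude/latitude of cell centers
#'
#' @param transform a [grid_transform()].
#' @param rows,cols integer row/column indices (1-based; row 1 northernmost).
#' @return Numeric vector of center coordinates.
#' @export
cell_center_lon <- function(transform, cols) transform$xmin + (cols - 0.5) * transform$dx

#' @rdname cell_center_lon
#' @export
cell_center_lat <- function(transform, rows) transform$ymax - (rows - 0.5) * transform$dy

#' Map points to grid cells
#'
#' Cells are half-open: a cell owns longitudes `[x, x + dx)` and latitudes
#' `(y - dy, y]`, so a point exactly on a shared edge belongs to exactly one
#' cell (the cell to its east, and the cell below whose top edge it sits on).
#' A point on the grid's northern edge belongs to row 1.
#'
#' @param transform a [grid_transform()].
#' @param nrow,ncol grid dimensions.
#' @param lon,lat point coordinates (degrees).
#' @return A data.frame with columns `row`, `col`; `NA` for points outside
#'   the grid extent.
#' @export
point_to_cell <- function(transform, nrow, ncol, lon, lat) {
  col <- floor((lon - transform$xmin) / transform$dx) + 1
  # cells are top-inclusive in latitude: (y - dy, y]; floor(drow) + 1 maps the
  # northern grid edge to row 1 and each shared horizontal edge to the cell below
  drow <- (transform$ymax - lat) / transform$dy
  row <- floor(drow) + 1
  bad <- col < 1 | col > ncol | row < 1 | row > nrow | is.na(lon) | is.na(lat)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Single-band georeferenced grid
#'
#' A lightweight raster: a numeric matrix (NA marks nodata) plus a
#' [grid_transform()]. Suitability maps, binary maps and consensus layers are
#' all `grid_map`s.
#'
#' @param values numeric matrix; `NA` = nodata.
#' @param transform a [grid_transform()].
#' @return A `grid_map` object.
#' @export
grid_map <- function(values, transform) {
  stopifnot(is.matrix(values), inherits(transform, "grid_transform"))
  structure(list(values = values, transform = transform), class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("grid_map: %d x %d cells, %d valid\n", nrow(x$values),
              ncol(x$values), sum(!is.na(x$values))))
  cat(" ", format(x$transform), "\n")
  invisible(x)
}

#' Multi-band climate raster stack
#'
#' Holds named 2-D grids of climate values sharing one georeference and one
#' nodata mask. Band names must be unique; all bands must share the same
#' `NA` pattern.
#'
#' @param bands named list of numeric matrices (NA = nodata).
#' @param transform a [grid_transform()].
#' @return A `climate_stack` object.
#' @export
climate_stack <- function(bands, transform) {
  if (length(bands) == 0) stopf("a climate stack needs at least one band")
  nm <- names(bands)
  if (is.null(nm) || any(nm == "")) stopf("all bands must be named")
  if (anyDuplicated(nm)) {
    stopf("duplicate band name: %s", nm[duplicated(nm)][1])
  }
  d <- dim(bands[[1]])
  for (b in nm) {
    if (!identical(dim(bands[[b]]), d)) stopf("band '%s' has mismatched dimensions", b)
  }
  mask <- is.na(bands[[1]])
  for (b in nm[-1]) {
    if (!identical(is.na(bands[[b]]), mask)) {
      stopf("band '%s' has a different nodata pattern than band '%s'", b, nm[1])
    }
  }
  structure(list(bands = bands, transform = transform, mask = mask),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d band(s) [%s], %d x %d cells, %d valid\n",
              length(x$bands), paste(names(x$bands), collapse = ", "),
              nrow(x$mask), ncol(x$mask), sum(!x$mask)))
  cat(" ", format(x$transform), "\n")
  invisible(x)
}

#' Band names of a climate stack
#' @param stack a [climate_stack()].
#' @export
band_names <- function(stack) names(stack$bands)

#' @export
dim.climate_stack <- function(x) dim(x$mask)

#' Extract raw band values at grid cells
#'
#' @param stack a [climate_stack()].
#' @param cells data.frame with `row`, `col` columns.
#' @param bands character vector of band names (default: all).
#' @return Numeric matrix, one row per cell, one named column per band.
#' @export
cell_values <- function(stack, cells, bands = band_names(stack)) {
  missing <- setdiff(bands, band_names(stack))
  if (length(missing)) stopf("band '%s' not present in the stack", missing[1])
  idx <- cbind(cells$row, cells$col)
  out <- vapply(bands, function(b) stack$bands[[b]][idx], numeric(nrow(cells)))
  if (nrow(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, bands))
  out
}

#' Rectangular focal window in geographic coordinates
#'
#' @param lon_min,lon_max,lat_min,lat_max window bounds (degrees).
#' @return A `focal_window` object.
#' @export
focal_window <- function(lon_min, lon_max, lat_min, lat_max) {
  if (!(lon_min < lon_max)) stopf("lon_min must be < lon_max")
  if (!(lat_min < lat_max)) stopf("lat_min must be < lat_max")
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max), class = "focal_window")
}

window_rowcols <- function(transform, nr, nc, window) {
  lons <- cell_center_lon(transform, seq_len(nc))
  lats <- cell_center_lat(transform, seq_len(nr))
  cols <- which(lons >= window$lon_min & lons <= window$lon_max)
  rows <- which(lats >= window$lat_min & lats <= window$lat_max)
  if (!length(rows) || !length(cols)) {
    stopf("focal window [%g, %g] x [%g, %g] contains no cell centers",
          window$lon_min, window$lon_max, window$lat_min, window$lat_max)
  }
  list(rows = rows, cols = cols)
}

#' Crop a raster to a focal window
#'
#' Keeps exactly the cells whose centers fall inside the closed window; the
#' georeference of the result is updated accordingly. Cropping twice with the
#' same window is idempotent.
#'
#' @param x a [grid_map()] or [climate_stack()].
#' @param window a [focal_window()].
#' @return Object of the same class as `x`.
#' @export
crop <- function(x, window) UseMethod("crop")

#' @export
crop.grid_map <- function(x, window) {
  rc <- window_rowcols(x$transform, nrow(x$values), ncol(x$values), window)
  tr <- grid_transform(x$transform$xmin + (min(rc$cols) - 1) * x$transform$dx,
                       x$transform$ymax - (min(rc$rows) - 1) * x$transform$dy,
                       x$transform$dx, x$transform$dy)
  grid_map(x$values[rc$rows, rc$cols, drop = FALSE], tr)
}

#' @export
crop.climate_stack <- function(x, window) {
  rc <- window_rowcols(x$transform, nrow(x$mask), ncol(x$mask), window)
  tr <- grid_transform(x$transform$xmin + (min(rc$cols) - 1) * x$transform$dx,
                       x$transform$ymax - (min(rc$rows) - 1) * x$transform$dy,
                       x$transform$dx, x$transform$dy)
  climate_stack(lapply(x$bands, function(m) m[rc$rows, rc$cols, drop = FALSE]), tr)
}

#' Write / read a climate stack
#'
#' The on-disk form is a multi-page 32-bit TIFF (one page per band, each band
#' min-max scaled to `[0, 1]`, nodata stored as 0 under the mask) plus a JSON
#' sidecar `<path>.json` carrying band names, per-band value ranges, the
#' affine transform and the nodata mask location. The round trip preserves
#' values to well below 1e-6 of the band range.
#'
#' @param stack a [climate_stack()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns a
#'   [climate_stack()].
#' @export
write_stack <- function(stack, path) {
  nm <- band_names(stack)
  rng <- lapply(nm, function(b) {
    v <- stack$bands[[b]][!stack$mask]
    if (!length(v)) c(0, 1) else range(v)
  })
  pages <- lapply(seq_along(nm), function(i) {
    v <- stack$bands[[nm[i]]]
    lo <- rng[[i]][1]; hi <- rng[[i]][2]
    s <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
    s[is.na(s)] <- 0
    s
  })
  pages <- c(pages, list(1 - stack$mask * 1))  # final page: validity mask
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    band_names = nm,
    band_min = vapply(rng, `[`, 0, 1),
    band_max = vapply(rng, `[`, 0, 2),
    transform = unclass(stack$transform),
    nrow = nrow(stack$mask), ncol = ncol(stack$mask),
    nodata = "mask page appended as last TIFF page (1 = valid)")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("raster file not found: %s", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    stopf("band-name metadata missing for %s (expected sidecar %s)", path, side)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$band_names) || !length(meta$band_names)) {
    stopf("band-name metadata missing in %s", side)
  }
  if (anyDuplicated(meta$band_names)) {
    stopf("duplicate band name in %s: %s", side,
          meta$band_names[duplicated(meta$band_names)][1])
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  nb <- length(meta$band_names)
  if (length(pages) != nb + 1) {
    stopf("%s holds %d pages but the sidecar names %d bands (+1 mask page)",
          path, length(pages), nb)
  }
  mask <- pages[[nb + 1]] < 0.5
  bands <- lapply(seq_len(nb), function(i) {
    lo <- meta$band_min[i]; hi <- meta$band_max[i]
    v <- pages[[i]]
    v <- if (hi > lo) v * (hi - lo) + lo else v + lo
    v[mask] <- NA_real_
    v
  })
  names(bands) <- meta$band_names
  tr <- grid_transform(meta$transform$xmin, meta$transform$ymax,
                       meta$transform$dx, meta$transform$dy)
  climate_stack(bands, tr)
}

#' Area-weighted agreement statistics of a consensus map
#'
#' Computes, over valid cells, the fraction unanimously predicted suitable
#' (consensus exactly 1), unanimously unsuitable (exactly 0), and the
#' high-agreement fraction (consensus `< 0.05` or `> 0.95`, i.e. at least
#' 95\% of models agree). Fractions are weighted either by plain cell count
#' or by the cosine of the cell-center latitude (cells shrink poleward at
#' fixed angular resolution); on a single-latitude-row raster the two
#' weightings coincide.
#'
#' @param consensus a [consensus_map()] or a [grid_map()] of values in
#'   `[0, 1]`.
#' @param window optional [focal_window()]; `NULL` = full extent.
#' @param weighting `"cos_latitude"` (default) or `"cell_count"`.
#' @param high_agreement half-width of the agreement band (default 0.95).
#' @return A one-row data.frame with the three fractions plus `scope` and
#'   `weighting` descriptors.
#' @export
area_stats <- function(consensus, window = NULL,
                       weighting = c("cos_latitude", "cell_count"),
                       high_agreement = 0.95) {
  weighting <- match.arg(weighting)
  gm <- if (inherits(consensus, "consensus_map")) consensus$mean else consensus
  if (!inherits(gm, "grid_map")) stopf("consensus must be a grid_map or consensus_map")
  if (!is.null(window)) gm <- crop(gm, window)
  v <- gm$values
  valid <- !is.na(v)
  if (!any(valid)) stopf("all cells are nodata in the requested scope")
  if (any(v[valid] < 0 | v[valid] > 1)) stopf("consensus values must lie in [0, 1]")
  w <- if (weighting == "cos_latitude") {
    matrix(cos(cell_center_lat(gm$transform, seq_len(nrow(v))) * pi / 180),
           nrow(v), ncol(v))
  } else {
    matrix(1, nrow(v), ncol(v))
  }
  wv <- w[valid]
  tot <- sum(wv)
  vv <- v[valid]
  data.frame(
    scope = if (is.null(window)) "global" else "focal",
    weighting = weighting,
    frac_unanimous_suitable = sum(wv[vv == 1]) / tot,
    frac_unanimous_unsuitable = sum(wv[vv == 0]) / tot,
    frac_high_agreement = sum(wv[vv < 1 - high_agreement | vv > high_agreement]) / tot,
    stringsAsFactors = FALSE)
}
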