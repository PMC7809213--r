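#' Occurrence records with region tags
#'
#' @param lon,lat coordinates in degrees (WGS84).
#' @param region_tag character labels (e.g. `"native"`, `"invaded"`,
#'   `"europe_analogue"`).
#' @param vocabulary optional declared tag vocabulary; tags outside it are
#'   rejected.
#' @return A data.frame of class `occurrence_set` with columns `lon`, `lat`,
#'   `region_tag`.
#' @export
occurrence_set <- function(lon, lat, region_tag, vocabulary = NULL) {
  if (length(lon) != length(lat) || length(lon) != length(region_tag)) {
    stopf("lon, lat and region_tag must have equal length")
  }
  if (length(lon) && (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))) {
    stopf("coordinates outside [-180, 180] x [-90, 90]")
  }
  if (!is.null(vocabulary) && length(region_tag) &&
      !all(region_tag %in% vocabulary)) {
    stopf("unknown region tag: %s", setdiff(region_tag, vocabulary)[1])
  }
  structure(data.frame(lon = as.numeric(lon), lat = as.numeric(lat),
                       region_tag = as.character(region_tag),
                       stringsAsFactors = FALSE),
            class = c("occurrence_set", "data.frame"))
}

#' Read / write occurrence CSV
#'
#' The CSV must carry a `lon, lat, region_tag` header.
#'
#' @param path CSV file path.
#' @param occ an [occurrence_set()].
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stopf("occurrence file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "region_tag")
  if (!all(need %in% names(d))) {
    stopf("%s lacks required column(s): %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  }
  occurrence_set(d$lon, d$lat, d$region_tag)
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("lon", "lat", "region_tag")], path, row.names = FALSE)
  invisible(path)
}

#' Thin occurrences to one record per raster cell
#'
#' Keeps the first record (in input order) falling in each cell of the
#' climate raster; records outside the raster extent or on nodata cells are
#' dropped. Thinning is idempotent.
#'
#' @param occ an [occurrence_set()].
#' @param stack a [climate_stack()].
#' @return An [occurrence_set()] with at most one record per cell.
#' @export
thin_occurrences <- function(occ, stack) {
  if (nrow(occ) == 0) return(occ)
  d <- dim(stack)
  rc <- point_to_cell(stack$transform, d[1], d[2], occ$lon, occ$lat)
  inside <- !is.na(rc$row)
  onland <- inside
  onland[inside] <- !stack$mask[cbind(rc$row[inside], rc$col[inside])]
  cellid <- ifelse(onland, (rc$row - 1) * d[2] + rc$col, NA_integer_)
  keep <- onland & !duplicated(cellid)
  occurrence_set(occ$lon[keep], occ$lat[keep], occ$region_tag[keep])
}

#' Sample background cells uniformly
#'
#' Draws `n` distinct valid cells uniformly at random within an extent mask,
#' emulating the random generation of background points over a wide area
#' representative of the species' habitat.
#'
#' @param stack a [climate_stack()].
#' @param n number of background cells.
#' @param extent_mask optional logical matrix (TRUE = eligible); `NULL` means
#'   the whole valid extent.
#' @param seed integer seed; the draw is reproducible.
#' @param extent_spec free-text description of the sampling region.
#' @return A `background_sample`: list with `cells` (data.frame `row`, `col`),
#'   `n` and `extent_spec`.
#' @export
sample_background <- function(stack, n, extent_mask = NULL, seed = 1L,
                              extent_spec = "full valid extent") {
  eligible <- !stack$mask
  if (!is.null(extent_mask)) {
    stopifnot(identical(dim(extent_mask), dim(stack$mask)))
    eligible <- eligible & extent_mask
  }
  idx <- which(eligible)
  if (length(idx) < n) {
    stopf("requested %d background cells but only %d valid cells are available",
          n, length(idx))
  }
  picked <- withr::with_seed(seed, sample(idx, n, replace = FALSE))
  d <- dim(stack$mask)
  structure(list(
    cells = data.frame(row = ((picked - 1) %% d[1]) + 1,
                       col = ((picked - 1) %/% d[1]) + 1),
    n = n, extent_spec = extent_spec, seed = seed),
    class = "background_sample")
}

#' @export
print.background_sample <- function(x, ...) {
  cat(sprintf("background_sample: %d cells (%s)\n", x$n, x$extent_spec))
  invisible(x)
}
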