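#' @title Synthetic climate and virtual-species generators
#' @description Generators for spatially autocorrelated, inter-correlated
#'   climate bands, pseudo-GCM future scenarios, and virtual species with a
#'   known logistic response, so the full screening/projection pipeline can
#'   be exercised end to end without external climate or occurrence data.
#' @name synthetic
NULL

# Gaussian smoothing of a matrix with edge renormalization; sigma in cells.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  sm1 <- function(v) {
    n <- length(v)
    num <- stats::convolve(c(numeric(r), v, numeric(r)), k, type = "filter")
    den <- stats::convolve(c(numeric(r), rep(1, n), numeric(r)), k, type = "filter")
    num / den
  }
  m <- t(apply(m, 1, sm1))
  t(apply(t(m), 1, sm1))
}

#' Generate a synthetic multi-band climate stack
#'
#' Each band is the sum of shared large-scale latitudinal and longitudinal
#' gradients (with band-specific random weights, inducing pairwise
#' correlation between bands) and a Gaussian random field obtained by
#' smoothing white noise with a kernel of width `correlation_length` cells.
#' The result is georeferenced (WGS84, north-up, cell-center registration)
#' and bit-for-bit reproducible under `seed`.
#'
#' @param rows,cols grid size (each at least 8).
#' @param band_names unique band names.
#' @param correlation_length spatial correlation length of the noise field,
#'   in cells; 0 gives white noise.
#' @param seed integer seed.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in degrees; the default
#'   covers the globe.
#' @param noise_sd standard deviation of the autocorrelated noise component
#'   relative to the unit-variance gradient components.
#' @param mask optional logical matrix (TRUE = nodata) applied to all bands.
#' @param noise_only band names whose gradient weights are set to zero, so
#'   they are pure autocorrelated noise, uncorrelated with the other bands
#'   (useful as negative-control predictors).
#' @return A [climate_stack()].
#' @export
gen_climate_stack <- function(rows, cols, band_names, correlation_length = 6,
                              seed = 1L, extent = c(-180, 180, -90, 90),
                              noise_sd = 1, mask = NULL,
                              noise_only = character()) {
  if (rows < 8 || cols < 8) stopf("grid must be at least 8 x 8 (got %d x %d)", rows, cols)
  if (!length(band_names)) stopf("band_names must be non-empty")
  if (anyDuplicated(band_names)) {
    stopf("duplicate band name: %s", band_names[duplicated(band_names)][1])
  }
  lat_g <- matrix(seq(1, -1, length.out = rows), rows, cols)
  lon_g <- matrix(seq(-1, 1, length.out = cols), rows, cols, byrow = TRUE)
  bands <- withr::with_seed(seed, {
    lapply(seq_along(band_names), function(i) {
      a <- stats::rnorm(1); b <- stats::rnorm(1)
      if (band_names[i] %in% noise_only) a <- b <- 0
      z <- gauss_smooth(matrix(stats::rnorm(rows * cols), rows, cols),
                        correlation_length)
      z <- z / stats::sd(z)
      off <- stats::runif(1, -2, 2)
      off + a * lat_g + b * lon_g + noise_sd * z
    })
  })
  names(bands) <- band_names
  if (!is.null(mask)) bands <- lapply(bands, function(m) { m[mask] <- NA_real_; m })
  tr <- grid_transform(extent[1], extent[4],
                       (extent[2] - extent[1]) / cols,
                       (extent[4] - extent[3]) / rows)
  climate_stack(bands, tr)
}

#' Pseudo-GCM scenario perturbation
#'
#' A smooth per-band offset field standing in for one global circulation
#' model's projected climate change. The spatial pattern depends only on
#' `(gcm_code, seed)`; the representative concentration pathway (RCP) and
#' horizon year only scale its amplitude, so for a fixed GCM the offset
#' magnitude is strictly increasing in radiative forcing (2.6 < 4.5 < 6.0 <
#' 8.5 W/m2) and from 2050 to 2070.
#'
#' @param gcm_code short GCM label (e.g. `"BC"`, `"CC"`).
#' @param rcp one of 2.6, 4.5, 6.0, 8.5.
#' @param year one of 2050, 2070.
#' @param template a [climate_stack()] giving grid and band names.
#' @param correlation_length smoothing length of the offset pattern (cells).
#' @param base_amplitude mean absolute offset (band units) at RCP 8.5 / 2070.
#' @param seed integer seed shared across scenarios of one synthetic study.
#' @return A `scenario_perturbation` with per-band offset matrices.
#' @export
scenario_perturbation <- function(gcm_code, rcp, year, template,
                                  correlation_length = 8, base_amplitude = 1,
                                  seed = 1L) {
  if (!rcp %in% c(2.6, 4.5, 6.0, 8.5)) stopf("rcp must be one of 2.6, 4.5, 6.0, 8.5")
  if (!year %in% c(2050, 2070)) stopf("year must be 2050 or 2070")
  d <- dim(template)
  pattern_seed <- derive_seed(seed, "gcm_pattern", gcm_code)
  patterns <- withr::with_seed(pattern_seed, {
    lapply(band_names(template), function(b) {
      z <- gauss_smooth(matrix(stats::rnorm(d[1] * d[2]), d[1], d[2]),
                        correlation_length)
      z / mean(abs(z))  # unit mean absolute offset
    })
  })
  names(patterns) <- band_names(template)
  amplitude <- base_amplitude * (rcp / 8.5) * ((year - 2030) / 40)
  offsets <- lapply(patterns, function(p) amplitude * p)
  structure(list(gcm_code = gcm_code, rcp = rcp, year = year,
                 amplitude = amplitude, offsets = offsets, seed = seed),
            class = "scenario_perturbation")
}

#' Apply a scenario perturbation to the current climate
#'
#' Adds the perturbation's per-band offsets to the current stack; grid,
#' band names and nodata mask are unchanged.
#'
#' @param current a [climate_stack()].
#' @param pert a [scenario_perturbation()] built on the same grid.
#' @return A [climate_stack()] of projected climate.
#' @export
gen_future_stack <- function(current, pert) {
  stopifnot(inherits(pert, "scenario_perturbation"))
  if (!identical(dim(pert$offsets[[1]]), dim(current))) {
    stopf("perturbation grid (%s) does not match the current stack (%s)",
          paste(dim(pert$offsets[[1]]), collapse = "x"),
          paste(dim(current), collapse = "x"))
  }
  missing <- setdiff(band_names(current), names(pert$offsets))
  if (length(missing)) stopf("perturbation lacks offsets for band '%s'", missing[1])
  bands <- lapply(band_names(current),
                  function(b) current$bands[[b]] + pert$offsets[[b]])
  names(bands) <- band_names(current)
  climate_stack(bands, current$transform)
}

#' Define a virtual species with a logistic climate response
#'
#' Suitability is the inverse logit of a linear predictor over standardized
#' driver-band values; standardization constants (mean/SD over valid cells)
#' are taken from the supplied current-climate stack and stored, so that
#' projecting onto a future stack reuses them exactly as a fitted model
#' would.
#'
#' @param stack the current-climate [climate_stack()].
#' @param driver_bands band names that truly affect suitability.
#' @param coefficients numeric weights, one per driver band, on the
#'   standardized scale.
#' @param intercept intercept of the linear predictor.
#' @param seed integer stored for provenance (the surface is deterministic
#'   given the stack).
#' @return A `virtual_species`, including its suitability [grid_map()].
#' @export
gen_virtual_species <- function(stack, driver_bands, coefficients,
                                intercept = 0, seed = 1L) {
  missing <- setdiff(driver_bands, band_names(stack))
  if (length(missing)) stopf("unknown driver band: %s", missing[1])
  if (length(coefficients) != length(driver_bands)) {
    stopf("need one coefficient per driver band (%d vs %d)",
          length(coefficients), length(driver_bands))
  }
  means <- vapply(driver_bands, function(b) mean(stack$bands[[b]], na.rm = TRUE), 0)
  sds <- vapply(driver_bands, function(b) stats::sd(stack$bands[[b]], na.rm = TRUE), 0)
  sds[sds == 0] <- 1
  vs <- structure(list(driver_bands = driver_bands,
                       coefficients = stats::setNames(coefficients, driver_bands),
                       intercept = intercept, means = means, sds = sds,
                       seed = seed),
                  class = "virtual_species")
  vs$suitability <- vs_suitability(vs, stack)
  vs
}

#' Suitability surface of a virtual species on a climate stack
#'
#' Uses the standardization constants stored in the species (from the
#' current climate), so future stacks are evaluated on the original scale.
#'
#' @param vs a [gen_virtual_species()] object.
#' @param stack a [climate_stack()] containing all driver bands.
#' @return A [grid_map()] with values in `[0, 1]`, `NA` under the mask.
#' @export
vs_suitability <- function(vs, stack) {
  missing <- setdiff(vs$driver_bands, band_names(stack))
  if (length(missing)) stopf("stack lacks driver band: %s", missing[1])
  eta <- matrix(vs$intercept, nrow(stack$mask), ncol(stack$mask))
  for (b in vs$driver_bands) {
    eta <- eta + vs$coefficients[[b]] * (stack$bands[[b]] - vs$means[[b]]) / vs$sds[[b]]
  }
  grid_map(stats::plogis(eta), stack$transform)
}

#' Sample virtual-species occurrences
#'
#' Draws `n` distinct cells with probability proportional to suitability
#' within a region mask, placing each record at its cell center (so
#' per-pixel thinning behaviour is exactly predictable).
#'
#' @param vs a virtual species.
#' @param n number of occurrence records.
#' @param region_mask optional logical matrix (TRUE = inside the region);
#'   `NULL` means the full valid extent.
#' @param region_tag tag for the sampled records.
#' @param seed integer seed.
#' @return An [occurrence_set()].
#' @export
sample_occurrences <- function(vs, n, region_mask = NULL,
                               region_tag = "native", seed = 1L) {
  suit <- vs$suitability$values
  eligible <- !is.na(suit) & suit > 0
  if (!is.null(region_mask)) eligible <- eligible & region_mask
  idx <- which(eligible)
  if (length(idx) < n) {
    stopf("requested %d occurrences but only %d cells with positive suitability are available",
          n, length(idx))
  }
  picked <- idx[withr::with_seed(
    seed, sample.int(length(idx), n, replace = FALSE, prob = suit[idx]))]
  tr <- vs$suitability$transform
  nr <- nrow(suit)
  row <- ((picked - 1) %% nr) + 1
  col <- ((picked - 1) %/% nr) + 1
  occurrence_set(cell_center_lon(tr, col), cell_center_lat(tr, row),
                 rep(region_tag, n))
}
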