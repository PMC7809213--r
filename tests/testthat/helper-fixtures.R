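# Small fixtures shared across tests; everything is generated in code.

# 30 x 30, 5-band stack with two "driver" bands and one pure-noise band.
tiny_stack <- function(seed = 11, rows = 30, cols = 30,
                       bands = c("tmax", "prec", "seas", "wet", "noise")) {
  gen_climate_stack(rows, cols, bands, correlation_length = 3, seed = seed,
                    noise_only = intersect("noise", bands))
}

tiny_species <- function(stack, coef = c(6, 4), intercept = -8) {
  gen_virtual_species(stack, c("tmax", "prec"), coef, intercept, seed = 1)
}

# Stack + species + thinned occurrences + background, sized for fast fits.
tiny_world <- function(seed = 11, n_occ = 80, n_bg = 400, n_holdout = 10) {
  st <- tiny_stack(seed)
  vs <- tiny_species(st)
  win <- pick_analogue_window(vs, 0.2)
  occ_n <- sample_occurrences(vs, n_occ, !win$mask, "native",
                              seed = derive_seed(seed, "occ"))
  occ_h <- sample_occurrences(vs, n_holdout, win$mask, "europe_analogue",
                              seed = derive_seed(seed, "hold"))
  occ <- occurrence_set(c(occ_n$lon, occ_h$lon), c(occ_n$lat, occ_h$lat),
                        c(occ_n$region_tag, occ_h$region_tag))
  occ <- thin_occurrences(occ, st)
  bg <- sample_background(st, n_bg, seed = derive_seed(seed, "bg"))
  list(stack = st, vs = vs, window = win, occ = occ, background = bg)
}

# A fast configuration for pipeline-level tests.
tiny_config <- function(master_seed = 5, ...) {
  run_config(master_seed = master_seed,
             rows = 30, cols = 30,
             band_names = c("tmax", "prec", "seas", "wet", "dry"),
             correlation_length = 3,
             driver_bands = c("tmax", "prec"),
             driver_coefficients = c(6, 4), driver_intercept = -8,
             n_native = 80, n_holdout = 6, analogue_frac = 0.1,
             gcms = c("BC", "CC"), rcps = c(2.6, 8.5), years = 2070,
             background_n = 300, replicates = 3,
             gates = list(auc_screen = 0.8, tss_screen = 0.6, min_passing = 2,
                          auc_final = 0.7, high_agreement = 0.95),
             subset_sizes = 4,
             screen_classes = c("linear", "quadratic"), knots = 5,
             multipliers = 1, tune_class_sets = c("L", "LQ"),
             ...)
}

cells_of <- function(occ, stack) {
  d <- dim(stack)
  point_to_cell(stack$transform, d[1], d[2], occ$lon, occ$lat)
}
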