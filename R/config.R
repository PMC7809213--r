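#' Run configuration
#'
#' One declarative object governs every stage: the synthetic study design,
#' the screening and retention gates, the tuning grids, the focal window and
#' the master seed. Gate defaults are the original study's values
#' (screening AUC > 0.8, TSS > 0.6, omission 0 with at least 5 of 10
#' replicates passing; final AUC > 0.7; 95\% agreement band), and every
#' stochastic stage derives its seed from the single `master_seed`.
#'
#' @param master_seed integer master seed for the whole run.
#' @param ... named overrides of any default listed below.
#' @return A `run_config` (named list).
#' @export
run_config <- function(master_seed = 1L, ...) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    # synthetic study design
    rows = 100, cols = 100,
    band_names = c("bio4", "bio8", "bio9", "bio10", "bio11", "bio12",
                   "bio15", "bio16", "bio17", "bio18", "bio19"),
    correlation_length = 6,
    driver_bands = c("bio10", "bio12"),
    driver_coefficients = c(8, 6),
    driver_intercept = -12,
    n_native = 200, n_holdout = 15,
    analogue_frac = 0.12,          # analogue window edge, as fraction of grid
    gcms = c("BC", "CC", "GS", "HD", "HE", "IP", "MC", "MG", "MI", "MR", "NO"),
    rcps = c(2.6, 4.5, 6.0, 8.5),
    years = c(2050, 2070),
    perturbation_amplitude = 1,
    perturbation_length = 8,
    # occurrence / background handling
    holdout_tag = "europe_analogue",
    background_n = 10000,
    # screening and final gates
    gates = list(auc_screen = 0.8, tss_screen = 0.6, min_passing = 5,
                 auc_final = 0.7, high_agreement = 0.95),
    replicates = 10,
    subset_sizes = c(4, 5),
    subset_bands = NULL,           # NULL = all band_names
    # model settings
    screen_classes = c("linear", "quadratic", "hinge"),
    screen_multiplier = 1,
    knots = 30,
    output_scale = "cloglog",
    multipliers = seq(0.5, 4, by = 0.5),
    tune_class_sets = names(feature_class_sets()),
    tune_occurrences = "non_holdout",
    tol = 1e-7, maxit = 500,
    # reporting
    focal = list(lon_min = -20, lon_max = 50, lat_min = 27.5, lat_max = 70),
    weighting = "cos_latitude")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopc("config_error", "unknown config field: %s", unknown[1])
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

stopc <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

#' Validate a run configuration
#'
#' Checks that every gate lies in its metric's range and that grid and
#' count fields are positive; raises a `config_error` naming the offending
#' field otherwise.
#'
#' @param config a [run_config()].
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  g <- config$gates
  chk <- function(ok, field) {
    if (!isTRUE(ok)) stopc("config_error", "invalid config value for '%s'", field)
  }
  chk(g$auc_screen >= 0 && g$auc_screen <= 1, "gates.auc_screen")
  chk(g$tss_screen >= -1 && g$tss_screen <= 1, "gates.tss_screen")
  chk(g$auc_final >= 0 && g$auc_final <= 1, "gates.auc_final")
  chk(g$min_passing >= 0 && g$min_passing <= config$replicates, "gates.min_passing")
  chk(g$high_agreement > 0.5 && g$high_agreement <= 1, "gates.high_agreement")
  chk(config$replicates >= 1, "replicates")
  chk(config$background_n >= 1, "background_n")
  chk(config$rows >= 8 && config$cols >= 8, "rows/cols")
  chk(config$screen_multiplier > 0, "screen_multiplier")
  chk(all(config$driver_bands %in% config$band_names), "driver_bands")
  chk(config$output_scale %in% c("cloglog", "logistic", "raw"), "output_scale")
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' `read_config` layers the file's fields over the defaults of
#' [run_config()]; parse, serialize, parse is the identity.
#'
#' @param path YAML file path.
#' @param config a [run_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopc("config_error", "config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  base <- run_config()
  for (nm in names(vals)) {
    if (!nm %in% names(base)) stopc("config_error", "unknown config field: %s", nm)
    if (nm == "gates") base$gates[names(vals$gates)] <- vals$gates
    else if (nm == "focal") base$focal[names(vals$focal)] <- vals$focal
    else base[nm] <- list(vals[[nm]])  # list() form keeps explicit NULLs
  }
  validate_config(base)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Apply `key=value` overrides to a configuration
#'
#' Dotted keys reach nested fields (`gates.auc_screen=0.9`); values are
#' parsed as YAML scalars.
#'
#' @param config a [run_config()].
#' @param overrides character vector of `key=value` strings.
#' @return The updated configuration (validated).
#' @export
config_override <- function(config, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopc("config_error", "malformed override '%s'", ov)
    val <- yaml::yaml.load(kv[2])
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    if (length(keys) == 1) {
      if (!keys %in% names(config)) stopc("config_error", "unknown config field: %s", keys)
      config[[keys]] <- val
    } else if (length(keys) == 2) {
      if (!keys[1] %in% names(config) || !keys[2] %in% names(config[[keys[1]]])) {
        stopc("config_error", "unknown config field: %s", kv[1])
      }
      config[[keys[1]]][[keys[2]]] <- val
    } else {
      stopc("config_error", "override key too deep: %s", kv[1])
    }
  }
  validate_config(config)
}

#' Append a machine-parsable entry to the run log
#'
#' @param out_dir run output directory.
#' @param stage stage name.
#' @param ... named values recorded as `key=value` fields.
#' @export
append_log <- function(out_dir, stage, ...) {
  kv <- list(...)
  line <- paste(c(sprintf("time=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                  sprintf("stage=%s", stage),
                  sprintf("%s=%s", names(kv), vapply(kv, as.character, ""))),
                collapse = " ")
  cat(line, "\n", sep = "", file = file.path(out_dir, "run.log"), append = TRUE)
  invisible(line)
}
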