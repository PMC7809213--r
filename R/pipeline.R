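#' @title Pipeline stage drivers
#' @description The exported `run_*` functions tie the modules into the
#'   two-step screening / final-fit / projection / report workflow, reading
#'   and writing plain artifacts (TIFF stacks, CSV tables, serialized
#'   models) under one run directory so each stage can be re-run or
#'   inspected independently. The numbered scripts under `analysis/` are
#'   thin drivers over these functions.
#' @name pipeline
NULL

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stopc("missing_dependency",
          "missing output of stage '%s' (%s) — run that stage first", stage, path)
  }
  path
}

#' Choose the "invaded late" analogue window
#'
#' Scans square candidate windows over the grid and returns the one with
#' the highest mean suitability — the synthetic stand-in for a region the
#' species reached late but where climate is favourable, used as the
#' held-out region in step-1 screening.
#'
#' @param vs a virtual species.
#' @param frac window edge length as a fraction of the grid edge.
#' @return List with `rows`, `cols` (index ranges) and a logical `mask`.
#' @export
pick_analogue_window <- function(vs, frac = 0.2) {
  s <- vs$suitability$values
  nr <- nrow(s); nc <- ncol(s)
  wr <- max(2L, floor(nr * frac)); wc <- max(2L, floor(nc * frac))
  best <- NULL
  for (r0 in seq(1L, nr - wr + 1L, by = max(1L, wr %/% 2L))) {
    for (c0 in seq(1L, nc - wc + 1L, by = max(1L, wc %/% 2L))) {
      m <- mean(s[r0:(r0 + wr - 1L), c0:(c0 + wc - 1L)], na.rm = TRUE)
      if (is.null(best) || (!is.na(m) && m > best$score)) {
        best <- list(score = m, r0 = r0, c0 = c0)
      }
    }
  }
  mask <- matrix(FALSE, nr, nc)
  mask[best$r0:(best$r0 + wr - 1L), best$c0:(best$c0 + wc - 1L)] <- TRUE
  list(rows = c(best$r0, best$r0 + wr - 1L),
       cols = c(best$c0, best$c0 + wc - 1L), mask = mask)
}

analogue_mask <- function(config, stack) {
  vs <- gen_virtual_species(stack, config$driver_bands,
                            config$driver_coefficients,
                            config$driver_intercept,
                            seed = derive_seed(config$master_seed, "species"))
  list(vs = vs, window = pick_analogue_window(vs, config$analogue_frac))
}

#' Simulate the synthetic study inputs
#'
#' Generates the current-climate stack, the virtual species, occurrence
#' records (a native sample outside the analogue window plus a smaller
#' sample inside it tagged as the held-out region), and one projected stack
#' per (GCM, RCP, year) scenario, writing everything under `out_dir`
#' together with a scenario manifest.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the stack, species, occurrences and
#'   manifest.
#' @export
run_simulate <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- gen_climate_stack(config$rows, config$cols, config$band_names,
                             config$correlation_length,
                             seed = derive_seed(config$master_seed, "climate"))
  am <- analogue_mask(config, stack)
  occ_native <- sample_occurrences(am$vs, config$n_native,
                                   region_mask = !am$window$mask,
                                   region_tag = "native",
                                   seed = derive_seed(config$master_seed, "occ_native"))
  occ_hold <- sample_occurrences(am$vs, config$n_holdout,
                                 region_mask = am$window$mask,
                                 region_tag = config$holdout_tag,
                                 seed = derive_seed(config$master_seed, "occ_holdout"))
  occ <- occurrence_set(c(occ_native$lon, occ_hold$lon),
                        c(occ_native$lat, occ_hold$lat),
                        c(occ_native$region_tag, occ_hold$region_tag))
  write_stack(stack, file.path(out_dir, "current.tif"))
  write_occurrences(occ, file.path(out_dir, "occurrences.csv"))
  manifest <- list()
  for (gcm in config$gcms) for (rcp in config$rcps) for (year in config$years) {
    pert <- scenario_perturbation(gcm, rcp, year, stack,
                                  correlation_length = config$perturbation_length,
                                  base_amplitude = config$perturbation_amplitude,
                                  seed = derive_seed(config$master_seed, "scenarios"))
    fut <- gen_future_stack(stack, pert)
    fn <- sprintf("future_%s_rcp%s_%s.tif", gcm, rcp, year)
    write_stack(fut, file.path(out_dir, fn))
    manifest[[length(manifest) + 1]] <- data.frame(
      gcm_code = gcm, rcp = rcp, year = year, path = fn,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "scenarios.csv"), row.names = FALSE)
  append_log(out_dir, "simulate", seed = config$master_seed,
             cells = config$rows * config$cols,
             bands = length(config$band_names),
             occurrences = nrow(occ), scenarios = nrow(manifest))
  invisible(list(stack = stack, species = am$vs, window = am$window,
                 occurrences = occ, manifest = manifest))
}

load_inputs <- function(config, out_dir) {
  stack <- read_stack(require_artifact(file.path(out_dir, "current.tif"), "simulate"))
  occ <- read_occurrences(require_artifact(file.path(out_dir, "occurrences.csv"), "simulate"))
  occ <- thin_occurrences(occ, stack)
  background <- sample_background(stack, config$background_n,
                                  seed = derive_seed(config$master_seed, "background"))
  list(stack = stack, occ = occ, background = background)
}

#' Screen all variable subsets (step 1)
#'
#' Thins the occurrences, samples the background, enumerates all subsets of
#' the configured sizes, screens each with [screen_subset()], and writes
#' `screening_records.csv` and `retained.csv`. An empty retention table is
#' a legal outcome and is reported as such.
#'
#' @param config a [run_config()].
#' @param out_dir run directory holding the `simulate` outputs.
#' @return Invisibly, list with `records` and `retained`.
#' @export
run_screen <- function(config, out_dir) {
  validate_config(config)
  inp <- load_inputs(config, out_dir)
  bands <- config$subset_bands %||% config$band_names
  subsets <- enumerate_subsets(bands, config$subset_sizes)
  records <- do.call(rbind, lapply(seq_len(nrow(subsets)), function(i) {
    screen_subset(subsets$bands[[i]], inp$occ, inp$stack, inp$background, config)
  }))
  retained <- retain_subsets(records, config$gates$min_passing)
  utils::write.csv(records, file.path(out_dir, "screening_records.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subset_id = retained, stringsAsFactors = FALSE),
                   file.path(out_dir, "retained.csv"), row.names = FALSE)
  append_log(out_dir, "screen", subsets = nrow(subsets),
             retained = length(retained),
             outcome = if (length(retained)) "ok" else "no dataset retained")
  invisible(list(records = records, retained = retained))
}

#' Tune MaxEnt parameters for the retained subsets
#'
#' Between the two steps, searches the multiplier x feature-class grid by
#' AICc for each retained subset (by default on the non-holdout occurrence
#' set) and writes `tuned.csv`.
#'
#' @param config a [run_config()].
#' @param out_dir run directory holding `screen` outputs.
#' @return Invisibly, named list `subset_id -> list(classes, reg_multiplier)`.
#' @export
run_tune <- function(config, out_dir) {
  validate_config(config)
  inp <- load_inputs(config, out_dir)
  retained <- utils::read.csv(
    require_artifact(file.path(out_dir, "retained.csv"), "screen"),
    stringsAsFactors = FALSE)$subset_id
  if (!length(retained)) {
    utils::write.csv(data.frame(subset_id = character(), class_set = character(),
                                reg_multiplier = numeric(), aicc = numeric()),
                     file.path(out_dir, "tuned.csv"), row.names = FALSE)
    append_log(out_dir, "tune", tuned = 0, outcome = "no dataset retained")
    return(invisible(list()))
  }
  occ_tune <- if (config$tune_occurrences == "non_holdout") {
    inp$occ[inp$occ$region_tag != config$holdout_tag, , drop = FALSE]
  } else inp$occ
  cells <- occ_cells(occ_tune, inp$stack)
  sets <- feature_class_sets()[config$tune_class_sets]
  tuned <- lapply(retained, function(sid) {
    bands <- strsplit(sid, "+", fixed = TRUE)[[1]]
    tr <- tune_maxent(inp$stack, cells, inp$background,
                      multipliers = config$multipliers, class_sets = sets,
                      knots = config$knots, bands = bands,
                      tol = config$tol, maxit = config$maxit)
    list(classes = tr$classes, class_set = tr$feature_class_set,
         reg_multiplier = tr$reg_multiplier, aicc = tr$aicc)
  })
  names(tuned) <- retained
  utils::write.csv(data.frame(
    subset_id = retained,
    class_set = vapply(tuned, `[[`, "", "class_set"),
    reg_multiplier = vapply(tuned, `[[`, 0, "reg_multiplier"),
    aicc = vapply(tuned, `[[`, 0, "aicc"), stringsAsFactors = FALSE),
    file.path(out_dir, "tuned.csv"), row.names = FALSE)
  append_log(out_dir, "tune", tuned = length(tuned))
  invisible(tuned)
}

read_tuned <- function(out_dir) {
  path <- file.path(out_dir, "tuned.csv")
  if (!file.exists(path)) return(NULL)
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(t)) return(list())
  tuned <- lapply(seq_len(nrow(t)), function(i) {
    list(classes = feature_class_sets()[[t$class_set[i]]],
         reg_multiplier = t$reg_multiplier[i])
  })
  names(tuned) <- t$subset_id
  tuned
}

#' Fit final models on all occurrences (step 2)
#'
#' Refits each retained subset on 80/20 splits of the full occurrence set
#' (holdout region included) with its tuned parameters, keeps replicates
#' with test AUC above the final gate, serializes the kept models, and
#' writes the current-climate consensus (mean and SD) of their binary maps.
#'
#' @param config a [run_config()].
#' @param out_dir run directory holding `screen` (and optionally `tune`)
#'   outputs.
#' @return Invisibly, the [fit_final()] result.
#' @export
run_fit <- function(config, out_dir) {
  validate_config(config)
  inp <- load_inputs(config, out_dir)
  retained <- utils::read.csv(
    require_artifact(file.path(out_dir, "retained.csv"), "screen"),
    stringsAsFactors = FALSE)$subset_id
  if (!length(retained)) {
    utils::write.csv(data.frame(subset_id = character(), replicate_id = integer(),
                                seed = integer(), auc_full = numeric(),
                                threshold = numeric(), kept = logical()),
                     file.path(out_dir, "final_records.csv"), row.names = FALSE)
    append_log(out_dir, "fit", kept = 0, outcome = "no dataset retained")
    return(invisible(list(records = data.frame(), models = list())))
  }
  bands <- config$subset_bands %||% config$band_names
  subsets <- enumerate_subsets(bands, config$subset_sizes)
  ff <- fit_final(retained, subsets, inp$occ, inp$stack, inp$background,
                  config, tuned = read_tuned(out_dir))
  utils::write.csv(ff$records, file.path(out_dir, "final_records.csv"),
                   row.names = FALSE)
  mdir <- file.path(out_dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (nm in names(ff$models)) {
    write_maxent(ff$models[[nm]], file.path(mdir, gsub("/", "_rep", nm, fixed = TRUE)))
  }
  kept <- ff$records[ff$records$kept, , drop = FALSE]
  if (nrow(kept)) {
    bins <- lapply(seq_len(nrow(kept)), function(i) {
      key <- paste(kept$subset_id[i], kept$replicate_id[i], sep = "/")
      project_task(list(model = ff$models[[key]], threshold = kept$threshold[i]),
                   inp$stack, config$output_scale)
    })
    cons <- consensus(bins, scenario_label = "current")
    write_stack(climate_stack(list(mean = cons$mean$values, sd = cons$sd$values),
                              cons$mean$transform),
                file.path(out_dir, "consensus_current.tif"))
  }
  append_log(out_dir, "fit", models = nrow(ff$records), kept = nrow(kept))
  invisible(ff)
}

#' Project the future ensemble
#'
#' Enumerates every (subset, replicate, year, RCP, GCM) task over the kept
#' models and the scenario manifest, projects and binarizes each at its
#' stored current-climate threshold, and writes one consensus (mean + SD)
#' stack per (RCP, year) group plus per-GCM centered deviation maps.
#'
#' @param config a [run_config()].
#' @param out_dir run directory holding `fit` outputs.
#' @return Invisibly, list with the task table and the per-group consensus.
#' @export
run_project <- function(config, out_dir) {
  validate_config(config)
  final <- utils::read.csv(
    require_artifact(file.path(out_dir, "final_records.csv"), "fit"),
    stringsAsFactors = FALSE)
  manifest <- utils::read.csv(
    require_artifact(file.path(out_dir, "scenarios.csv"), "simulate"),
    stringsAsFactors = FALSE)
  if (!nrow(final)) {
    append_log(out_dir, "project", tasks = 0, outcome = "no dataset retained")
    return(invisible(list(tasks = data.frame(), consensus = list())))
  }
  kept <- final[final$kept, , drop = FALSE]
  retained <- unique(kept$subset_id)
  tasks <- enumerate_tasks(retained, max(kept$replicate_id),
                           unique(manifest$gcm_code), unique(manifest$rcp),
                           unique(manifest$year))
  tasks$kept <- paste(tasks$subset_id, tasks$replicate_id, sep = "/") %in%
    paste(kept$subset_id, kept$replicate_id, sep = "/")
  tasks <- tasks[tasks$kept, setdiff(names(tasks), "kept"), drop = FALSE]
  mdir <- file.path(out_dir, "models")
  models <- list()
  thresholds <- stats::setNames(kept$threshold,
                                paste(kept$subset_id, kept$replicate_id, sep = "/"))
  stacks <- list()
  results <- vector("list", nrow(tasks))
  for (i in seq_len(nrow(tasks))) {
    t <- tasks[i, ]
    skey <- sprintf("%s_rcp%s_%s", t$gcm_code, t$rcp, t$year)
    if (is.null(stacks[[skey]])) {
      row <- manifest[manifest$gcm_code == t$gcm_code & manifest$rcp == t$rcp &
                        manifest$year == t$year, ]
      stacks[[skey]] <- read_stack(file.path(out_dir, row$path[1]))
    }
    mkey <- paste(t$subset_id, t$replicate_id, sep = "/")
    if (is.null(models[[mkey]])) {
      models[[mkey]] <- read_maxent(
        file.path(mdir, gsub("/", "_rep", mkey, fixed = TRUE)))
    }
    results[[i]] <- project_task(list(model = models[[mkey]],
                                      threshold = thresholds[[mkey]]),
                                 stacks[[skey]], config$output_scale)
  }
  groups <- scenario_consensus(tasks, results)
  for (g in names(groups)) {
    write_stack(climate_stack(list(mean = groups[[g]]$mean$values,
                                   sd = groups[[g]]$sd$values),
                              groups[[g]]$mean$transform),
                file.path(out_dir, sprintf("consensus_%s.tif", g)))
  }
  # per-GCM sub-consensus and centered deviation maps, per (rcp, year)
  for (rcp in unique(tasks$rcp)) for (year in unique(tasks$year)) {
    sel <- tasks$rcp == rcp & tasks$year == year
    per_gcm <- lapply(unique(tasks$gcm_code), function(g) {
      consensus(results[sel & tasks$gcm_code == g],
                scenario_label = sprintf("%s_rcp%s_%s", g, rcp, year))
    })
    names(per_gcm) <- unique(tasks$gcm_code)
    centered <- gcm_centered_maps(per_gcm)
    for (g in names(centered)) {
      write_stack(climate_stack(list(centered = centered[[g]]$values),
                                centered[[g]]$transform),
                  file.path(out_dir, sprintf("centered_%s_rcp%s_%s.tif", g, rcp, year)))
    }
  }
  append_log(out_dir, "project", tasks = nrow(tasks), groups = length(groups))
  invisible(list(tasks = tasks, consensus = groups))
}

#' Agreement table for a set of consensus maps
#'
#' One row per (scenario, scope, weighting): the unanimity and
#' high-agreement fractions of each consensus map, globally and over the
#' configured focal window, under both weighting conventions.
#'
#' @param consensus_maps named list of `consensus_map`s or [grid_map()]s.
#' @param config a [run_config()].
#' @return data.frame with columns `scenario`, `scope`, `weighting` and the
#'   three agreement fractions.
#' @export
report_agreement <- function(consensus_maps, config) {
  window <- focal_window(config$focal$lon_min, config$focal$lon_max,
                         config$focal$lat_min, config$focal$lat_max)
  rows <- list()
  for (scen in names(consensus_maps)) {
    for (w in c("cell_count", "cos_latitude")) {
      rows[[length(rows) + 1]] <- cbind(scenario = scen,
        area_stats(consensus_maps[[scen]], NULL, w, config$gates$high_agreement))
      rows[[length(rows) + 1]] <- cbind(scenario = scen,
        area_stats(consensus_maps[[scen]], window, w, config$gates$high_agreement))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Agreement-statistics tables and run summary
#'
#' For the current-climate consensus and every scenario consensus, computes
#' the unanimity and high-agreement area fractions over both scopes (global
#' and the focal window) and both weightings (cell count and cosine
#' latitude), writes `agreement.csv`, and a plain-text `summary.txt` of the
#' run (subsets screened and retained, models kept, tasks projected).
#' Re-running on unchanged artifacts reproduces both files byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir run directory.
#' @return Invisibly, the agreement table.
#' @export
run_report <- function(config, out_dir) {
  validate_config(config)
  window <- focal_window(config$focal$lon_min, config$focal$lon_max,
                         config$focal$lat_min, config$focal$lat_max)
  files <- list.files(out_dir, pattern = "^consensus_.*\\.tif$")
  rows <- list()
  for (f in files) {
    scen <- sub("^consensus_(.*)\\.tif$", "\\1", f)
    st <- read_stack(file.path(out_dir, f))
    gm <- grid_map(st$bands$mean, st$transform)
    for (w in c("cell_count", "cos_latitude")) {
      rows[[length(rows) + 1]] <- cbind(scenario = scen,
        area_stats(gm, NULL, w, config$gates$high_agreement))
      rows[[length(rows) + 1]] <- cbind(scenario = scen,
        area_stats(gm, window, w, config$gates$high_agreement))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scenario = character(), scope = character(),
               weighting = character(), frac_unanimous_suitable = numeric(),
               frac_unanimous_unsuitable = numeric(),
               frac_high_agreement = numeric())
  utils::write.csv(tab, file.path(out_dir, "agreement.csv"), row.names = FALSE)
  srec <- file.path(out_dir, "screening_records.csv")
  frec <- file.path(out_dir, "final_records.csv")
  screened <- if (file.exists(srec)) {
    length(unique(utils::read.csv(srec, stringsAsFactors = FALSE)$subset_id))
  } else 0
  retained <- if (file.exists(file.path(out_dir, "retained.csv"))) {
    nrow(utils::read.csv(file.path(out_dir, "retained.csv")))
  } else 0
  fr <- if (file.exists(frec)) utils::read.csv(frec, stringsAsFactors = FALSE) else NULL
  kept <- if (!is.null(fr) && nrow(fr)) sum(fr$kept) else 0
  tasks <- length(list.files(out_dir, pattern = "^centered_.*\\.tif$"))
  summary_lines <- c(
    sprintf("subsets screened: %d", screened),
    sprintf("subsets retained: %d%s", retained,
            if (retained == 0) " (no dataset fulfilled the evaluation criteria)" else ""),
    sprintf("models kept: %d", kept),
    sprintf("scenario groups reported: %d", sum(grepl("^consensus_rcp", files))),
    sprintf("agreement rows: %d", nrow(tab)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  append_log(out_dir, "report", rows = nrow(tab))
  invisible(tab)
}
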