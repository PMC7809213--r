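#' Enumerate climate-variable subsets
#'
#' All combinations of the requested sizes (default 4 and 5, the grouping
#' used to keep individual models small and limit overfitting), in
#' deterministic order: by size, then lexicographically. An optional
#' constraint function filters subsets after enumeration (e.g. to require a
#' core band).
#'
#' @param band_names candidate band names.
#' @param sizes subset sizes (default `c(4, 5)`).
#' @param constraint optional `function(names) -> logical`.
#' @return data.frame with `subset_id` (sorted names joined by `+`), `size`,
#'   and a `bands` list-column.
#' @export
enumerate_subsets <- function(band_names, sizes = c(4, 5), constraint = NULL) {
  if (length(band_names) < max(sizes)) {
    stopf("need at least %d bands, got %d", max(sizes), length(band_names))
  }
  out <- list()
  for (s in sort(sizes)) {
    cmb <- utils::combn(band_names, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  if (!is.null(constraint)) out <- Filter(constraint, out)
  data.frame(
    subset_id = vapply(out, function(b) paste(sort(b), collapse = "+"), ""),
    size = lengths(out),
    bands = I(out),
    stringsAsFactors = FALSE)
}

subset_bands <- function(subsets, subset_id) {
  subsets$bands[[match(subset_id, subsets$subset_id)]]
}

split_80_20 <- function(n, seed) {
  n_train <- floor(0.8 * n)
  idx <- withr::with_seed(seed, sample.int(n, n))
  list(train = sort(idx[seq_len(n_train)]), test = sort(idx[-seq_len(n_train)]))
}

occ_cells <- function(occ, stack) {
  d <- dim(stack)
  point_to_cell(stack$transform, d[1], d[2], occ$lon, occ$lat)
}

#' Screen one variable subset by spatial transfer
#'
#' The first step of the two-step procedure: the holdout region's records
#' (the invaded-late region, Europe in the original study design) are set
#' aside; for each of `config$replicates` replicates the remaining records
#' are split 80/20, a model is fitted on the 80\% with the configured
#' screening parameters, and the replicate is scored by (1) test AUC,
#' (2) maximum test TSS, and (3) omission of the holdout-region records at
#' the TSS-optimal threshold. A replicate passes when
#' `auc > config$gates$auc_screen`, `tss > config$gates$tss_screen` and
#' omission is 0 (all holdout occurrences predicted suitable).
#'
#' @param subset character vector of band names (size 4 or 5).
#' @param occ thinned [occurrence_set()] including holdout-region records.
#' @param stack a [climate_stack()].
#' @param background a [sample_background()].
#' @param config a [run_config()].
#' @return data.frame of screening records, one row per replicate, with
#'   `subset_id`, `replicate_id`, `seed`, `auc_test`, `tss_test`,
#'   `threshold`, `omission_region`, `passed`, `reason`.
#' @export
screen_subset <- function(subset, occ, stack, background, config) {
  subset_id <- paste(sort(subset), collapse = "+")
  holdout <- occ[occ$region_tag == config$holdout_tag, , drop = FALSE]
  rest <- occ[occ$region_tag != config$holdout_tag, , drop = FALSE]
  if (nrow(rest) < 10) stopf("need at least 10 non-holdout occurrences, got %d", nrow(rest))
  expansion <- build_expansion(stack, background, classes = config$screen_classes,
                               knots = config$knots, bands = subset)
  B <- cell_values(stack, background$cells, subset)
  bg_F <- expand_features(expansion, B)
  rest_cells <- occ_cells(rest, stack)
  hold_cells <- if (nrow(holdout)) occ_cells(holdout, stack) else NULL
  rows <- lapply(seq_len(config$replicates), function(rep) {
    seed <- derive_seed(config$master_seed, "screen", subset_id, rep)
    sp <- split_80_20(nrow(rest), seed)
    rec <- data.frame(subset_id = subset_id, replicate_id = rep, seed = seed,
                      auc_test = NA_real_, tss_test = NA_real_,
                      threshold = NA_real_, omission_region = NA_real_,
                      passed = FALSE, reason = "", stringsAsFactors = FALSE)
    if (length(sp$test) < 2) {
      rec$reason <- "fewer than 2 test presences"
      return(rec)
    }
    model <- maxent_fit(stack, rest_cells[sp$train, ], background,
                        expansion = expansion,
                        reg_multiplier = config$screen_multiplier,
                        tol = config$tol, maxit = config$maxit)
    bg_scores <- score_features(model, bg_F, config$output_scale)
    test_scores <- predict_scores(model,
                                  cell_values(stack, rest_cells[sp$test, ], subset),
                                  config$output_scale)
    th <- tss_optimal_threshold(test_scores, bg_scores)
    rec$auc_test <- auc(test_scores, bg_scores)
    rec$tss_test <- th$tss_max
    rec$threshold <- th$threshold
    if (!is.null(hold_cells) && nrow(hold_cells)) {
      hold_scores <- predict_scores(model,
                                    cell_values(stack, hold_cells, subset),
                                    config$output_scale)
      rec$omission_region <- omission_rate(hold_scores, th$threshold)
    }
    rec$passed <- isTRUE(rec$auc_test > config$gates$auc_screen &&
                         rec$tss_test > config$gates$tss_screen &&
                         !is.na(rec$omission_region) &&
                         rec$omission_region == 0)
    rec
  })
  do.call(rbind, rows)
}

# Apply the output transform to an already-expanded feature matrix.
score_features <- function(model, FX, output) {
  raw <- exp(drop(FX %*% model$lambda) - model$logZ)
  switch(output,
         raw = raw,
         cloglog = 1 - exp(-exp(model$entropy) * raw),
         logistic = { r <- exp(model$entropy) * raw; r / (1 + r) })
}

#' Retain subsets passing the screening gate
#'
#' A subset is retained when at least `min_passing` of its replicates pass
#' all three screening criteria jointly. An empty retention list is a legal
#' outcome (the pipeline then stops with a "no dataset retained" report
#' rather than an error).
#'
#' @param records row-bound [screen_subset()] records.
#' @param min_passing minimum passing replicates (default 5 of 10).
#' @return Character vector of retained `subset_id`s (possibly empty).
#' @export
retain_subsets <- function(records, min_passing = 5) {
  tab <- tapply(records$passed, records$subset_id, sum)
  names(tab)[!is.na(tab) & tab >= min_passing]
}

#' Fit final models on all occurrences
#'
#' The second step: for each retained subset, `config$replicates` replicates
#' split ALL occurrences (now including the holdout region) 80/20, fit with
#' the subset's tuned parameters, score AUC on the test split, and keep the
#' model when `auc_full > config$gates$auc_final`. The TSS-optimal
#' threshold from that replicate's test data is stored for binarization of
#' present and future predictions.
#'
#' @param subset_ids retained subset ids.
#' @param subsets the [enumerate_subsets()] table.
#' @param occ thinned [occurrence_set()] (all regions).
#' @param stack,background,config as in [screen_subset()].
#' @param tuned optional named list `subset_id -> list(classes,
#'   reg_multiplier)` from [tune_maxent()]; defaults to the screening
#'   parameters.
#' @return List with `records` (data.frame: `subset_id`, `replicate_id`,
#'   `seed`, `auc_full`, `threshold`, `kept`) and `models` (list of
#'   `maxent_model`, named `subset_id/replicate_id`, kept models only).
#' @export
fit_final <- function(subset_ids, subsets, occ, stack, background, config,
                      tuned = NULL) {
  all_cells <- occ_cells(occ, stack)
  records <- list()
  models <- list()
  for (sid in subset_ids) {
    bands <- subset_bands(subsets, sid)
    pars <- tuned[[sid]] %||% list(classes = config$screen_classes,
                                   reg_multiplier = config$screen_multiplier)
    expansion <- build_expansion(stack, background, classes = pars$classes,
                                 knots = config$knots, bands = bands)
    bg_F <- expand_features(expansion,
                            cell_values(stack, background$cells, bands))
    for (rep in seq_len(config$replicates)) {
      seed <- derive_seed(config$master_seed, "final", sid, rep)
      sp <- split_80_20(nrow(occ), seed)
      model <- maxent_fit(stack, all_cells[sp$train, ], background,
                          expansion = expansion,
                          reg_multiplier = pars$reg_multiplier,
                          tol = config$tol, maxit = config$maxit)
      bg_scores <- score_features(model, bg_F, config$output_scale)
      test_scores <- predict_scores(model,
                                    cell_values(stack, all_cells[sp$test, ], bands),
                                    config$output_scale)
      th <- tss_optimal_threshold(test_scores, bg_scores)
      auc_full <- auc(test_scores, bg_scores)
      kept <- auc_full > config$gates$auc_final
      records[[length(records) + 1]] <- data.frame(
        subset_id = sid, replicate_id = rep, seed = seed,
        auc_full = auc_full, threshold = th$threshold, kept = kept,
        stringsAsFactors = FALSE)
      if (kept) models[[paste(sid, rep, sep = "/")]] <- model
    }
  }
  list(records = do.call(rbind, records), models = models)
}

#' Consensus of binary maps
#'
#' Per-pixel fraction of models voting "suitable" (stored as exact vote
#' count over model count, so unanimity is testable as exactly 0 or 1) and
#' the per-pixel population standard deviation of the 0/1 votes. Nodata
#' wherever any input map is nodata.
#'
#' @param binary_maps non-empty list of aligned binary [grid_map()]s.
#' @param scenario_label free-text label stored with the map.
#' @return A `consensus_map`: `mean` and `sd` [grid_map()]s, `n_models`,
#'   `scenario_label`.
#' @export
consensus <- function(binary_maps, scenario_label = "current") {
  if (!length(binary_maps)) stopf("consensus needs at least one binary map")
  tr <- binary_maps[[1]]$transform
  d <- dim(binary_maps[[1]]$values)
  for (m in binary_maps) {
    if (!identical(dim(m$values), d) || !isTRUE(all.equal(unclass(m$transform), unclass(tr)))) {
      stopf("binary maps are not aligned on the same grid")
    }
  }
  n <- length(binary_maps)
  votes <- Reduce(`+`, lapply(binary_maps, `[[`, "values"))
  p <- votes / n
  sd <- sqrt(pmax(p * (1 - p), 0))
  structure(list(mean = grid_map(p, tr), sd = grid_map(sd, tr),
                 n_models = n, scenario_label = scenario_label),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("consensus_map '%s': %d models, %d x %d cells\n",
              x$scenario_label, x$n_models, nrow(x$mean$values), ncol(x$mean$values)))
  invisible(x)
}

#' Enumerate future-projection tasks
#'
#' Full Cartesian product of retained subsets, replicates, years, RCPs and
#' GCMs, in deterministic order (subset, then replicate, then year, then
#' RCP, then GCM). With the original study shape (14 subsets x 10
#' replicates x 4 RCPs x 11 GCMs x 2 years) this yields 12,320 tasks.
#'
#' @param retained retained subset ids.
#' @param replicates_per_subset replicate count.
#' @param gcms,rcps,years scenario labels from the manifest.
#' @return data.frame of tasks (`subset_id`, `replicate_id`, `gcm_code`,
#'   `rcp`, `year`).
#' @export
enumerate_tasks <- function(retained, replicates_per_subset, gcms, rcps, years) {
  if (!length(retained) || !length(gcms) || !length(rcps) || !length(years) ||
      replicates_per_subset < 1) {
    stopf("all task dimensions must be non-empty")
  }
  g <- expand.grid(gcm_code = gcms, rcp = rcps, year = years,
                   replicate_id = seq_len(replicates_per_subset),
                   subset_id = retained,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("subset_id", "replicate_id", "year", "rcp", "gcm_code")]
  rownames(g) <- NULL
  g
}

#' Project one task onto a scenario stack
#'
#' Predicts with the stored model on the scenario's climate stack and
#' binarizes at the model's stored current-climate TSS-optimal threshold
#' (thresholds are never re-derived on projected scores).
#'
#' @param model_record list with `model` (a `maxent_model`) and `threshold`.
#' @param scenario_stack the scenario's [climate_stack()].
#' @param output_scale output transform used when the threshold was derived.
#' @return A binary [grid_map()].
#' @export
project_task <- function(model_record, scenario_stack,
                         output_scale = "cloglog") {
  suit <- predict_maxent(model_record$model, scenario_stack, output_scale)
  binarize(suit, model_record$threshold)
}

#' Consensus per scenario group
#'
#' Groups task results by (RCP, year) and averages all binary maps in each
#' group (all subsets x replicates x GCMs) into one consensus map per
#' group. Every enumerated task must have a result.
#'
#' @param tasks the [enumerate_tasks()] table.
#' @param results list of binary [grid_map()]s, one per row of `tasks`, in
#'   the same order.
#' @return Named list (`"rcp<r>_<year>"`) of `consensus_map`s.
#' @export
scenario_consensus <- function(tasks, results) {
  if (nrow(tasks) != length(results) || any(vapply(results, is.null, TRUE))) {
    miss <- if (nrow(tasks) != length(results)) {
      sprintf("%d tasks vs %d results", nrow(tasks), length(results))
    } else {
      paste(which(vapply(results, is.null, TRUE)), collapse = ", ")
    }
    stopf("incomplete task results (%s)", miss)
  }
  key <- sprintf("rcp%s_%s", tasks$rcp, tasks$year)
  out <- lapply(unique(key), function(k) {
    consensus(results[key == k], scenario_label = k)
  })
  names(out) <- unique(key)
  out
}

#' Per-GCM consensus maps centered on the across-GCM mean
#'
#' For a fixed (RCP, year), subtracts the across-GCM per-pixel mean
#' suitability from each GCM's consensus map: negative values mark pixels
#' where that GCM predicts lower suitability than the GCM average, positive
#' values higher. The centered maps sum to zero per pixel by construction.
#'
#' @param per_gcm_consensus named list of aligned consensus [grid_map()]s
#'   (or `consensus_map`s), one per GCM.
#' @return Named list of centered [grid_map()]s.
#' @export
gcm_centered_maps <- function(per_gcm_consensus) {
  if (!length(per_gcm_consensus)) stopf("need at least one GCM consensus map")
  maps <- lapply(per_gcm_consensus,
                 function(x) if (inherits(x, "consensus_map")) x$mean else x)
  tr <- maps[[1]]$transform
  d <- dim(maps[[1]]$values)
  for (m in maps) {
    if (!identical(dim(m$values), d) || !isTRUE(all.equal(unclass(m$transform), unclass(tr)))) {
      stopf("GCM consensus maps are not aligned")
    }
  }
  avg <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  lapply(maps, function(m) grid_map(m$values - avg, tr))
}
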