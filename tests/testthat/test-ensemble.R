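test_that("subset enumeration covers all 4- and 5-combinations deterministically", {
  s11 <- enumerate_subsets(paste0("bio", 1:11))
  expect_identical(nrow(s11), as.integer(choose(11, 4) + choose(11, 5)))  # 330 + 462 = 792
  s6 <- enumerate_subsets(paste0("v", 1:6))
  expect_identical(nrow(s6), 21L)  # 15 + 6
  expect_identical(nrow(enumerate_subsets(letters[1:4], sizes = 4)), 1L)
  expect_identical(s11$subset_id, enumerate_subsets(paste0("bio", 1:11))$subset_id)
  expect_false(anyDuplicated(s11$subset_id) > 0)
  # constraint hook filters after enumeration
  core <- enumerate_subsets(paste0("v", 1:6), constraint = function(b) "v1" %in% b)
  expect_true(all(vapply(core$bands, function(b) "v1" %in% b, TRUE)))
  expect_identical(nrow(core), as.integer(choose(5, 3) + choose(5, 4)))
  expect_error(enumerate_subsets(letters[1:3]), "at least 5 bands")
})

test_that("retention needs at least min_passing jointly-passing replicates", {
  rec <- function(id, n_pass, n_tot = 10) {
    data.frame(subset_id = id, replicate_id = seq_len(n_tot),
               passed = seq_len(n_tot) <= n_pass)
  }
  records <- rbind(rec("a", 5), rec("b", 4), rec("c", 10), rec("d", 0))
  expect_identical(sort(retain_subsets(records)), c("a", "c"))
  expect_identical(retain_subsets(records, min_passing = 6), "c")
  expect_identical(length(retain_subsets(rec("x", 4))), 0L)
})

test_that("task enumeration is the full Cartesian product in stable order", {
  t1 <- enumerate_tasks(paste0("s", 1:14), 10, paste0("g", 1:11),
                        c(2.6, 4.5, 6.0, 8.5), c(2050, 2070))
  expect_identical(nrow(t1), 12320L)
  expect_identical(nrow(enumerate_tasks("s", 1, "g", 2.6, 2050)), 1L)
  expect_identical(nrow(enumerate_tasks(paste0("s", 1:3), 2, paste0("g", 1:2),
                                        c(2.6, 8.5), c(2050, 2070))), 48L)
  # deterministic precedence: subset, replicate, year, rcp, gcm
  expect_identical(t1$subset_id[1:2], c("s1", "s1"))
  expect_identical(t1$gcm_code[1:2], c("g1", "g2"))
  # property: count is the product of arbitrary dimension sizes
  for (seed in 1:8) {
    dims <- withr::with_seed(seed, sample(1:5, 5, replace = TRUE))
    t <- enumerate_tasks(paste0("s", seq_len(dims[1])), dims[2],
                         paste0("g", seq_len(dims[3])),
                         seq_len(dims[4]), 2000 + seq_len(dims[5]))
    expect_identical(nrow(t), as.integer(prod(dims)))
  }
  expect_error(enumerate_tasks(character(), 1, "g", 1, 1), "non-empty")
})

test_that("consensus stores exact vote fractions with population SD", {
  tr <- grid_transform(0, 2, 1, 1)
  ones <- grid_map(matrix(1, 2, 2), tr)
  zeros <- grid_map(matrix(0, 2, 2), tr)
  both <- consensus(list(ones, zeros))
  expect_true(all(both$mean$values == 0.5))
  expect_true(all(both$sd$values == 0.5))
  expect_identical(both$n_models, 2L)
  same <- consensus(list(ones, ones, ones))
  expect_true(all(same$mean$values == 1))
  expect_true(all(same$sd$values == 0))
  single <- consensus(list(zeros))
  expect_equal(single$mean$values, zeros$values)
  expect_true(all(single$sd$values == 0))
  off <- grid_map(matrix(1, 3, 3), tr)
  expect_error(consensus(list(ones, off)), "not aligned")
})

test_that("consensus SD is zero exactly at unanimity, and nodata propagates", {
  tr <- grid_transform(0, 4, 1, 1)
  maps <- withr::with_seed(42, lapply(1:7, function(i) {
    v <- matrix(sample(0:1, 16, TRUE), 4, 4)
    v[1, 1] <- NA  # one shared nodata cell
    if (i == 1) v[2, 2] <- NA  # nodata in a single model
    grid_map(v, tr)
  }))
  cm <- consensus(maps)
  expect_true(is.na(cm$mean$values[1, 1]) && is.na(cm$mean$values[2, 2]))
  v <- cm$mean$values; s <- cm$sd$values
  ok <- !is.na(v)
  expect_identical(s[ok] == 0, v[ok] %in% c(0, 1))
  expect_true(all(v[ok] >= 0 & v[ok] <= 1))
})

test_that("GCM-centered maps are exact anomalies about the GCM mean", {
  tr <- grid_transform(0, 1, 1, 1)
  g1 <- grid_map(matrix(0.2, 1, 2), tr)
  g2 <- grid_map(matrix(0.4, 1, 2), tr)
  cent <- gcm_centered_maps(list(A = g1, B = g2))
  expect_equal(cent$A$values, matrix(-0.1, 1, 2))
  expect_equal(cent$B$values, matrix(0.1, 1, 2))
  # centering identity on random stacks of maps
  maps <- withr::with_seed(1, lapply(1:5, function(i)
    grid_map(matrix(stats::runif(12), 3, 4), tr)))
  names(maps) <- paste0("g", 1:5)
  cent5 <- gcm_centered_maps(maps)
  total <- Reduce(`+`, lapply(cent5, `[[`, "values"))
  expect_lt(max(abs(total)), 1e-12)
  one <- gcm_centered_maps(maps[1])
  expect_true(all(one[[1]]$values == 0))
})

test_that("screening returns one auditable record per replicate", {
  w <- tiny_world()
  cfg <- tiny_config()
  rec <- screen_subset(c("tmax", "prec", "seas", "wet"), w$occ, w$stack,
                       w$background, cfg)
  expect_identical(nrow(rec), as.integer(cfg$replicates))
  expect_identical(rec$replicate_id, seq_len(cfg$replicates))
  # `passed` is recomputable from the stored metrics and the gates
  recomputed <- rec$auc_test > cfg$gates$auc_screen &
    rec$tss_test > cfg$gates$tss_screen & rec$omission_region == 0
  expect_identical(rec$passed, recomputed)
  # the driver subset passes here; a pure noise subset should not
  expect_gte(sum(rec$passed), 1)
})

test_that("projection onto the current climate reproduces the current binary map", {
  w <- tiny_world()
  cfg <- tiny_config()
  m <- maxent_fit(w$stack, cells_of(w$occ, w$stack), w$background,
                  classes = cfg$screen_classes, knots = cfg$knots)
  suit <- predict_maxent(m, w$stack, "cloglog")
  th <- 0.4
  current_bin <- binarize(suit, th)
  proj <- project_task(list(model = m, threshold = th), w$stack, "cloglog")
  expect_equal(proj$values, current_bin$values)
})

test_that("a uniform shift of the single driver moves the suitable area", {
  st <- tiny_stack()
  vs <- gen_virtual_species(st, "tmax", 4, -4)
  occ <- sample_occurrences(vs, 60, region_tag = "native", seed = 3)
  bg <- sample_background(st, 300, seed = 4)
  m <- maxent_fit(st, cells_of(occ, st), bg, classes = c("linear", "quadratic"),
                  bands = c("tmax", "prec"))
  th <- 0.5
  n_now <- sum(project_task(list(model = m, threshold = th), st)$values)
  shifted <- st
  shifted$bands$tmax <- shifted$bands$tmax + 10 * stats::sd(st$bands$tmax)
  shifted <- climate_stack(shifted$bands, shifted$transform)
  n_future <- sum(project_task(list(model = m, threshold = th), shifted)$values)
  expect_false(n_now == n_future)
  # nodata propagates through projection
  mask <- matrix(FALSE, 30, 30); mask[1, ] <- TRUE
  stm <- gen_climate_stack(30, 30, band_names(st), 3, seed = 11, mask = mask)
  proj <- project_task(list(model = m, threshold = th), stm)
  expect_true(all(is.na(proj$values[1, ])))
})

test_that("scenario grouping pools every task of an (rcp, year) cell", {
  tasks <- enumerate_tasks(c("a", "b"), 2, c("g1", "g2"), c(2.6, 8.5), 2050)
  tr <- grid_transform(0, 2, 1, 1)
  results <- withr::with_seed(9, lapply(seq_len(nrow(tasks)), function(i)
    grid_map(matrix(sample(0:1, 4, TRUE), 2, 2), tr)))
  groups <- scenario_consensus(tasks, results)
  expect_identical(length(groups), 2L)
  expect_identical(groups[[1]]$n_models, 8L)  # 2 subsets x 2 reps x 2 gcms
  expect_true(all(vapply(groups, function(g)
    all(g$mean$values >= 0 & g$mean$values <= 1), TRUE)))
  single <- scenario_consensus(tasks[1, ], results[1])
  expect_equal(single[[1]]$mean$values, results[[1]]$values)
  expect_error(scenario_consensus(tasks, results[-1]), "incomplete")
})

test_that("final fitting keeps replicates above the AUC gate with stored thresholds", {
  w <- tiny_world()
  cfg <- tiny_config()
  subsets <- enumerate_subsets(band_names(w$stack), 4)
  sid <- "prec+seas+tmax+wet"
  ff <- fit_final(sid, subsets, w$occ, w$stack, w$background, cfg)
  expect_identical(nrow(ff$records), as.integer(cfg$replicates))
  expect_identical(ff$records$kept,
                   ff$records$auc_full > cfg$gates$auc_final)
  expect_identical(sort(names(ff$models)),
                   sort(paste(sid, ff$records$replicate_id[ff$records$kept],
                              sep = "/")))
  # an impossible gate keeps nothing
  cfg2 <- tiny_config()
  cfg2$gates$auc_final <- 1.0
  ff2 <- fit_final(sid, subsets, w$occ, w$stack, w$background, cfg2)
  expect_identical(sum(ff2$records$kept), 0L)
})
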