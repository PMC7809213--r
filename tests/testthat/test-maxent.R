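test_that("feature counts follow the class definitions", {
  w <- tiny_world()
  st4 <- w$stack
  b4 <- c("tmax", "prec", "seas", "wet")
  e1 <- build_expansion(st4, w$background, "linear", bands = b4)
  expect_identical(n_features(e1), 4L)
  e2 <- build_expansion(st4, w$background, c("linear", "quadratic"), bands = b4)
  expect_identical(n_features(e2), 8L)
  e3 <- build_expansion(st4, w$background, c("linear", "quadratic", "product"),
                        bands = b4)
  expect_identical(n_features(e3), 14L)  # 4 + 4 + C(4,2)
  expect_error(build_expansion(st4, w$background, "splines"), "unknown feature class")
  expect_error(build_expansion(st4, w$background, "hinge", knots = 1), "at least 2 knots")
})

test_that("expanded features stay in [0,1] with clamping, knots increase strictly", {
  w <- tiny_world()
  e <- build_expansion(w$stack, w$background,
                       c("linear", "quadratic", "product", "hinge", "threshold"),
                       knots = 8, bands = c("tmax", "prec"))
  B <- cell_values(w$stack, w$background$cells, c("tmax", "prec"))
  FB <- expand_features(e, B)
  expect_true(all(FB >= 0 & FB <= 1))
  for (b in e$bands) expect_true(all(diff(e$knots[[b]]) > 0))
  # out-of-range input is clamped, not extrapolated
  Xout <- matrix(c(1e6, -1e6), 1, 2, dimnames = list(NULL, c("tmax", "prec")))
  expect_true(all(expand_features(e, Xout) >= 0 & expand_features(e, Xout) <= 1))
})

test_that("a constant band contributes no hinge features and no error", {
  st <- tiny_stack()
  st$bands$flat <- matrix(3.14, nrow(st$mask), ncol(st$mask))
  st <- climate_stack(st$bands, st$transform)
  bg <- sample_background(st, 100, seed = 1)
  e <- build_expansion(st, bg, c("linear", "hinge"), knots = 5,
                       bands = c("tmax", "flat"))
  expect_identical(sum(e$table$band == "flat" & e$table$type != "linear"), 0L)
  expect_gt(sum(e$table$band == "tmax" & e$table$type == "hinge_fwd"), 0)
})

test_that("overwhelming regularization shrinks every coefficient to zero", {
  w <- tiny_world()
  m <- maxent_fit(w$stack, cells_of(w$occ, w$stack), w$background,
                  reg_multiplier = 1e6, knots = 5)
  expect_true(all(m$lambda == 0))
  B <- cell_values(w$stack, w$background$cells, m$expansion$bands)
  raw <- predict_scores(m, B, "raw")
  expect_equal(raw, rep(1 / w$background$n, w$background$n), tolerance = 1e-12)
  expect_error(maxent_fit(w$stack, cells_of(w$occ, w$stack), w$background,
                          reg_multiplier = 0), "reg_multiplier")
})

test_that("the one-binary-feature coefficient solves the penalized score equation", {
  # presences all have f = 1, background half 1: lambda has a 1-D closed grid
  Fp <- matrix(1, 20, 1)
  Fb <- matrix(rep(c(0, 1), 25), 50, 1)
  beta <- 0.05
  sol <- maxent_solve(Fp, Fb, beta)
  grid <- seq(-2, 8, by = 1e-4)
  obj <- grid - log(25 * exp(grid) + 25) - beta * abs(grid)
  expect_equal(sol$lambda, grid[which.max(obj)], tolerance = 1e-4)
})

test_that("the penalized objective is non-decreasing across iterations", {
  w <- tiny_world()
  m <- maxent_fit(w$stack, cells_of(w$occ, w$stack), w$background,
                  classes = c("linear", "quadratic", "hinge"), knots = 10)
  expect_true(all(diff(m$trace) >= -1e-10))
  m2 <- maxent_fit(w$stack, cells_of(w$occ, w$stack), w$background,
                   classes = c("linear", "quadratic"), knots = 5,
                   tol = 1e-10, maxit = 10000)
  expect_true(m2$converged)
  expect_true(all(diff(m2$trace) >= -1e-10))
})

test_that("fitted coefficients match a dense grid-search oracle", {
  for (seed in 1:3) {
    sc <- withr::with_seed(seed, {
      Fb <- matrix(stats::runif(50 * 2), 50, 2)
      Fp <- matrix(stats::runif(15 * 2)^0.5, 15, 2)  # biased towards 1
      list(Fp = Fp, Fb = Fb)
    })
    beta <- c(0.08, 0.08)
    sol <- maxent_solve(sc$Fp, sc$Fb, beta, tol = 1e-12, maxit = 5000)
    oracle <- grid_oracle(sc$Fp, sc$Fb, beta)
    expect_equal(unname(sol$lambda), unname(oracle), tolerance = 1e-3)
  }
})

test_that("predictions are invariant to a rescaling of a raw band", {
  w <- tiny_world()
  cells <- cells_of(w$occ, w$stack)
  m1 <- maxent_fit(w$stack, cells, w$background, knots = 8,
                   tol = 1e-14, maxit = 1e5)
  st2 <- w$stack
  st2$bands$tmax <- st2$bands$tmax * 10
  st2 <- climate_stack(st2$bands, st2$transform)
  m2 <- maxent_fit(st2, cells, w$background, knots = 8,
                   tol = 1e-14, maxit = 1e5)
  r1 <- predict_maxent(m1, w$stack, "raw")
  r2 <- predict_maxent(m2, st2, "raw")
  expect_lt(max(abs(r1$values - r2$values)), 1e-6)
})

test_that("nonzero-coefficient count is non-increasing along the multiplier grid", {
  w <- tiny_world()
  cells <- cells_of(w$occ, w$stack)
  e <- build_expansion(w$stack, w$background, c("linear", "quadratic", "hinge"),
                       knots = 8, bands = c("tmax", "prec", "seas", "wet"))
  ks <- vapply(seq(0.5, 4, by = 0.5), function(rm) {
    sum(maxent_fit(w$stack, cells, w$background, expansion = e,
                   reg_multiplier = rm, tol = 1e-10, maxit = 1e4)$lambda != 0)
  }, 0)
  expect_true(all(diff(ks) <= 0))
})

test_that("raw output is a distribution over the background; cloglog is monotone", {
  w <- tiny_world()
  m <- maxent_fit(w$stack, cells_of(w$occ, w$stack), w$background, knots = 8)
  B <- cell_values(w$stack, w$background$cells, m$expansion$bands)
  raw <- predict_scores(m, B, "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-6)
  cll <- predict_scores(m, B, "cloglog")
  ord <- order(raw)
  expect_true(all(diff(cll[ord]) >= 0))
  expect_true(all(cll > 0 & cll < 1))
  # all-zero coefficients give a flat cloglog surface
  m0 <- maxent_fit(w$stack, cells_of(w$occ, w$stack), w$background,
                   reg_multiplier = 1e6, knots = 5)
  c0 <- predict_maxent(m0, w$stack, "cloglog")
  expect_equal(max(c0$values) - min(c0$values), 0, tolerance = 1e-12)
  expect_error(predict_maxent(m, crop(w$stack, focal_window(-180, 0, -90, 90))),
               NA)
  stripped <- climate_stack(w$stack$bands["noise"], w$stack$transform)
  expect_error(predict_maxent(m, stripped), "lacks band")
})

test_that("AICc follows the Warren-Seifert bookkeeping", {
  w <- tiny_world()
  cells <- cells_of(w$occ, w$stack)
  n <- nrow(cells)
  # fully penalized model: uniform raw, k = 0, AICc = 2 n ln N
  m0 <- maxent_fit(w$stack, cells, w$background, reg_multiplier = 1e6, knots = 5)
  expect_equal(maxent_aicc(m0, w$stack, cells, w$background),
               2 * n * log(w$background$n), tolerance = 1e-6)
  # n <= k + 1 diverges
  m <- maxent_fit(w$stack, cells, w$background, knots = 8)
  k <- sum(m$lambda != 0)
  expect_gt(k, 1)
  few <- cells[seq_len(min(k, n)), ]
  expect_identical(maxent_aicc(m, w$stack, few, w$background), Inf)
  # plain AIC is the uncorrected value
  a_c <- maxent_aicc(m, w$stack, cells, w$background)
  a <- maxent_aicc(m, w$stack, cells, w$background, correct = FALSE)
  expect_equal(a_c - a, 2 * k * (k + 1) / (n - k - 1), tolerance = 1e-9)
})

test_that("tuning scans the grid and returns the AICc argmin", {
  w <- tiny_world(n_occ = 40, n_bg = 150)
  cells <- cells_of(w$occ, w$stack)
  one <- tune_maxent(w$stack, cells, w$background, multipliers = 2,
                     class_sets = feature_class_sets()["LQ"], knots = 4,
                     bands = c("tmax", "prec"))
  expect_identical(one$feature_class_set, "LQ")
  expect_identical(one$reg_multiplier, 2)
  expect_identical(nrow(one$aicc_table), 1L)
  full <- tune_maxent(w$stack, cells, w$background, knots = 4,
                      bands = c("tmax", "prec"), maxit = 200)
  expect_identical(nrow(full$aicc_table), 48L)  # 8 multipliers x 6 class sets
  finite <- full$aicc_table$aicc[is.finite(full$aicc_table$aicc)]
  expect_equal(full$aicc, min(finite))
})

test_that("model serialization round-trips predictions to 1e-12", {
  w <- tiny_world()
  m <- maxent_fit(w$stack, cells_of(w$occ, w$stack), w$background,
                  classes = c("linear", "quadratic", "hinge", "threshold"),
                  knots = 6)
  base <- file.path(withr::local_tempdir(), "model")
  write_maxent(m, base)
  back <- read_maxent(base)
  expect_equal(back$lambda, m$lambda, tolerance = 1e-15)
  B <- cell_values(w$stack, w$background$cells, m$expansion$bands)
  expect_equal(predict_scores(back, B, "cloglog"),
               predict_scores(m, B, "cloglog"), tolerance = 1e-12)
  expect_error(read_maxent(file.path(tempdir(), "absent")), "not found")
})
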