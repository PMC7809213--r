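#' Penalized maximum-entropy solver
#'
#' Maximizes the L1-penalized presence log-likelihood of the Gibbs
#' distribution over the background,
#' \deqn{\ell(\lambda) = \frac{1}{m}\sum_i \lambda^\top f(x_i) -
#'   \log \sum_{b} e^{\lambda^\top f(b)} - \sum_j \beta_j |\lambda_j|,}
#' by proximal-gradient ascent (soft-thresholding step) with backtracking
#' line search, which makes the penalized objective non-decreasing across
#' iterations. Iteration stops when the improvement falls below `tol` or
#' after `maxit` iterations. With all `beta > 0` the optimum is finite even
#' under complete separation.
#'
#' @param Fp feature matrix at presence points (m x p, values in `[0, 1]`).
#' @param Fb feature matrix at background points (N x p).
#' @param beta per-feature L1 penalties (all `> 0`).
#' @param tol convergence tolerance on the objective improvement.
#' @param maxit maximum iterations.
#' @return List with `lambda`, `logZ` (log normalizer over the background),
#'   `objective` (final penalized objective), `trace` (objective per
#'   accepted iteration), `converged`, `iterations`.
#' @export
maxent_solve <- function(Fp, Fb, beta, tol = 1e-7, maxit = 500) {
  stopifnot(ncol(Fp) == ncol(Fb), length(beta) == ncol(Fp))
  beta <- unname(beta)
  if (any(beta <= 0)) stopf("all penalties must be positive (reg_multiplier = 0 is rejected)")
  if (nrow(Fp) < 2) stopf("need at least 2 presence points")
  p <- ncol(Fp)
  fbar <- unname(colMeans(Fp))
  lambda <- numeric(p)
  eta_b <- numeric(nrow(Fb))        # Fb %*% lambda, kept incrementally
  objval <- function(eta_p_mean, eta_b, lambda) {
    m <- max(eta_b)
    eta_p_mean - (m + log(sum(exp(eta_b - m)))) - sum(beta * abs(lambda))
  }
  gradient <- function(eta_b) {
    m <- max(eta_b)
    w <- exp(eta_b - m)
    fbar - unname(drop(crossprod(w / sum(w), Fb)))
  }
  obj <- objval(0, eta_b, lambda)
  trace <- obj
  step <- 1
  converged <- FALSE
  it <- 0
  grad <- gradient(eta_b)
  while (it < maxit) {
    it <- it + 1
    accepted <- FALSE
    while (step > 1e-13) {
      cand <- lambda + step * grad
      cand <- sign(cand) * pmax(abs(cand) - step * beta, 0)
      eta_b2 <- drop(Fb %*% cand)
      obj2 <- objval(sum(fbar * cand), eta_b2, cand)
      if (obj2 >= obj - 1e-14) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    improvement <- obj2 - obj
    grad2 <- gradient(eta_b2)
    # Barzilai-Borwein spectral step for the next iteration (safeguarded by
    # the backtracking above, which preserves the ascent property)
    s <- cand - lambda
    y <- grad - grad2
    sy <- sum(s * y)
    step <- if (sy > 1e-300) min(max(sum(s * s) / sy, 1e-8), 1e8) else step * 2
    lambda <- cand; eta_b <- eta_b2; obj <- obj2; grad <- grad2
    trace <- c(trace, obj)
    if (improvement < tol) { converged <- TRUE; break }
  }
  mzx <- max(eta_b)
  logZ <- mzx + log(sum(exp(eta_b - mzx)))
  list(lambda = lambda, logZ = logZ, objective = obj, trace = trace,
       converged = converged, iterations = it)
}

#' Fit a maximum-entropy presence-background model
#'
#' Expands features on the background, assembles per-feature default
#' penalties scaled by the regularization multiplier, runs [maxent_solve()],
#' and stores the normalizer and entropy of the fitted raw distribution over
#' the background (needed for the cloglog/logistic output transforms).
#'
#' @param stack a [climate_stack()].
#' @param presence_cells data.frame with `row`, `col` of presence cells (all
#'   valid in the stack).
#' @param background a [sample_background()] result.
#' @param expansion optional prebuilt [build_expansion()]; built from
#'   `classes`/`knots`/`bands` when `NULL`.
#' @param reg_multiplier positive regularization (rate) multiplier.
#' @param classes,knots,bands forwarded to [build_expansion()] when
#'   `expansion` is `NULL`.
#' @param tol,maxit forwarded to [maxent_solve()].
#' @return A `maxent_model`.
#' @export
maxent_fit <- function(stack, presence_cells, background, expansion = NULL,
                       reg_multiplier = 1,
                       classes = c("linear", "quadratic", "hinge"),
                       knots = 30, bands = band_names(stack),
                       tol = 1e-7, maxit = 500) {
  if (is.null(expansion)) {
    expansion <- build_expansion(stack, background, classes = classes,
                                 knots = knots, bands = bands)
  }
  P <- cell_values(stack, presence_cells, expansion$bands)
  if (anyNA(P)) stopf("presence cells include nodata cells")
  B <- cell_values(stack, background$cells, expansion$bands)
  Fp <- expand_features(expansion, P)
  Fb <- expand_features(expansion, B)
  beta <- default_betas(expansion, Fp, reg_multiplier)
  sol <- maxent_solve(Fp, Fb, beta, tol = tol, maxit = maxit)
  raw_b <- exp(drop(Fb %*% sol$lambda) - sol$logZ)
  entropy <- -sum(raw_b * log(pmax(raw_b, 1e-300)))
  structure(list(
    expansion = expansion, lambda = sol$lambda, logZ = sol$logZ,
    entropy = entropy, reg_multiplier = reg_multiplier, beta = beta,
    n_presence = nrow(Fp), n_background = nrow(Fb),
    background_checksum = sum(B) + nrow(B),
    trace = sol$trace, converged = sol$converged),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d features (%d nonzero), classes {%s}, multiplier %g\n",
    length(x$lambda), sum(x$lambda != 0),
    paste(x$expansion$classes, collapse = ", "), x$reg_multiplier))
  invisible(x)
}

#' Score raw band values with a fitted model
#'
#' @param model a [maxent_fit()] result.
#' @param X raw-value matrix with one named column per modelled band.
#' @param output `"cloglog"` (default), `"raw"`, or `"logistic"`. Raw is the
#'   Gibbs density normalized over the fitting background; cloglog is
#'   `1 - exp(-exp(H) * raw)` with `H` the entropy of the raw distribution.
#' @return Numeric score vector.
#' @export
predict_scores <- function(model, X,
                           output = c("cloglog", "raw", "logistic")) {
  output <- match.arg(output)
  FX <- expand_features(model$expansion, X)
  raw <- exp(drop(FX %*% model$lambda) - model$logZ)
  switch(output,
         raw = raw,
         cloglog = 1 - exp(-exp(model$entropy) * raw),
         logistic = {
           r <- exp(model$entropy) * raw
           r / (1 + r)
         })
}

#' Predict a suitability map over a climate stack
#'
#' @param model a [maxent_fit()] result.
#' @param stack a [climate_stack()] containing every modelled band.
#' @param output output scale, see [predict_scores()].
#' @return A [grid_map()]; nodata cells stay `NA`.
#' @export
predict_maxent <- function(model, stack,
                           output = c("cloglog", "raw", "logistic")) {
  output <- match.arg(output)
  missing <- setdiff(model$expansion$bands, band_names(stack))
  if (length(missing)) stopf("stack lacks band '%s' required by the model", missing[1])
  valid <- which(!stack$mask)
  d <- dim(stack)
  cells <- data.frame(row = ((valid - 1) %% d[1]) + 1,
                      col = ((valid - 1) %/% d[1]) + 1)
  X <- cell_values(stack, cells, model$expansion$bands)
  out <- matrix(NA_real_, d[1], d[2])
  out[valid] <- predict_scores(model, X, output)
  grid_map(out, stack$transform)
}

#' Sample-size-corrected Akaike information criterion
#'
#' AICc of a fitted model at the presence points, with the raw distribution
#' renormalized to sum to exactly 1 over the fitting background before
#' taking logs, and `k` the number of features with nonzero coefficients:
#' `AICc = 2k - 2L + 2k(k+1)/(n-k-1)`, infinite when `n <= k + 1`.
#'
#' @param model a [maxent_fit()] result.
#' @param stack the fitting [climate_stack()].
#' @param presence_cells presence cells (data.frame `row`, `col`).
#' @param background the fitting [sample_background()].
#' @param correct use the small-sample correction (default); `FALSE` gives
#'   plain AIC.
#' @return A single number (possibly `Inf`).
#' @export
maxent_aicc <- function(model, stack, presence_cells, background,
                        correct = TRUE) {
  k <- sum(model$lambda != 0)
  n <- nrow(presence_cells)
  B <- cell_values(stack, background$cells, model$expansion$bands)
  raw_b <- predict_scores(model, B, "raw")
  P <- cell_values(stack, presence_cells, model$expansion$bands)
  raw_p <- predict_scores(model, P, "raw") / sum(raw_b)
  L <- sum(log(raw_p))
  if (!correct) return(2 * k - 2 * L)
  if (n <= k + 1) return(Inf)
  2 * k - 2 * L + 2 * k * (k + 1) / (n - k - 1)
}

#' The six standard feature-class sets
#'
#' Linear; linear+quadratic; hinge; linear+quadratic+hinge;
#' linear+quadratic+hinge+product; linear+quadratic+hinge+product+threshold.
#'
#' @return Named list of character vectors, ordered by class count.
#' @export
feature_class_sets <- function() {
  list(L = "linear",
       LQ = c("linear", "quadratic"),
       H = "hinge",
       LQH = c("linear", "quadratic", "hinge"),
       LQHP = c("linear", "quadratic", "hinge", "product"),
       LQHPT = c("linear", "quadratic", "hinge", "product", "threshold"))
}

#' Tune regularization multiplier and feature classes by AICc
#'
#' Fits every combination of the multiplier grid (default 0.5 to 4 in steps
#' of 0.5) and the six feature-class sets on all supplied presences against
#' the background, scores each with [maxent_aicc()], and returns the
#' combination with the minimum finite AICc. Ties are broken toward fewer
#' feature classes, then toward a smaller multiplier.
#'
#' @param stack,presence_cells,background as in [maxent_fit()].
#' @param multipliers candidate regularization multipliers.
#' @param class_sets named list of feature-class vectors (default
#'   [feature_class_sets()]), iterated in order of increasing class count.
#' @param knots,bands forwarded to [build_expansion()].
#' @param correct AICc (default) or plain AIC.
#' @param tol,maxit forwarded to the solver.
#' @return A `tune_result`: `reg_multiplier`, `feature_class_set` (name and
#'   classes), and the full `aicc_table` (one row per combination with its
#'   AICc and nonzero-coefficient count).
#' @export
tune_maxent <- function(stack, presence_cells, background,
                        multipliers = seq(0.5, 4, by = 0.5),
                        class_sets = feature_class_sets(),
                        knots = 30, bands = band_names(stack),
                        correct = TRUE, tol = 1e-7, maxit = 500) {
  ord <- order(lengths(class_sets))
  class_sets <- class_sets[ord]
  rows <- list()
  best <- NULL
  for (cs in names(class_sets)) {
    expansion <- build_expansion(stack, background, classes = class_sets[[cs]],
                                 knots = knots, bands = bands)
    for (rm in sort(multipliers)) {
      model <- maxent_fit(stack, presence_cells, background,
                          expansion = expansion, reg_multiplier = rm,
                          tol = tol, maxit = maxit)
      a <- maxent_aicc(model, stack, presence_cells, background, correct = correct)
      rows[[length(rows) + 1]] <- data.frame(
        class_set = cs, reg_multiplier = rm, aicc = a,
        k_nonzero = sum(model$lambda != 0), stringsAsFactors = FALSE)
      if (is.finite(a) && (is.null(best) || a < best$aicc)) {
        best <- list(class_set = cs, classes = class_sets[[cs]],
                     reg_multiplier = rm, aicc = a, model = model)
      }
    }
  }
  if (is.null(best)) stopf("all candidate models have infinite AICc (too few presences)")
  structure(list(reg_multiplier = best$reg_multiplier,
                 feature_class_set = best$class_set,
                 classes = best$classes, aicc = best$aicc,
                 aicc_table = do.call(rbind, rows)),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("tune_result: classes %s, multiplier %g (AICc %.3f; %d combinations)\n",
              x$feature_class_set, x$reg_multiplier, x$aicc, nrow(x$aicc_table)))
  invisible(x)
}

#' Serialize / restore a fitted model
#'
#' Writes a flat text lambdas table (feature type, bands, knot, coefficient,
#' normalizer min/max) and a JSON header (classes, multiplier, log
#' normalizer, entropy, background checksum). The round trip reproduces
#' predictions to 1e-12.
#'
#' @param model a [maxent_fit()] result.
#' @param path base path; `<path>.lambdas.tsv` and `<path>.json` are
#'   written.
#' @export
write_maxent <- function(model, path) {
  ex <- model$expansion
  t <- ex$table
  t$coefficient <- model$lambda
  t$lo <- ex$lo[t$band]
  t$hi <- ex$hi[t$band]
  num <- vapply(t, is.numeric, TRUE)
  t[num] <- lapply(t[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(t, paste0(path, ".lambdas.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  header <- list(classes = ex$classes, bands = ex$bands,
                 knots_requested = ex$knots_requested,
                 lo = as.list(ex$lo), hi = as.list(ex$hi),
                 reg_multiplier = model$reg_multiplier,
                 logZ = model$logZ, entropy = model$entropy,
                 n_presence = model$n_presence,
                 n_background = model$n_background,
                 background_checksum = model$background_checksum)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  hfile <- paste0(path, ".json")
  lfile <- paste0(path, ".lambdas.tsv")
  if (!file.exists(hfile) || !file.exists(lfile)) {
    stopf("model files not found at base path %s", path)
  }
  h <- jsonlite::read_json(hfile, simplifyVector = TRUE)
  t <- utils::read.table(lfile, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character",
                                        "numeric", "numeric", "numeric", "numeric"))
  bands <- h$bands
  lo <- stats::setNames(unlist(h$lo)[bands], bands)
  hi <- stats::setNames(unlist(h$hi)[bands], bands)
  knot_list <- lapply(bands, function(b) {
    sort(unique(t$knot[t$band == b & t$type %in% c("hinge_fwd", "hinge_rev", "threshold")]))
  })
  names(knot_list) <- bands
  expansion <- structure(list(classes = h$classes, bands = bands, lo = lo,
                              hi = hi, knots = knot_list,
                              knots_requested = h$knots_requested,
                              table = t[c("type", "band", "band2", "knot")]),
                         class = "feature_expansion")
  structure(list(expansion = expansion, lambda = t$coefficient,
                 logZ = h$logZ, entropy = h$entropy,
                 reg_multiplier = h$reg_multiplier, beta = NULL,
                 n_presence = h$n_presence, n_background = h$n_background,
                 background_checksum = h$background_checksum,
                 trace = NULL, converged = NA),
            class = "maxent_model")
}
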