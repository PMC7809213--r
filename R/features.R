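#' Feature expansion for the maximum-entropy model
#'
#' Builds the basis-function dictionary over raw climate values: `linear`
#' (min-max scaled band), `quadratic` (scaled square), `product` (scaled
#' pairwise products), `hinge` (forward and reverse hinges at a knot grid)
#' and `threshold` (step functions at the same knots). Scaling constants and
#' knots come from the background sample, so every feature maps in-range
#' input into `[0, 1]`; out-of-range values are clamped.
#'
#' Knots are placed at background quantiles and kept strictly increasing; a
#' band that is constant over the background contributes no hinge or
#' threshold features (recorded in the expansion, not an error).
#'
#' @param stack a [climate_stack()] restricted to the modelled bands, or any
#'   stack together with `bands` naming the subset to use.
#' @param background a [sample_background()] result.
#' @param classes subset of `c("linear", "quadratic", "product", "hinge",
#'   "threshold")`.
#' @param knots number of interior quantile knots per band for hinge and
#'   threshold features (at least 2 when those classes are requested).
#' @param bands band names to expand (default: all bands of the stack).
#' @return A `feature_expansion` object.
#' @export
build_expansion <- function(stack, background,
                            classes = c("linear", "quadratic", "hinge"),
                            knots = 30, bands = band_names(stack)) {
  ok <- c("linear", "quadratic", "product", "hinge", "threshold")
  if (!all(classes %in% ok)) {
    stopf("unknown feature class: %s", setdiff(classes, ok)[1])
  }
  if (any(c("hinge", "threshold") %in% classes) && knots < 2) {
    stopf("hinge/threshold features need at least 2 knots")
  }
  B <- cell_values(stack, background$cells, bands)
  lo <- apply(B, 2, min)
  hi <- apply(B, 2, max)
  knot_list <- lapply(bands, function(b) {
    if (hi[b] <= lo[b]) return(numeric(0))
    q <- unique(stats::quantile(B[, b], probs = (1:knots) / (knots + 1),
                                names = FALSE, type = 7))
    q[q > lo[b] & q < hi[b]]
  })
  names(knot_list) <- bands
  feat <- list()
  add <- function(type, band, band2 = NA_character_, knot = NA_real_) {
    feat[[length(feat) + 1]] <<- data.frame(
      type = type, band = band, band2 = band2, knot = knot,
      stringsAsFactors = FALSE)
  }
  if ("linear" %in% classes) for (b in bands) add("linear", b)
  if ("quadratic" %in% classes) for (b in bands) add("quadratic", b)
  if ("product" %in% classes && length(bands) > 1) {
    cmb <- utils::combn(bands, 2)
    for (j in seq_len(ncol(cmb))) add("product", cmb[1, j], cmb[2, j])
  }
  if ("hinge" %in% classes) {
    for (b in bands) for (k in knot_list[[b]]) {
      add("hinge_fwd", b, knot = k)
      add("hinge_rev", b, knot = k)
    }
  }
  if ("threshold" %in% classes) {
    for (b in bands) for (k in knot_list[[b]]) add("threshold", b, knot = k)
  }
  table <- do.call(rbind, feat)
  structure(list(classes = classes, bands = bands, lo = lo, hi = hi,
                 knots = knot_list, knots_requested = knots, table = table),
            class = "feature_expansion")
}

#' Number of features in an expansion
#' @param expansion a [build_expansion()] result.
#' @export
n_features <- function(expansion) nrow(expansion$table)

feature_names <- function(expansion) {
  t <- expansion$table
  ifelse(t$type == "product", paste0("prod:", t$band, "*", t$band2),
  ifelse(is.na(t$knot), paste0(substr(t$type, 1, 4), ":", t$band),
         paste0(t$type, ":", t$band, "@", signif(t$knot, 8))))
}

#' Evaluate the feature expansion on raw band values
#'
#' @param expansion a [build_expansion()] result.
#' @param X numeric matrix of raw values with one named column per expanded
#'   band (see [cell_values()]).
#' @return Matrix with one row per input row and one column per feature,
#'   all values in `[0, 1]`.
#' @export
expand_features <- function(expansion, X) {
  missing <- setdiff(expansion$bands, colnames(X))
  if (length(missing)) stopf("input lacks band '%s'", missing[1])
  n <- nrow(X)
  scaled <- vapply(expansion$bands, function(b) {
    if (expansion$hi[b] > expansion$lo[b]) {
      clamp01((X[, b] - expansion$lo[b]) / (expansion$hi[b] - expansion$lo[b]))
    } else {
      rep(0.5, n)
    }
  }, numeric(n))
  if (n == 1L) scaled <- matrix(scaled, 1, dimnames = list(NULL, expansion$bands))
  t <- expansion$table
  out <- matrix(0, n, nrow(t))
  for (j in seq_len(nrow(t))) {
    b <- t$band[j]
    out[, j] <- switch(t$type[j],
      linear = scaled[, b],
      quadratic = scaled[, b]^2,
      product = scaled[, b] * scaled[, t$band2[j]],
      hinge_fwd = clamp01((X[, b] - t$knot[j]) / (expansion$hi[b] - t$knot[j])),
      hinge_rev = clamp01((t$knot[j] - X[, b]) / (t$knot[j] - expansion$lo[b])),
      threshold = as.numeric(X[, b] >= t$knot[j]))
  }
  colnames(out) <- feature_names(expansion)
  out
}

#' Per-feature default regularization weights
#'
#' Default per-feature L1 penalties following the published MaxEnt
#' defaults: a class- and sample-size-dependent base value (linear/
#' quadratic/product interpolated over presence counts 0/10/30/100 from
#' 1/1/0.2/0.05; hinge constant 0.5; threshold from 2 at n=0 to 1 at
#' n>=100) scaled by `sd(feature at presences) / sqrt(n)`. The final
#' penalty is `reg_multiplier` times this weight.
#'
#' @param expansion a [build_expansion()] result.
#' @param Fp feature matrix at presences (from [expand_features()]).
#' @param reg_multiplier positive regularization (rate) multiplier.
#' @return Numeric vector of per-feature penalties.
#' @export
default_betas <- function(expansion, Fp, reg_multiplier) {
  if (reg_multiplier <= 0) stopf("reg_multiplier must be > 0")
  n <- nrow(Fp)
  base_for <- function(type) {
    switch(type,
      linear = , quadratic = , product =
        stats::approx(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05), n, rule = 2)$y,
      hinge_fwd = , hinge_rev = 0.5,
      threshold = stats::approx(c(0, 100), c(2, 1), n, rule = 2)$y)
  }
  sds <- apply(Fp, 2, stats::sd)
  if (n < 2) sds[] <- 0
  sds <- pmax(sds, 0.001)  # floor keeps constant-at-presence features penalized
  base <- vapply(expansion$table$type, base_for, 0)
  reg_multiplier * base * sds / sqrt(max(n, 1))
}
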