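# Independent brute-force oracles used by the metric and solver tests.

# Exhaustive pairwise comparison for the rank-sum AUC.
auc_oracle <- function(p, b) {
  wins <- 0
  for (x in p) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(p) * length(b))
}

# Naive full scan over all candidate thresholds for the TSS optimum.
tss_oracle <- function(p, b) {
  cand <- sort(unique(c(p, b)))
  best <- c(threshold = NA_real_, tss = -Inf)
  for (t in cand) {
    tss <- mean(p >= t) + mean(b < t) - 1
    if (tss > best["tss"]) best <- c(threshold = t, tss = tss)
  }
  best
}

# Iteratively refined dense grid search over the penalized maximum-entropy
# objective; independent of the proximal-gradient path.
grid_oracle <- function(Fp, Fb, beta, lo = -6, hi = 6, points = 13, rounds = 6) {
  p <- ncol(Fp)
  fbar <- colMeans(Fp)
  objective <- function(lam) {
    eta <- drop(Fb %*% lam)
    m <- max(eta)
    sum(fbar * lam) - (m + log(sum(exp(eta - m)))) - sum(beta * abs(lam))
  }
  centers <- rep(0, p)
  width <- hi - lo
  for (round in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(j) {
      seq(centers[j] - width / 2, centers[j] + width / 2, length.out = points)
    })
    cand <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(cand, 1, objective)
    centers <- cand[which.max(vals), ]
    width <- width * 2 / (points - 1)
  }
  centers
}
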