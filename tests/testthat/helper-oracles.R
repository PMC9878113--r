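# Independent brute-force oracles used to cross-check the package's
# statistical primitives. Deliberately naive implementations that share no
# code path with the functions they validate.

# Step-up FDR adjustment straight from the definition: the adjusted value of
# element i is the minimum of m * p_(j) / j over all order statistics with
# p_(j) >= p_i (value comparison, so ties resolve to the largest index).
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  sorted <- p[ord]
  vapply(p, function(pi) {
    js <- which(sorted >= pi)
    min(1, min(m * sorted[js] / js))
  }, numeric(1))
}

# Spearman rho via explicit mid-rank assignment plus the Pearson formula
# written out by hand.
oracle_spearman <- function(x, y) {
  midrank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# AUC by exhaustive enumeration of all positive-negative score pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# O(n^3) UPGMA: clusters as index sets; the inter-cluster distance is the
# mean of all member-pair Euclidean distances, recomputed from scratch at
# every step. Returns the sorted merge heights.
oracle_upgma_heights <- function(m) {
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

# Small deterministic expression matrix for unit tests.
toy_matrix <- function(values, platform = "miRNA", scale = "raw",
                       detected = NULL) {
  expr_matrix(values, detected = detected, scale = scale, platform = platform)
}
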