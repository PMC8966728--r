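# Independent reference implementations used only as test oracles.
# Each is a direct, unoptimized transcription of the defining formula and
# shares no code with the package internals it checks.

# Naive O(n^3) agglomerative Ward clustering. Cluster distance is the
# closed form sqrt(2 |A||B| / (|A|+|B|)) * ||centroid_A - centroid_B||
# (the square-root Ward cost, whose singleton case is the Euclidean
# distance). Returns the sequence of merge heights.
oracle_ward_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        ca <- colMeans(x[clusters[[a]], , drop = FALSE])
        cb <- colMeans(x[clusters[[b]], , drop = FALSE])
        na <- length(clusters[[a]]); nb <- length(clusters[[b]])
        d <- sqrt(2 * na * nb / (na + nb)) * sqrt(sum((ca - cb)^2))
        if (d < best[1]) best <- c(d, a, b)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Direct per-point silhouette: a = mean distance to own cluster, b =
# smallest mean distance to another cluster, s = (b - a)/max(a, b);
# singleton clusters contribute 0.
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  dm <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(dm[i, own])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dm[i, labels == l]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force Pearson r, t statistic, and two-sided p from the defining
# sums, without cor()/cor.test().
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  r <- num / den
  df <- n - 2
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# Best rank-k approximation error via dense eigendecomposition of X'X:
# ||X - X_k||_F^2 = sum of the discarded eigenvalues of X'X.
oracle_rank_k_error <- function(x, k) {
  ev <- eigen(crossprod(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  sqrt(sum(ev[-seq_len(k)]))
}

# Plain cosine of two vectors.
oracle_cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
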