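# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# classical pooled-variance two-sample t statistic
oracle_two_sample_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# classical one-way ANOVA F statistic
oracle_anova_F <- function(y, f) {
  f <- factor(f)
  gm <- mean(y)
  ssb <- sum(tapply(y, f, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, f, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(f) - 1; df2 <- length(y) - nlevels(f)
  (ssb / df1) / (ssw / df2)
}

# one-sided (greater) hypergeometric tail by direct log-choose summation:
# P(X >= a) with X ~ Hyper(universe N, set size K, draws n)
oracle_hyper_tail <- function(a, K, N, n) {
  ks <- a:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (length(ks) == 0) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# exhaustive best Gini split over all features and observation midpoints;
# returns the feature, threshold and impurity decrease of the best split
oracle_best_gini_split <- function(X, y) {
  y <- factor(y)
  gini <- function(lab) {
    p <- table(lab) / length(lab)
    1 - sum(p^2)
  }
  n <- length(y)
  parent <- gini(y)
  best <- list(gain = -Inf)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    cuts <- sort(unique(v))
    if (length(cuts) < 2) next
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (th in mids) {
      l <- y[v < th]; r <- y[v >= th]
      gain <- parent - (length(l) * gini(l) + length(r) * gini(r)) / n
      if (gain > best$gain)
        best <- list(feature = colnames(X)[j], threshold = th, gain = gain)
    }
  }
  best
}
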