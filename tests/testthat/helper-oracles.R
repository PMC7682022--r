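# Independent brute-force oracles: plain double loops over the defining
# formulas, deliberately sharing no code with the package implementations.

oracle_prs <- function(X, w) {
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    s <- 0
    for (j in seq_len(ncol(X))) s <- s + X[i, j] * w[j]
    out[i] <- s
  }
  out
}

oracle_percentile <- function(scores, ancestry) {
  out <- numeric(length(scores))
  for (i in seq_along(scores)) {
    grp <- which(ancestry == ancestry[i])
    c_less <- sum(scores[grp] < scores[i])
    c_equal <- sum(scores[grp] == scores[i])
    out[i] <- 100 * (c_less + 0.5 * c_equal) / length(grp)
  }
  out
}

oracle_r2 <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  cov <- sum((a - ma) * (b - mb)) / (n - 1)
  va <- sum((a - ma)^2) / (n - 1); vb <- sum((b - mb)^2) / (n - 1)
  if (va == 0 || vb == 0) return(0)
  (cov / sqrt(va * vb))^2
}

oracle_fscore <- function(imp, tru) {
  f1s <- c()
  for (cl in sort(unique(tru))) {
    tp <- sum(imp == cl & tru == cl)
    p <- if (sum(imp == cl) == 0) 0 else tp / sum(imp == cl)
    r <- tp / sum(tru == cl)
    f1s <- c(f1s, if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
  mean(f1s)
}

oracle_iqs <- function(imp, tru) {
  n <- length(tru)
  p_obs <- sum(imp == tru) / n
  p_exp <- 0
  for (cl in 0:2) p_exp <- p_exp + (sum(imp == cl) / n) * (sum(tru == cl) / n)
  if (abs(1 - p_exp) < 1e-12) return(if (p_obs >= 1 - 1e-12) 1 else 0)
  (p_obs - p_exp) / (1 - p_exp)
}

# Gini per individual over all ordered replicate pairs, averaged.
oracle_gini_variant <- function(X) {
  K <- ncol(X)
  g <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    s <- 0
    for (a in seq_len(K)) for (b in seq_len(K)) s <- s + abs(X[i, a] - X[i, b])
    m <- mean(X[i, ])
    g[i] <- if (m == 0 || s == 0) 0 else s / (2 * K^2 * m)
  }
  mean(g)
}

oracle_pve <- function(w, X) {
  v <- numeric(length(w))
  for (j in seq_along(w)) {
    x <- X[, j]
    m <- sum(x) / length(x)
    v[j] <- w[j]^2 * sum((x - m)^2) / (length(x) - 1)
  }
  100 * v / sum(v)
}

oracle_range_counts <- function(reps_pct, thresholds) {
  n <- nrow(reps_pct)
  rng <- numeric(n)
  for (i in seq_len(n)) rng[i] <- max(reps_pct[i, ]) - min(reps_pct[i, ])
  c(sum(rng <= 1), sapply(thresholds, function(t) sum(rng > t)))
}

oracle_tier <- function(pct, cuts) {
  if (pct < cuts[1]) "low" else if (pct > cuts[2]) "high" else "intermediate"
}

oracle_tier_matrix <- function(reps_pct, cuts) {
  labels <- c("low", "intermediate", "high")
  M <- matrix(0, 3, 3, dimnames = list(labels, labels))
  n <- nrow(reps_pct); K <- ncol(reps_pct)
  for (i in seq_len(n)) {
    col_tier <- oracle_tier(mean(reps_pct[i, ]), cuts)
    for (k in seq_len(K)) {
      row_tier <- oracle_tier(reps_pct[i, k], cuts)
      M[row_tier, col_tier] <- M[row_tier, col_tier] + 1
    }
  }
  100 * M / (n * K)
}

oracle_highrisk_rate <- function(wgs, reps_pct, direction, cut) {
  in_tier <- if (direction == "<") wgs < cut else wgs > cut
  m <- sum(in_tier)
  if (m == 0) return(NA_real_)
  n_re <- 0
  for (i in which(in_tier)) {
    outside <- if (direction == "<") sum(reps_pct[i, ] >= cut)
               else sum(reps_pct[i, ] <= cut)
    if (outside >= 2) n_re <- n_re + 1
  }
  100 * n_re / m
}
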