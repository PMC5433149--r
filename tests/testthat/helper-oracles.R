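# Brute-force / closed-form oracles, coded independently of the package
# implementations they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quantile normalization: sort each column, average across columns rank by
# rank, map back through each column's rank; ties get the mean of their
# rank-span targets via explicit grouping.
oracle_quantile_normalize <- function(x) {
  n <- nrow(x)
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    ord <- order(col)
    vals <- numeric(n)
    vals[ord] <- target
    for (v in unique(col)) {
      idx <- which(col == v)
      vals[idx] <- mean(vals[idx])
    }
    out[, j] <- vals
  }
  out
}

# Benjamini-Hochberg step-up: q_i = min_{j >= i} m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[ord][i:m] / (i:m))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Elementwise-loop Tanimoto kernel.
oracle_tanimoto <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(B))) {
    a <- A[i, ]; b <- B[, j]
    num <- sum(a * b)
    out[i, j] <- num / sqrt(sum(a^2) + sum(b^2) - abs(num))
  }
  out
}

# Mann-Whitney AUC of scores for a binary outcome (ties count half).
oracle_binary_auc <- function(scores, is_case) {
  cs <- scores[is_case]; ct <- scores[!is_case]
  cmp <- outer(cs, ct, `>`) + 0.5 * outer(cs, ct, `==`)
  mean(cmp)
}

# Two-sided Fisher exact p by full enumeration of tables with the observed
# margins: sum hypergeometric probabilities <= observed table's.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho via the explicit rank formula with average ties.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# One-sample two-sided KS statistic against Uniform(0,1).
oracle_ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

# Rank-based AUC separating lab==1 from lab==0 scores.
rank_auc <- function(scores, lab) {
  r <- rank(scores)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Kaplan-Meier survival at time t, aggregated d/n tie formula (independent
# of the package's sequential-product internal).
oracle_km_at <- function(time, event, t) {
  s <- 1
  for (u in sort(unique(time[event == 1 & time <= t]))) {
    d <- sum(time == u & event == 1)
    n_at <- sum(time >= u)
    s <- s * (1 - d / n_at)
  }
  s
}

# Naive O(n^3) average-linkage agglomeration: returns the sorted sequence of
# merge heights (cluster-average distances) for a distance matrix.
oracle_average_linkage_heights <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d_ij <- mean(dmat[clusters[[i]], clusters[[j]]])
      if (d_ij < best_d) { best_d <- d_ij; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}
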