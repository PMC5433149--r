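#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns with average linkage, the
#' convention for expression-based subtype discovery, cut to exactly `k`
#' clusters. The default distance is 1 - Pearson correlation between sample
#' profiles; Euclidean distance is available for signals that are uniform
#' shifts (which correlation distance cannot see).
#'
#' @param x features x samples expression matrix.
#' @param k number of clusters (default 2, the two-subtype hypothesis).
#' @param distance `"correlation"` or `"euclidean"`.
#' @return object of class `cluster_assignment`: `sample_ids`, `labels`
#'   (integers 1..k, contiguous), `merge`, `height`, `distance`.
#' @export
hierarchical_cluster <- function(x, k = 2L,
                                 distance = c("correlation", "euclidean")) {
  check_expression_matrix(x)
  distance <- match.arg(distance)
  n <- ncol(x)
  if (k > n) stop("k must not exceed the number of samples")
  if (k < 1) stop("k must be at least 1")
  d <- switch(distance,
              correlation = stats::as.dist(1 - stats::cor(x)),
              euclidean = stats::dist(t(x)))
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = k)
  labels <- as.integer(factor(raw, levels = unique(raw)))  # contiguous 1..k
  structure(list(sample_ids = colnames(x), labels = labels,
                 merge = hc$merge, height = hc$height,
                 distance = distance, k = as.integer(k)),
            class = "cluster_assignment")
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' Classical MDS on Euclidean sample distances, which is algebraically PCA of
#' the centered data: the standard 3-D representation of sample locations in
#' expression space.
#'
#' @param x features x samples expression matrix.
#' @param dims embedding dimension (default 3).
#' @return samples x dims coordinate matrix.
#' @export
classical_mds <- function(x, dims = 3L) {
  check_expression_matrix(x)
  if (dims < 1) stop("dims must be at least 1")
  if (dims > ncol(x) - 1) stop("dims must be at most n_samples - 1")
  coords <- stats::cmdscale(stats::dist(t(x)), k = dims)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}

# Vectorized Welch two-sample t-test across matrix rows; returns statistic
# (group2 - group1 direction), p, and a flag for degenerate rows.
row_welch_t <- function(x, g1, g2) {
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  degen <- !is.finite(stat)
  stat[degen] <- 0; p[degen] <- 1
  list(statistic = stat, p = p, direction = ifelse(m2 >= m1, "up", "down"),
       degenerate = degen)
}

#' Two-group differential expression with Benjamini-Hochberg FDR
#'
#' Per-feature two-sided Welch t-test (`method = "t"`) or Mann-Whitney U test
#' (`method = "mann_whitney"`) between the two label groups, with BH q-values
#' and the direction of change in the second group. Constant features under
#' the t-test get statistic 0 and p = 1 with a warning.
#'
#' @param x features x samples expression matrix.
#' @param labels two-level grouping, one per sample.
#' @param method `"t"` (default) or `"mann_whitney"`.
#' @return data.frame of class `differential_table`: `feature`, `statistic`,
#'   `p`, `q`, `direction` (up/down in the second group level).
#' @export
two_group_test <- function(x, labels, method = c("t", "mann_whitney")) {
  check_expression_matrix(x)
  method <- match.arg(method)
  g <- factor(labels)
  if (length(g) != ncol(x)) stop("labels must match sample columns")
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("exactly two non-empty groups are required")
  g1 <- which(g == levels(g)[1]); g2 <- which(g == levels(g)[2])
  if (method == "t") {
    if (length(g1) < 2 || length(g2) < 2)
      stop("t-test requires at least 2 samples per group")
    res <- row_welch_t(x, g1, g2)
    if (any(res$degenerate))
      warning(sum(res$degenerate),
              " constant feature(s): statistic set to 0, p to 1")
  } else {
    stats_p <- apply(x, 1, function(v) {
      wt <- suppressWarnings(stats::wilcox.test(v[g2], v[g1]))
      c(wt$statistic, wt$p.value)
    })
    res <- list(statistic = stats_p[1, ], p = stats_p[2, ],
                direction = ifelse(apply(x, 1, function(v)
                  stats::median(v[g2]) >= stats::median(v[g1])), "up", "down"))
  }
  out <- data.frame(feature = rownames(x), statistic = res$statistic,
                    p = res$p, q = stats::p.adjust(res$p, method = "BH"),
                    direction = res$direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Random-splits null for the observed differential-expression count
#'
#' Statistic: the number of features differentially expressed at `p < alpha`
#' (Welch t). Null: `n_splits` random relabelings of the samples preserving
#' the observed group sizes. Empirical p is the fraction of random splits
#' reaching at least the observed count — the published rule declares the
#' subtypes significant when fewer than 5% of 100 random splits do.
#'
#' @param x features x samples expression matrix.
#' @param labels observed two-level grouping.
#' @param n_splits number of random splits (>= 20; default 100).
#' @param alpha per-feature significance threshold (default 0.05).
#' @param seed integer seed.
#' @return list: `observed_count`, `null_counts`, `empirical_p`.
#' @export
random_split_null <- function(x, labels, n_splits = 100L, alpha = 0.05,
                              seed = 1L) {
  check_expression_matrix(x)
  g <- factor(labels)
  if (n_splits < 20) stop("n_splits must be at least 20")
  if (nlevels(g) != 2 || any(table(g) < 2))
    stop("two groups with at least 2 samples each are required")
  g2_lv <- levels(g)[2]
  n2 <- sum(g == g2_lv)
  n <- ncol(x)
  count_de <- function(idx2) {
    idx1 <- setdiff(seq_len(n), idx2)
    sum(row_welch_t(x, idx1, idx2)$p < alpha)
  }
  observed <- count_de(which(g == g2_lv))
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_splits), function(i) count_de(sample.int(n, n2)),
           numeric(1))
  })
  list(observed_count = observed, null_counts = null_counts,
       empirical_p = mean(null_counts >= observed))
}

#' Concordance of two binary classifications by Fisher's exact test
#'
#' @param labels_a,labels_b binary labelings of the same samples.
#' @return list: `table` (2 x 2), `odds_ratio`, `p` (two-sided exact).
#' @export
fisher_concordance <- function(labels_a, labels_b) {
  a <- factor(labels_a); b <- factor(labels_b)
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (nlevels(a) != 2 || nlevels(b) != 2)
    stop("both labelings must be binary (exactly two levels each)")
  tab <- table(a, b)
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Hypergeometric test for the overlap of two feature lists
#'
#' `p = P(X >= observed overlap)` for X hypergeometric with the given
#' universe size — the standard enrichment test for the overlap of two
#' differential-expression lists.
#'
#' @param list_a,list_b character vectors of feature ids (deduplicated).
#' @param universe either the universe size (a single number) or the
#'   character vector of all features, in which case membership is checked.
#' @return list: `overlap`, `p`, `n_a`, `n_b`, `universe_size`.
#' @export
hypergeometric_overlap <- function(list_a, list_b, universe) {
  a <- unique(as.character(list_a)); b <- unique(as.character(list_b))
  if (is.character(universe)) {
    u <- unique(universe)
    bad <- setdiff(c(a, b), u)
    if (length(bad))
      stop("list items outside the universe: ", paste(bad, collapse = ", "))
    n_u <- length(u)
  } else {
    n_u <- as.integer(universe)
    if (length(a) > n_u || length(b) > n_u)
      stop("a list is larger than the stated universe")
  }
  ov <- length(intersect(a, b))
  p <- stats::phyper(ov - 1, length(a), n_u - length(a), length(b),
                     lower.tail = FALSE)
  list(overlap = ov, p = p, n_a = length(a), n_b = length(b),
       universe_size = n_u)
}

#' Construct a gene set
#' @param name set name.
#' @param members unique, non-empty member feature ids.
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  if (!length(members)) stop("gene set must be non-empty")
  if (anyDuplicated(members)) stop("gene set members must be unique")
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' KS/LS functional class scoring of a gene set
#'
#' Given per-feature p-values from a differential analysis, scores the set
#' with LS = mean of -ln(p) over the set and KS = one-sample two-sided
#' Kolmogorov-Smirnov statistic of the set's p-values against Uniform(0,1).
#' Significance comes from permuting which features form the set.
#'
#' @param pvalues named vector of per-feature p-values (all features).
#' @param set a [gene_set()]; members are intersected with `names(pvalues)`.
#' @param n_perm number of set permutations (>= 99).
#' @param seed integer seed.
#' @return list: `ls`, `ks`, `p_ls`, `p_ks`, `set_size`, `n_perm`.
#' @export
gene_set_ks_ls <- function(pvalues, set, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(set, "gene_set"))
  if (is.null(names(pvalues))) stop("pvalues must be named by feature id")
  if (n_perm < 99) stop("n_perm must be at least 99")
  members <- intersect(set$members, names(pvalues))
  if (!length(members)) stop("gene set is empty after intersecting features")
  ls_stat <- function(p) mean(-log(p))
  ks_stat <- function(p)
    unname(suppressWarnings(stats::ks.test(p, "punif"))$statistic)
  obs_p <- pvalues[members]
  ls_obs <- ls_stat(obs_p); ks_obs <- ks_stat(obs_p)
  m <- length(members)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- pvalues[sample.int(length(pvalues), m)]
      c(ls_stat(p), ks_stat(p))
    }, numeric(2))
  })
  list(ls = ls_obs, ks = ks_obs,
       p_ls = (1 + sum(perms[1, ] >= ls_obs)) / (n_perm + 1),
       p_ks = (1 + sum(perms[2, ] >= ks_obs)) / (n_perm + 1),
       set_size = m, n_perm = n_perm)
}
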