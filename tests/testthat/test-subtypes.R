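expr_mat <- function(v, nr, nc) {
  matrix(v, nr, nc, dimnames = list(sprintf("f%03d", seq_len(nr)),
                                    sprintf("s%03d", seq_len(nc))))
}

test_that("average-linkage clustering recovers separated blobs and reproduces a hand-worked merge trace", {
  set.seed(8)
  blob <- cbind(matrix(rnorm(20 * 10), 20, 10),
                matrix(rnorm(20 * 10, mean = 8), 20, 10))
  dimnames(blob) <- list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:20))
  cl <- hierarchical_cluster(blob, k = 2, distance = "euclidean")
  truth <- rep(1:2, each = 10)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  expect_setequal(unique(cl$labels), 1:2)

  # 4 one-dimensional points at 0, 1, 5, 11: average linkage merges
  # (s1,s2) at d=1; then {s1,s2} joins s3 at mean(|0-5|,|1-5|) = 4.5
  # (smaller than d(s3,s4) = 6); finally s4 joins at mean(11,10,6) = 9
  x4 <- expr_mat(c(0, 1, 5, 11), 1, 4)
  cl4 <- hierarchical_cluster(x4, k = 2, distance = "euclidean")
  hc <- stats::hclust(stats::dist(t(x4)), method = "average")
  expect_equal(hc$height, c(1, 4.5, 9))
  expect_equal(cl4$merge, hc$merge)
  expect_equal(length(unique(cl4$labels[1:3])), 1L)  # s1,s2,s3 together
  expect_false(cl4$labels[4] == cl4$labels[1])

  # duplicating every sample preserves the structure on the duplicates
  dup <- cbind(blob, blob)
  colnames(dup) <- sprintf("s%02d", 1:40)
  cld <- hierarchical_cluster(dup, k = 2, distance = "euclidean")
  expect_equal(cld$labels[1:20], cld$labels[21:40])
  expect_error(hierarchical_cluster(blob, k = 21), "exceed")
})

test_that("clustering is invariant to sample column permutation up to label names", {
  co <- generate_cohort(cohort_config(n_samples = 30L, n_features = 40L,
                                      n_cluster_features = 10L, seed = 5L))
  x <- co$expression
  set.seed(2); perm <- sample(ncol(x))
  a <- hierarchical_cluster(x, k = 2, distance = "euclidean")$labels
  b <- hierarchical_cluster(x[, perm], k = 2, distance = "euclidean")$labels
  restored <- integer(length(b)); restored[perm] <- b
  expect_equal(mclust::adjustedRandIndex(a, restored), 1)
})

test_that("classical MDS embeds exact low-rank data and matches PCA scores", {
  set.seed(12)
  pts <- matrix(rnorm(3 * 15), 3, 15)  # 15 samples living in 3-D
  dimnames(pts) <- list(paste0("d", 1:3), sprintf("s%02d", 1:15))
  coords <- classical_mds(pts, dims = 3)
  expect_equal(as.matrix(dist(coords)), as.matrix(dist(t(pts))),
               tolerance = 1e-10, ignore_attr = TRUE)
  # identity with PCA of centered data, up to axis sign
  pc <- prcomp(t(pts), center = TRUE, scale. = FALSE)$x[, 1:3]
  for (j in 1:3)
    expect_equal(abs(coords[, j]), abs(pc[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  expect_error(classical_mds(pts, dims = 0), "dims")
  expect_error(classical_mds(pts, dims = 15), "dims")
})

test_that("two-group t statistics match a hand-worked toy and BH matches the step-up oracle", {
  a <- c(1.1, 2.3, 1.9, 3.0, 2.2)
  b <- c(2.8, 3.9, 3.1, 4.4, 3.6)
  x <- expr_mat(c(a, b), 1, 10)
  lab <- rep(c("g1", "g2"), each = 5)
  res <- two_group_test(x, lab)
  ref <- t.test(x[1, 6:10], x[1, 1:5])      # Welch, group2 - group1
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$direction, "up")

  # BH on p = (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(50)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }

  # q >= p elementwise and monotone in sorted order
  set.seed(14)
  xx <- expr_mat(rnorm(300), 30, 10)
  rr <- two_group_test(xx, rep(c("a", "b"), each = 5))
  expect_true(all(rr$q >= rr$p - 1e-15))
  o <- order(rr$p)
  expect_true(all(diff(rr$q[o]) >= -1e-15))
})

test_that("two-group tests flag constant features and support Mann-Whitney", {
  x <- rbind(rep(1, 10), rnorm(10))
  dimnames(x) <- list(c("const", "ok"), sprintf("s%03d", 1:10))
  expect_warning(res <- two_group_test(x, rep(c("a", "b"), each = 5)),
                 "constant")
  expect_equal(res$p[1], 1)
  expect_equal(res$statistic[1], 0)

  set.seed(15)
  y <- expr_mat(rnorm(40), 4, 10)
  lab <- rep(c("a", "b"), each = 5)
  mw <- two_group_test(y, lab, method = "mann_whitney")
  for (i in 1:4) {
    ref <- suppressWarnings(wilcox.test(y[i, 6:10], y[i, 1:5]))
    expect_equal(mw$p[i], ref$p.value, tolerance = 1e-10)
  }
  expect_error(two_group_test(y, rep("a", 10)), "two non-empty")
})

test_that("random-splits null returns one count per split and detects planted subtypes", {
  co <- generate_cohort(cohort_config(n_samples = 50L, n_features = 100L,
                                      n_cluster_features = 20L,
                                      effect_size_delta = 1.5, seed = 31L))
  rs <- random_split_null(co$expression, co$subtype, n_splits = 100,
                          seed = 9L)
  expect_length(rs$null_counts, 100)
  expect_lt(rs$empirical_p, 0.05)
  expect_gte(rs$observed_count, max(rs$null_counts))
  expect_error(random_split_null(co$expression, co$subtype, n_splits = 10),
               "20")
})

test_that("Fisher concordance matches full enumeration and is symmetric", {
  a <- rep(c(0, 1), each = 5)
  b <- rep(c(0, 1), each = 5)
  fc <- fisher_concordance(a, b)
  expect_equal(fc$p, oracle_fisher_2x2(fc$table), tolerance = 1e-12)
  expect_equal(fc$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_concordance(b, a)$p, fc$p)

  set.seed(18)
  for (i in 1:25) {
    n <- sample(8:25, 1)
    aa <- rbinom(n, 1, 0.5); bb <- rbinom(n, 1, 0.5)
    if (length(unique(aa)) < 2 || length(unique(bb)) < 2) next
    fc2 <- fisher_concordance(aa, bb)
    expect_equal(fc2$p, oracle_fisher_2x2(fc2$table), tolerance = 1e-9)
  }
  expect_error(fisher_concordance(c(1, 2, 3), c(1, 1, 2)), "binary")
})

test_that("hypergeometric overlap matches the pmf enumeration", {
  u <- sprintf("m%02d", 1:20)
  a <- u[1:5]; b <- u[c(1:4, 10)]
  ho <- hypergeometric_overlap(a, b, u)
  expect_equal(ho$overlap, 4)
  expect_equal(ho$p, sum(dhyper(4:5, 5, 15, 5)), tolerance = 1e-12)
  # saturated: both lists fill the universe
  sat <- hypergeometric_overlap(u, u, u)
  expect_equal(sat$p, 1)
  expect_equal(sat$overlap, 20)
  # disjoint lists: overlap 0, p near 1
  dj <- hypergeometric_overlap(u[1:5], u[6:10], u)
  expect_equal(dj$overlap, 0)
  expect_gt(dj$p, 0.8)
  expect_error(hypergeometric_overlap(c(a, "zz"), b, u), "outside")
})

test_that("KS/LS statistics have their closed forms and match the hand-worked KS", {
  p_all <- setNames(runif(50), sprintf("g%02d", 1:50))
  p_all[c("g01", "g02", "g03")] <- 1
  s1 <- gene_set_ks_ls(p_all, gene_set("ones", c("g01", "g02", "g03")),
                       n_perm = 99, seed = 1L)
  expect_equal(s1$ls, 0)
  p_all[c("g04", "g05")] <- exp(-1)
  s2 <- gene_set_ks_ls(p_all, gene_set("e", c("g04", "g05")),
                       n_perm = 99, seed = 1L)
  expect_equal(s2$ls, 1)
  # KS for p-values (0.1, 0.2, 0.9): sup deviation from uniform CDF
  p_all[c("g06", "g07", "g08")] <- c(0.1, 0.2, 0.9)
  s3 <- gene_set_ks_ls(p_all, gene_set("ks", c("g06", "g07", "g08")),
                       n_perm = 99, seed = 1L)
  expect_equal(s3$ks, oracle_ks_uniform(c(0.1, 0.2, 0.9)))
  expect_equal(s3$ks, 7 / 15)   # hand: max(1/3-0.1, 2/3-0.2, 0.9-2/3) = 7/15
  expect_error(gene_set_ks_ls(p_all, gene_set("none", "zz"), n_perm = 99),
               "empty")
  # an enriched set (small p-values) is called significant
  set.seed(44)
  p_null <- setNames(runif(200), sprintf("h%03d", 1:200))
  p_null[1:10] <- p_null[1:10] / 100
  hit <- gene_set_ks_ls(p_null, gene_set("hit", names(p_null)[1:10]),
                        n_perm = 199, seed = 2L)
  expect_lt(hit$p_ls, 0.05)
  expect_lt(hit$p_ks, 0.05)
})
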