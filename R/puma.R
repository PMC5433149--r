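#' Bundle the priors for message-passing network inference
#'
#' @param W0 motif/target prior, regulators x genes, with dimnames.
#' @param P0 cooperativity (PPI) prior, regulators x regulators, symmetric
#'   with unit diagonal.
#' @param expression genes x samples matrix used to build the gene-gene
#'   Pearson coexpression prior C0.
#' @param mirna_ids regulator ids that are miRNAs (possibly empty); these
#'   regulators are barred from gaining cooperativity edges during
#'   message passing.
#' @return object of class `regulatory_priors`.
#' @export
regulatory_priors <- function(W0, P0, expression, mirna_ids = character()) {
  stopifnot(is.matrix(W0), is.matrix(P0), is.matrix(expression))
  if (is.null(rownames(W0)) || is.null(colnames(W0)))
    stop("W0 needs regulator row names and gene column names")
  if (nrow(P0) != nrow(W0) || ncol(P0) != nrow(W0))
    stop("P0 must be square with one row per regulator")
  if (max(abs(P0 - t(P0))) > 1e-12) stop("P0 must be symmetric")
  if (max(abs(diag(P0) - 1)) > 1e-12) stop("P0 must have unit diagonal")
  if (nrow(expression) != ncol(W0) ||
      !identical(rownames(expression), colnames(W0)))
    stop("expression rows must match W0 gene columns")
  mirna_ids <- as.character(mirna_ids)
  if (!all(mirna_ids %in% rownames(W0)))
    stop("mirna_ids must be a subset of the regulator ids")
  structure(list(W0 = W0, P0 = P0, expression = expression,
                 mirna_ids = mirna_ids), class = "regulatory_priors")
}

#' Row-and-column z-score normalization
#'
#' `Z_ij = [(x_ij - rowmean_i)/rowsd_i + (x_ij - colmean_j)/colsd_j] / sqrt(2)`
#' with sample (n-1) standard deviations; zero-variance rows or columns fall
#' back to the overall standard deviation with a warning. This is the
#' standard conditioning applied to all three priors before message passing.
#'
#' @param x finite numeric matrix.
#' @return the normalized matrix, dimnames preserved.
#' @export
normalize_matrix_zscores <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(!is.finite(x))) stop("matrix must be finite")
  overall_sd <- stats::sd(as.vector(x))
  if (overall_sd == 0) stop("all-constant matrix cannot be normalized")
  rs <- row_sds(x); cs <- col_sds(x)
  if (any(rs == 0, na.rm = TRUE) || any(cs == 0, na.rm = TRUE) ||
      anyNA(rs) || anyNA(cs))
    warning("zero-variance rows/columns: overall SD used as fallback")
  rs[is.na(rs) | rs == 0] <- overall_sd
  cs[is.na(cs) | cs == 0] <- overall_sd
  zr <- (x - rowMeans(x)) / rs
  zc <- sweep(sweep(x, 2, colMeans(x)), 2, cs, `/`)
  (zr + zc) / sqrt(2)
}

#' Continuous Tanimoto similarity kernel
#'
#' `T_ij = (A_i . B_j) / sqrt(||A_i||^2 + ||B_j||^2 - |A_i . B_j|)` for rows
#' of `A` against columns of `B` — the message-passing similarity used to
#' combine prior, cooperativity and coexpression evidence. Near-zero
#' denominators (both vectors null) are guarded with a small epsilon and
#' reported.
#'
#' @param A,B numeric matrices with `ncol(A) == nrow(B)`.
#' @return `nrow(A)` x `ncol(B)` similarity matrix.
#' @export
tanimoto_similarity <- function(A, B) {
  stopifnot(is.matrix(A), is.matrix(B))
  if (ncol(A) != nrow(B)) stop("inner dimensions must agree")
  num <- A %*% B
  den2 <- outer(rowSums(A^2), colSums(B^2), `+`) - abs(num)
  eps <- .Machine$double.eps
  if (any(den2 <= eps)) {
    message("tanimoto_similarity: ", sum(den2 <= eps),
            " near-zero denominator(s) guarded")
    den2[den2 <= eps] <- eps
  }
  num / sqrt(den2)
}

#' PUMA message-passing regulatory-network inference
#'
#' PANDA-style message passing between a motif prior W, a regulator
#' cooperativity prior P, and a gene coexpression prior C (Pearson
#' correlation of the supplied expression), with the PUMA constraint: after
#' every cooperativity update, the P rows and columns belonging to miRNA
#' regulators are reset to their prior values, so miRNAs never gain
#' cooperativity edges and influence their targets only through W.
#'
#' Each iteration computes the responsibility `R = T(P, W)` and availability
#' `A = T(W, C)` with the Tanimoto kernel, moves
#' `W <- (1 - alpha) W + alpha (R + A)/2`, then relaxes
#' `P <- (1 - alpha) P + alpha T(W, W^T)` and
#' `C <- (1 - alpha) C + alpha T(W^T, W)`. To prevent self-similarity
#' blow-up, each updated similarity matrix's diagonal is replaced by its own
#' off-diagonal column standard deviation (with a `sqrt((d-2)/(d-1))`
#' finite-size correction) times `d * exp(2 alpha iter)`, the annealing
#' schedule of the canonical message-passing implementation. Convergence is
#' declared when the mean absolute change in W falls below `tol`.
#'
#' @param priors a [regulatory_priors()].
#' @param alpha update rate in (0, 1), default 0.1.
#' @param tol convergence threshold on mean |delta W|, default 1e-3.
#' @param max_iter iteration cap, default 200.
#' @param check_constraint when TRUE, records the maximum deviation of the
#'   miRNA cooperativity rows from their prior at every iteration (attribute
#'   `constraint_deviation`; all zeros when the constraint holds).
#' @return object of class `inferred_network`: `scores` (regulators x genes,
#'   z-score scale), `alpha`, `iterations`, `h` (final convergence gap),
#'   `converged`.
#' @export
puma_infer <- function(priors, alpha = 0.1, tol = 1e-3, max_iter = 200L,
                       check_constraint = FALSE) {
  stopifnot(inherits(priors, "regulatory_priors"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  # annealed diagonal: off-diagonal column SD of the matrix itself,
  # scaled by dim * exp(2 * alpha * iter)
  update_diagonal <- function(M, iter) {
    d <- nrow(M)
    off <- M; diag(off) <- NA
    dstd <- apply(off, 2, stats::sd, na.rm = TRUE) * sqrt((d - 2) / (d - 1))
    diag(M) <- dstd * d * exp(2 * alpha * iter)
    M
  }
  c0 <- stats::cor(t(priors$expression))
  if (anyNA(c0)) {
    warning("constant genes in expression: coexpression entries set to 0")
    c0[is.na(c0)] <- 0
    diag(c0) <- 1
  }
  W <- normalize_matrix_zscores(priors$W0)
  P <- normalize_matrix_zscores(priors$P0)
  C <- normalize_matrix_zscores(c0)
  mir <- match(priors$mirna_ids, rownames(priors$W0))
  P_prior <- P
  h <- Inf
  dev <- if (check_constraint) numeric(max_iter) else NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    R <- tanimoto_similarity(P, W)
    A <- tanimoto_similarity(W, t(C))
    W_new <- (1 - alpha) * W + alpha * (R + A) / 2
    h <- mean(abs(W_new - W))
    W <- W_new

    P <- update_diagonal((1 - alpha) * P + alpha * tanimoto_similarity(W, t(W)),
                         iter)
    if (length(mir)) {
      P[mir, ] <- P_prior[mir, , drop = FALSE]
      P[, mir] <- P_prior[, mir, drop = FALSE]
    }
    if (check_constraint && length(mir))
      dev[iter] <- max(abs(P[mir, , drop = FALSE] -
                             P_prior[mir, , drop = FALSE]),
                       abs(P[, mir, drop = FALSE] -
                             P_prior[, mir, drop = FALSE]))

    C <- update_diagonal((1 - alpha) * C + alpha * tanimoto_similarity(t(W), W),
                         iter)

    if (h < tol) break
  }
  converged <- h < tol
  if (!converged)
    warning(sprintf("puma_infer: not converged after %d iterations (h = %g)",
                    max_iter, h))
  out <- structure(list(scores = W, alpha = alpha, iterations = iter,
                        h = h, converged = converged),
                   class = "inferred_network")
  if (check_constraint)
    attr(out, "constraint_deviation") <- dev[seq_len(iter)]
  out
}

#' @export
print.inferred_network <- function(x, ...) {
  cat(sprintf("Inferred network: %d regulators x %d genes, %s in %d iterations (h = %.2g)\n",
              nrow(x$scores), ncol(x$scores),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$h))
  invisible(x)
}

#' Edge significance between two groups via permuted-background networks
#'
#' Infers one network per group (group-specific coexpression, shared priors),
#' takes the per-edge score difference, and builds a per-edge background by
#' shuffling the sample-to-group assignment `n_perm` times and re-inferring
#' both networks. An edge is significant when its observed difference lies
#' outside four standard deviations of its own background differences — the
#' 4-SD rule.
#'
#' @param exprA,exprB genes x samples expression matrices for the two groups
#'   (same genes as the priors; >= 3 samples each).
#' @param priors a [regulatory_priors()] (its `expression` slot is ignored;
#'   group expression is supplied here).
#' @param n_perm number of label permutations (>= 10).
#' @param seed integer seed.
#' @param ... passed to [puma_infer()] (alpha, tol, max_iter).
#' @return data.frame of class `edge_table`: `regulator`, `gene`,
#'   `score_a`, `score_b`, `difference`, `background_sd`, `significant`.
#' @export
edge_significance <- function(exprA, exprB, priors, n_perm = 20L, seed = 1L,
                              ...) {
  stopifnot(inherits(priors, "regulatory_priors"))
  if (n_perm < 10) stop("n_perm must be at least 10")
  if (ncol(exprA) < 3 || ncol(exprB) < 3)
    stop("both groups need at least 3 samples for coexpression")
  if (!identical(rownames(exprA), colnames(priors$W0)) ||
      !identical(rownames(exprB), colnames(priors$W0)))
    stop("group expression genes must match the prior's genes")
  infer_scores <- function(expr) {
    pr <- priors; pr$expression <- expr
    suppressWarnings(puma_infer(pr, ...))$scores
  }
  diff_for <- function(ea, eb) infer_scores(ea) - infer_scores(eb)
  sa <- infer_scores(exprA)
  sb <- infer_scores(exprB)
  obs <- sa - sb
  pooled <- cbind(exprA, exprB)
  nA <- ncol(exprA); n <- ncol(pooled)
  perm_diffs <- with_seed(seed, {
    lapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n)
      diff_for(pooled[, idx[seq_len(nA)], drop = FALSE],
               pooled[, idx[(nA + 1):n], drop = FALSE])
    })
  })
  bg <- array(unlist(perm_diffs), dim = c(nrow(obs), ncol(obs), n_perm))
  bg_sd <- apply(bg, c(1, 2), stats::sd)
  out <- data.frame(
    regulator = rep(rownames(obs), times = ncol(obs)),
    gene = rep(colnames(obs), each = nrow(obs)),
    score_a = as.vector(sa),
    score_b = as.vector(sb),
    difference = as.vector(obs),
    background_sd = as.vector(bg_sd),
    stringsAsFactors = FALSE)
  out$significant <- abs(out$difference) > 4 * out$background_sd
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Differential targeting per regulator
#'
#' A regulator's targeting score in a network is the sum of its edge scores
#' over all genes; the differential targeting between two group networks is
#' the difference of these sums, highlighting regulators whose overall reach
#' shifts between subtypes.
#'
#' @param netA,netB `inferred_network` objects (or plain score matrices) of
#'   identical dimensions.
#' @return data.frame: `regulator`, `targeting_a`, `targeting_b`,
#'   `difference`.
#' @export
differential_targeting <- function(netA, netB) {
  sa <- if (inherits(netA, "inferred_network")) netA$scores else netA
  sb <- if (inherits(netB, "inferred_network")) netB$scores else netB
  if (!identical(dim(sa), dim(sb)))
    stop("networks must have identical dimensions")
  data.frame(regulator = rownames(sa),
             targeting_a = rowSums(sa),
             targeting_b = rowSums(sb),
             difference = rowSums(sa) - rowSums(sb),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract the most differential sub-network around seed regulators
#'
#' For each seed regulator keeps its `top_k` significant edges ranked by
#' absolute difference (fewer when fewer are significant), mirroring the
#' convention of displaying the 20 most differential edges per module.
#'
#' @param edges an `edge_table` from [edge_significance()].
#' @param seed_regulators character ids present in the table.
#' @param top_k edges kept per seed regulator (default 20).
#' @return list: `edges` (the selected rows), `node_sizes` (named edge
#'   counts per node, regulators and genes).
#' @export
extract_module <- function(edges, seed_regulators, top_k = 20L) {
  stopifnot(is.data.frame(edges))
  req <- c("regulator", "gene", "difference", "significant")
  if (!all(req %in% names(edges)))
    stop("edges must carry columns ", paste(req, collapse = ", "))
  unknown <- setdiff(seed_regulators, unique(edges$regulator))
  if (length(unknown))
    stop("unknown regulator id(s): ", paste(unknown, collapse = ", "))
  picked <- do.call(rbind, lapply(seed_regulators, function(r) {
    e <- edges[edges$regulator == r & edges$significant, , drop = FALSE]
    e[order(-abs(e$difference))[seq_len(min(top_k, nrow(e)))], ,
      drop = FALSE]
  }))
  if (is.null(picked)) picked <- edges[0, ]
  nodes <- c(picked$regulator, picked$gene)
  list(edges = picked,
       node_sizes = if (length(nodes)) table(nodes) else table(character()))
}

#' Screen genes against a drug-gene interaction table
#'
#' Case-normalized inner join of a gene list against a user-supplied
#' interaction table (columns `gene`, `drug`, `source`), with duplicate
#' (gene, drug, source) rows collapsed — the local analogue of a DGIdb
#' druggability screen for network-module genes.
#'
#' @param gene_ids character vector of gene ids.
#' @param interaction_table data.frame with columns gene, drug, source.
#' @return data.frame of matched, deduplicated rows.
#' @export
drug_interaction_screen <- function(gene_ids, interaction_table) {
  req <- c("gene", "drug", "source")
  if (!is.data.frame(interaction_table) ||
      !all(req %in% names(interaction_table)))
    stop("interaction_table must have columns gene, drug, source")
  tab <- interaction_table[, req]
  tab$gene <- toupper(tab$gene)
  tab <- unique(tab)
  hits <- tab[tab$gene %in% toupper(unique(gene_ids)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
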