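#' Quantile normalize an expression matrix
#'
#' Forces every sample (column) onto the common empirical distribution given
#' by the across-sample mean of sorted values. Tied values within a column
#' receive the mean of the target values over their rank span (average-ties
#' dialect), so the output is deterministic and idempotent.
#'
#' @param x features x samples numeric matrix with dimnames.
#' @return the normalized matrix, same dimnames, with attribute
#'   `normalized = TRUE`.
#' @export
quantile_normalize <- function(x) {
  check_expression_matrix(x)
  if (ncol(x) < 2) stop("quantile normalization needs at least 2 samples")
  target <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    # ties.method = "first" spreads a tie group over its rank span;
    # ave() then averages the target values within the group
    v <- target[rank(col, ties.method = "first")]
    stats::ave(v, col)
  })
  dimnames(out) <- dimnames(x)
  attr(out, "normalized") <- TRUE
  out
}

#' Drop the lowest-variance features
#'
#' Removes exactly `floor(drop_fraction * n_features)` features with the
#' smallest sample variance (n - 1 denominator), breaking variance ties by
#' feature id in lexicographic order so the result is deterministic. The
#' convention in the underlying analysis drops 33% of miRNA probes and 66% of
#' mRNA probes before any genome-wide analysis.
#'
#' @param x features x samples matrix with feature row names.
#' @param drop_fraction fraction in `[0, 1)` of features to drop.
#' @return the filtered matrix, original row order preserved.
#' @export
variance_filter <- function(x, drop_fraction) {
  check_expression_matrix(x)
  if (!is.numeric(drop_fraction) || length(drop_fraction) != 1 ||
      drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in [0, 1)")
  n_drop <- floor(drop_fraction * nrow(x))
  if (n_drop == 0) return(x)
  v <- row_vars(x)
  ord <- order(v, rownames(x))
  drop_ids <- rownames(x)[ord[seq_len(n_drop)]]
  x[!(rownames(x) %in% drop_ids), , drop = FALSE]
}

#' Convert methylation beta values to M-values
#'
#' `M = log2(beta / (1 - beta))`. Values outside `(eps, 1 - eps)` are clamped
#' to avoid infinite M-values; the number of clamped entries is reported as a
#' warning. M-values have better statistical properties than betas for
#' differential analysis (approximately Gaussian, unbounded support).
#'
#' @param beta matrix (or vector) of beta values in `[0, 1]`.
#' @param eps clamp threshold, default `1e-6`.
#' @return matrix/vector of M-values, dimnames preserved.
#' @seealso [m_to_beta()] for the exact inverse.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (anyNA(beta) || any(beta < 0 | beta > 1))
    stop("beta values must lie in [0, 1] with no missing entries")
  n_clamped <- sum(beta < eps | beta > 1 - eps)
  if (n_clamped > 0)
    warning(sprintf("%d beta value(s) clamped to (%g, %g)", n_clamped,
                    eps, 1 - eps))
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Invert the M-value transform
#'
#' @param m matrix/vector of M-values.
#' @return beta values `2^M / (1 + 2^M)`, strictly inside (0, 1).
#' @export
m_to_beta <- function(m) {
  if (anyNA(m) || any(!is.finite(m))) stop("M-values must be finite")
  1 / (1 + 2^(-m))
}
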