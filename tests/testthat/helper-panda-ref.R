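# Independently coded plain-PANDA reference: same message-passing equations
# as the package, written with explicit elementwise loops and no shared code,
# serving as the oracle for the matrix-algebra implementation. No miRNA
# constraint — this is the unconstrained algorithm.

ref_normalize <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  overall <- stats::sd(as.vector(x))
  z <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rs <- stats::sd(x[i, ]); cs <- stats::sd(x[, j])
    if (is.na(rs) || rs == 0) rs <- overall
    if (is.na(cs) || cs == 0) cs <- overall
    z[i, j] <- ((x[i, j] - mean(x[i, ])) / rs +
                  (x[i, j] - mean(x[, j])) / cs) / sqrt(2)
  }
  dimnames(z) <- dimnames(x)
  z
}

ref_tanimoto <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(B))) {
    num <- 0
    for (k in seq_len(ncol(A))) num <- num + A[i, k] * B[k, j]
    out[i, j] <- num / sqrt(sum(A[i, ]^2) + sum(B[, j]^2) - abs(num))
  }
  out
}

ref_update_diag <- function(M, alpha, it) {
  d <- nrow(M)
  for (j in seq_len(d)) {
    off <- M[-j, j]
    M[j, j] <- stats::sd(off) * sqrt((d - 2) / (d - 1)) * d *
      exp(2 * alpha * it)
  }
  M
}

ref_panda <- function(W0, P0, expr, alpha = 0.1, tol = 1e-3,
                      max_iter = 200L) {
  C0 <- stats::cor(t(expr))
  W <- ref_normalize(W0)
  P <- ref_normalize(P0)
  C <- ref_normalize(C0)
  for (it in seq_len(max_iter)) {
    R <- ref_tanimoto(P, W)
    A <- ref_tanimoto(W, t(C))
    W_new <- (1 - alpha) * W + alpha * (R + A) / 2
    h <- mean(abs(W_new - W))
    W <- W_new
    P <- ref_update_diag((1 - alpha) * P + alpha * ref_tanimoto(W, t(W)),
                         alpha, it)
    C <- ref_update_diag((1 - alpha) * C + alpha * ref_tanimoto(t(W), W),
                         alpha, it)
    if (h < tol) break
  }
  list(W = W, iterations = it, h = h)
}
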