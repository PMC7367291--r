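#' Seeded randomized truncated SVD
#'
#' Rank-`k` truncated singular value decomposition by random range sketching
#' with orthonormalized power iterations (the FastPCA-class algorithm).  The
#' sketch width `k + oversample` is clamped at `min(dim(A))`; when the clamp
#' binds, the sketch spans the full row/column space and the decomposition
#' is exact to machine precision.  Output is deterministic given `seed`.
#' Singular-vector sign is fixed so that the entry of largest magnitude in
#' each left singular vector is positive.
#'
#' @param A numeric matrix (M x N).
#' @param k number of singular triplets to return.
#' @param oversample extra sketch columns (default 10).
#' @param power_iters number of power iterations (default 2).
#' @param seed integer seed for the Gaussian test matrix.
#' @return list with `u` (M x k), `d` (length k), `v` (N x k).
#' @export
randomized_svd <- function(A, k, oversample = 10, power_iters = 2, seed = 1L) {
  mn <- min(dim(A))
  if (k > mn) stop("`k` exceeds min(dim(A))")
  l <- min(k + oversample, mn)
  if (l < k) stop("sketch width below k")
  with_seed(seed, {
    omega <- matrix(stats::rnorm(ncol(A) * l), ncol(A), l)
    Y <- A %*% omega
    Q <- qr.Q(qr(Y))
    for (i in seq_len(power_iters)) {
      Z <- crossprod(A, Q)
      Z <- qr.Q(qr(Z))
      Y <- A %*% Z
      Q <- qr.Q(qr(Y))
    }
    B <- crossprod(Q, A)               # l x N
    s <- svd(B, nu = k, nv = k)
    u <- Q %*% s$u
    out <- list(u = u, d = s$d[seq_len(k)], v = s$v)
    .fix_signs(out)
  })
}

# Deterministic sign convention: largest-magnitude entry of each left
# singular vector positive; right vectors flipped in step.
.fix_signs <- function(sv) {
  for (j in seq_len(ncol(sv$u))) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      if (!is.null(sv$v)) sv$v[, j] <- -sv$v[, j]
    }
  }
  sv
}

# Truncated SVD with solver selection: exact LAPACK SVD for small problems
# (randomized sketching only pays off at scale), seeded randomized SVD
# above the cutoff.  `method` forces a path.
.svd_auto <- function(A, k, seed, oversample = 10, power_iters = 2,
                      method = c("auto", "dense", "randomized"),
                      dense_cutoff = 512L) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (min(dim(A)) <= dense_cutoff) "dense" else "randomized"
  if (method == "dense") {
    s <- svd(A, nu = k, nv = k)
    .fix_signs(list(u = s$u, d = s$d[seq_len(k)], v = s$v))
  } else {
    randomized_svd(A, k, oversample = oversample, power_iters = power_iters,
                   seed = seed)
  }
}
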