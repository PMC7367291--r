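#' Classical MDS on IBS distances
#'
#' PLINK-style IBS distance `1 - W_ij / (2 M_ij)` with `M_ij` the count of
#' SNPs non-missing in both samples (the pairwise normalization mimics the
#' MDS tool the method is compared against, even though the SUGIBS degree
#' itself is unnormalized), followed by classical (Torgerson) scaling via
#' [stats::cmdscale].  MDS has no projection of new samples.
#'
#' @param x an [snp_panel].
#' @param k number of dimensions (k <= N - 1).
#' @return An object of class `ibs_mds`: list with `coordinates` (N x k,
#'   column-centered), `eigenvalues` (length k, descending), and the
#'   `distances` matrix.
#' @export
ibs_mds <- function(x, k = 8) {
  g <- as_panel(x)
  n <- n_samples(g)
  if (k > n - 1) stop("`k` must be <= N - 1")
  W <- ibs_matrix(g)$W
  obs <- (!is.na(g$genotypes)) * 1
  Mij <- crossprod(obs)
  if (any(Mij == 0))
    stop("sample pair(s) share no non-missing SNPs; distance undefined")
  D <- 1 - W / (2 * Mij)
  # cmdscale warns when asked for more dimensions than positive eigenvalues;
  # trailing dimensions are filled with zeros below
  mds <- suppressWarnings(stats::cmdscale(D, k = k, eig = TRUE))
  coords <- mds$points
  if (ncol(coords) < k) {  # cmdscale drops dimensions with nonpositive eigenvalues
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  dimnames(coords) <- list(g$samples$iid, paste0("C", seq_len(k)))
  structure(list(coordinates = coords,
                 eigenvalues = mds$eig[seq_len(k)],
                 distances = D),
            class = "ibs_mds")
}

#' @export
print.ibs_mds <- function(x, ...) {
  cat(sprintf("ibs_mds: %d samples x %d dimensions\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("eigenvalues:", format(signif(x$eigenvalues, 4)), "\n")
  invisible(x)
}
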