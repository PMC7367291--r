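#' Identity-by-state similarity matrix and similarity degrees
#'
#' Allele-sharing counts between all sample pairs.  Per SNP a pair
#' contributes 2 for identical genotypes (including het-het), 1 for a
#' heterozygote against either homozygote, 0 for opposite homozygotes, and 0
#' whenever either genotype is missing.  No missingness normalization is
#' applied.  The similarity degree of a sample is its row sum of `W`
#' including the self term (`w_ii` = twice the sample's non-missing count).
#'
#' @param g an [snp_panel] or genotype matrix.
#' @return An object of class `ibs_similarity`: list with integer matrix `W`
#'   (N x N), numeric `degrees` (length N), and sample `ids`.
#' @export
ibs_matrix <- function(g) {
  g <- as_panel(g)
  if (n_samples(g) < 1) stop("panel has no samples")
  W <- .ibs_self(g)
  structure(list(W = W, degrees = rowSums(W),
                 ids = paste(g$samples$fid, g$samples$iid)),
            class = "ibs_similarity")
}

# Within-panel specialization of .ibs_cross that builds each large
# intermediate only once (matters at biobank-ish panel sizes).
.ibs_self <- function(g) {
  x <- geno_zero(g)
  x2 <- x * x
  if (!anyNA(g$genotypes)) {
    q <- colSums(x2)
    W <- crossprod(x) + crossprod(x2)
    W <- W + 2 * nrow(x) - outer(q, rep(1, length(q))) -
      outer(rep(1, length(q)), q)
  } else {
    b <- (!is.na(g$genotypes)) * 1
    R2 <- crossprod(x2, b)
    W <- 2 * crossprod(b) + crossprod(x) + crossprod(x2) - R2 - t(R2)
  }
  round(W)
}

# Allele-sharing counts between the samples of panel `a` (rows) and panel
# `b` (columns).  For genotypes coded -1/0/1 with missing -> 0 and observed
# indicator B, the per-SNP contribution 2 - |g_i - g_j| over both-observed
# pairs expands to
#   W = 2 B_a' B_b + X_a' X_b + (X_a^2)' (X_b^2) - (X_a^2)' B_b - B_a' (X_b^2)
# which is exact in integer arithmetic (verified against the lookup table in
# the tests).
.ibs_cross <- function(a, b) {
  xa <- geno_zero(a); xb <- geno_zero(b)
  xa2 <- xa * xa; xb2 <- xb * xb
  if (!anyNA(a$genotypes) && !anyNA(b$genotypes)) {
    # fully observed: the indicator crossproducts collapse to rank-one terms
    m <- nrow(xa)
    W <- crossprod(xa, xb) + crossprod(xa2, xb2)
    W <- W + 2 * m - outer(colSums(xa2), rep(1, ncol(xb))) -
      outer(rep(1, ncol(xa)), colSums(xb2))
  } else {
    ba <- (!is.na(a$genotypes)) * 1; bb <- (!is.na(b$genotypes)) * 1
    W <- 2 * crossprod(ba, bb) + crossprod(xa, xb) + crossprod(xa2, xb2) -
      crossprod(xa2, bb) - crossprod(ba, xb2)
  }
  round(W)
}

#' IBS similarity degrees without materializing W
#'
#' Computes the same degrees as `ibs_matrix(g)$degrees` in O(MN) time and
#' memory via per-SNP genotype counts, for large panels.
#'
#' @param g an [snp_panel] or genotype matrix.
#' @return numeric vector of length N.
#' @export
ibs_degrees <- function(g) {
  g <- as_panel(g)
  x <- g$genotypes
  m <- nrow(x)
  d <- numeric(ncol(x))
  chunk <- max(1L, min(m, floor(2e7 / max(1L, ncol(x)))))
  for (s in seq(1L, m, by = chunk)) {
    rows <- s:min(s + chunk - 1L, m)
    xi <- x[rows, , drop = FALSE]
    storage.mode(xi) <- "double"
    obs <- !is.na(xi)
    x0 <- xi; x0[!obs] <- 0
    x2 <- x0 * x0
    nA <- rowSums(x0 == 1 & obs)
    nC <- rowSums(x0 == -1 & obs)
    nH <- rowSums(obs) - nA - nC
    # degree contribution of genotype g at a SNP is quadratic in g:
    #   f(g) = (nA + 2 nH + nC) + (nA - nC) g - nH g^2
    d <- d + crossprod(obs, nA + 2 * nH + nC)[, 1] +
      crossprod(x0, nA - nC)[, 1] - crossprod(x2, nH)[, 1]
  }
  d
}

#' Reference degrees of a target panel against a reference panel
#'
#' Allele-sharing counts between every target sample and every reference
#' sample, using the identical per-SNP rule as [ibs_matrix].  The reference
#' degree of a target sample is its summed similarity over the reference
#' samples only.  Panels must be harmonized (same variants, same allele
#' orientation).
#'
#' @param reference,target harmonized [snp_panel] objects.
#' @return An object of class `ibs_cross`: list with matrix `W` (N_target x
#'   N_reference), numeric `degrees` (length N_target), and target `ids`.
#' @export
cross_ibs_degrees <- function(reference, target) {
  reference <- as_panel(reference)
  target <- as_panel(target)
  if (n_variants(reference) != n_variants(target) ||
      !all(reference$variants$id == target$variants$id) ||
      !all(reference$variants$a1 == target$variants$a1) ||
      !all(reference$variants$a2 == target$variants$a2))
    stop("panels are not harmonized; run harmonize() first")
  W <- .ibs_cross(target, reference)
  structure(list(W = W, degrees = rowSums(W),
                 ids = paste(target$samples$fid, target$samples$iid)),
            class = "ibs_cross")
}

#' Unnormalized genomic relationship matrix
#'
#' `G = (1/M) X' X` with `X` the additively coded genotype matrix after
#' substituting 0 for missing genotypes.  No centering or frequency
#' standardization is applied.
#'
#' @param g an [snp_panel] or genotype matrix.
#' @return N x N symmetric numeric matrix.
#' @export
ug_relationship <- function(g) {
  g <- as_panel(g)
  if (n_variants(g) < 1) stop("panel has no variants")
  crossprod(geno_zero(g)) / n_variants(g)
}

#' Write a square similarity or degree table as TSV
#'
#' Diagnostic writer for [ibs_matrix] / [cross_ibs_degrees] results.
#'
#' @param x an `ibs_similarity` or `ibs_cross` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(x, path) {
  tab <- as.data.frame(x$W)
  tab <- cbind(id = x$ids, degree = x$degrees, tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
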