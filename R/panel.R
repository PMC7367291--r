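#' SNP genotype panel
#'
#' Container for an additively coded genotype matrix with variant and sample
#' metadata.  Genotypes are stored SNP-major (one row per variant, one column
#' per sample) using the unnormalized coding aa = -1, Aa = 0, AA = +1, where
#' `A` is the second allele of the variant record (the "counted" allele, as
#' in PLINK binary files).  Missing genotypes are `NA`; the substitution of 0
#' for missing values that some downstream methods use happens inside those
#' methods, never in the container.
#'
#' @param genotypes integer or numeric matrix, M variants x N samples, with
#'   values in \{-1, 0, 1, NA\}.
#' @param variants optional data frame with columns `chrom`, `id`, `cm`,
#'   `pos`, `a1`, `a2` (the six .bim fields).  Autogenerated when omitted.
#' @param samples optional data frame with columns `fid`, `iid`, `pat`,
#'   `mat`, `sex`, `pheno` (the six .fam fields).  Autogenerated when
#'   omitted.
#' @return An object of class `snp_panel`.
#' @examples
#' g <- snp_panel(matrix(c(-1L, 0L, 1L, NA), 2, 2))
#' dim(g)
#' @export
snp_panel <- function(genotypes, variants = NULL, samples = NULL) {
  if (!is.matrix(genotypes))
    stop("`genotypes` must be a matrix")
  storage.mode(genotypes) <- "integer"
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < -1L || max(bad) > 1L))
    stop("genotypes must be coded -1/0/1 with NA for missing")
  m <- nrow(genotypes)
  n <- ncol(genotypes)
  if (is.null(variants)) {
    variants <- data.frame(
      chrom = rep("1", m),
      id    = if (m) paste0("snp", seq_len(m)) else character(),
      cm    = rep(0, m),
      pos   = seq_len(m),
      a1    = rep("A", m),
      a2    = rep("B", m),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(samples)) {
    samples <- data.frame(
      fid   = if (n) paste0("F", seq_len(n)) else character(),
      iid   = if (n) paste0("I", seq_len(n)) else character(),
      pat   = rep("0", n),
      mat   = rep("0", n),
      sex   = rep(0L, n),
      pheno = rep(-9, n),
      stringsAsFactors = FALSE
    )
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(variants) != m)
    stop("`variants` must have one row per genotype row")
  if (nrow(samples) != n)
    stop("`samples` must have one row per genotype column")
  if (anyDuplicated(paste(samples$fid, samples$iid)))
    stop("(fid, iid) pairs must be unique")
  structure(
    list(genotypes = genotypes, variants = variants, samples = samples),
    class = "snp_panel"
  )
}

#' @export
dim.snp_panel <- function(x) dim(x$genotypes)

#' Number of variants / samples in a panel
#' @param x an `snp_panel`.
#' @return integer count.
#' @export
n_variants <- function(x) nrow(x$genotypes)

#' @rdname n_variants
#' @export
n_samples <- function(x) ncol(x$genotypes)

#' @export
print.snp_panel <- function(x, ...) {
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("snp_panel: %d variants x %d samples (%.2f%% missing)\n",
              n_variants(x), n_samples(x), 100 * miss))
  invisible(x)
}

#' Subset a panel by variant and/or sample index
#'
#' Row (variant) and column (sample) subsetting that keeps metadata in step.
#' Retained variants and samples keep their original relative order.
#'
#' @param x an `snp_panel`.
#' @param i variant index (integer or logical), missing for all.
#' @param j sample index (integer or logical), missing for all.
#' @param ... ignored.
#' @export
`[.snp_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_variants(x))
  if (missing(j)) j <- seq_len(n_samples(x))
  snp_panel(x$genotypes[i, j, drop = FALSE],
            x$variants[i, , drop = FALSE],
            x$samples[j, , drop = FALSE])
}

# Internal: genotype matrix as double with NA -> 0 (the unnormalized coding
# used by the similarity and space operations).
geno_zero <- function(x) {
  g <- x$genotypes
  storage.mode(g) <- "double"
  g[is.na(g)] <- 0
  g
}

as_panel <- function(x) {
  if (inherits(x, "snp_panel")) return(x)
  if (is.matrix(x)) return(snp_panel(x))
  stop("expected an `snp_panel` or a genotype matrix")
}
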