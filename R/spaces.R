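#' Fit a reference ancestry space
#'
#' Central fitting function for the three projectable ancestry-space
#' methods:
#' \describe{
#'   \item{`sugibs`}{Generalized spectral decomposition of the unnormalized
#'     genomic relationship matrix `G = (1/M) X'X` with respect to the
#'     diagonal IBS similarity-degree matrix `D`: components solve
#'     `G v = lambda D v` and are computed from the SVD of
#'     `X D^{-1/2}`.  The first generalized eigenvector only aggregates the
#'     average SNP pattern and is discarded, so component `j` is generalized
#'     eigenvector `j + 1`.}
#'   \item{`pca`}{PCA on frequency-standardized genotypes: per SNP,
#'     `z = (g - mu)/sigma` with `mu = 2 p - 1` and
#'     `sigma = sqrt(2 p (1 - p))` estimated from non-missing genotypes;
#'     missing values are mean-imputed (`z = 0`).}
#'   \item{`upca`}{PCA on raw, uncentered genotypes (missing as 0); the
#'     first component aggregates the average SNP pattern and is
#'     discarded.}
#' }
#' All methods store SNP loadings `L = U S^{-1}` so that new samples can be
#' projected with [predict.ancestry_space]; singular-vector signs follow a
#' deterministic convention (largest-magnitude loading entry positive).
#'
#' @param x an [snp_panel] (or genotype matrix).
#' @param k number of ancestry components (default 8).
#' @param method one of `"sugibs"`, `"pca"`, `"upca"`.
#' @param seed integer seed for the randomized SVD sketch.
#' @param svd_method `"auto"` (dense LAPACK SVD when `min(M, N) <= 512`,
#'   randomized above), `"dense"`, or `"randomized"`.
#' @param oversample,power_iters randomized-SVD sketch parameters.
#' @return An object of class `ancestry_space` with components `method`,
#'   `k`, `loadings` (M x k), `singular_values`, `scores` (N x k reference
#'   scores), `variant_keys`, and for PCA the per-SNP `center`/`scale`; for
#'   SUGIBS the reference IBS `degrees`.
#' @seealso [predict.ancestry_space], [ibs_mds], [suggest_component_count]
#' @examples
#' sim <- simulate_admixed(simulate_drift(300, fst = 0.1, seed = 1), 60, seed = 2)
#' fit <- ancestry_space(sim$panel, k = 2)
#' head(fit$scores)
#' @export
ancestry_space <- function(x, k = 8, method = c("sugibs", "pca", "upca"),
                           seed = 1L, svd_method = c("auto", "dense", "randomized"),
                           oversample = 10, power_iters = 2) {
  g <- as_panel(x)
  method <- match.arg(method)
  svd_method <- match.arg(svd_method)
  m <- n_variants(g); n <- n_samples(g)
  skip1 <- method %in% c("sugibs", "upca")
  ncomp <- k + skip1
  if (k < 1) stop("`k` must be >= 1")
  if (ncomp > min(m, n))
    stop(sprintf("k%s = %d exceeds min(M, N) = %d",
                 if (skip1) " + 1" else "", ncomp, min(m, n)))

  center <- NULL; scale <- NULL; degrees <- NULL
  if (method == "sugibs") {
    degrees <- ibs_degrees(g)
    if (any(degrees <= 0))
      stop("sample(s) with zero IBS degree: ",
           paste(g$samples$iid[degrees <= 0], collapse = ", "))
    A <- geno_zero(g)
    A <- sweep(A, 2L, sqrt(degrees), "/")
    x0 <- NULL   # scores come from A: D^-1 X' L = D^-1/2 A' L
  } else if (method == "pca") {
    p <- (rowMeans(g$genotypes, na.rm = TRUE) + 1) / 2
    if (any(is.nan(p) | p <= 0 | p >= 1))
      stop("monomorphic or all-missing SNPs present; apply filter_maf() first")
    center <- 2 * p - 1
    scale <- sqrt(2 * p * (1 - p))
    A <- (g$genotypes - center) / scale
    A[is.na(A)] <- 0
    x0 <- A
  } else {
    x0 <- geno_zero(g)
    A <- x0
  }

  sv <- .svd_auto(A, ncomp, seed = seed, oversample = oversample,
                  power_iters = power_iters, method = svd_method)
  keep <- seq.int(1L + skip1, ncomp)
  u <- sv$u[, keep, drop = FALSE]
  sig <- sv$d[keep]
  if (any(sig <= 0)) stop("rank-deficient panel: nonpositive singular values")
  loadings <- sweep(u, 2L, sig, "/")
  scores <- if (method == "sugibs") {
    crossprod(A, loadings) / sqrt(degrees)
  } else {
    crossprod(x0, loadings)
  }
  dimnames(loadings) <- list(g$variants$id, paste0("C", seq_len(k)))
  dimnames(scores) <- list(g$samples$iid, paste0("C", seq_len(k)))

  structure(list(
    method = method, k = k,
    loadings = loadings,
    singular_values = sig,
    scores = scores,
    variant_keys = g$variants[, c("id", "a1", "a2")],
    samples = g$samples[, c("fid", "iid")],
    center = center, scale = scale, degrees = degrees,
    seed = seed, svd_method = svd_method
  ), class = "ancestry_space")
}

#' Project new samples onto a fitted ancestry space
#'
#' For SUGIBS the projected scores are `D~^{-1} X~' L`, where the reference
#' degree `d~_ii` of target sample `i` is its summed IBS similarity to all
#' reference samples ([cross_ibs_degrees]); the correction is applied per
#' individual and compensates missing genotypes and genotyping errors.  PCA
#' projection standardizes the target with the reference per-SNP constants
#' and mean-imputes missing values (the documented shrinkage behaviour under
#' corruption is a property of the method, kept for comparator fidelity);
#' UPCA projection is the uncorrected product `X~' L`.
#'
#' @param object an `ancestry_space` fit.
#' @param newdata target [snp_panel], harmonized to the fit's variants
#'   (same ids, same allele orientation; see [harmonize]).
#' @param reference the reference [snp_panel] the model was fitted on
#'   (required for SUGIBS cross degrees).
#' @param ... ignored.
#' @return An object of class `ancestry_projection`: list with `scores`
#'   (N~ x k), `method`, and for SUGIBS the reference `degrees` used.
#' @export
predict.ancestry_space <- function(object, newdata, reference = NULL, ...) {
  g <- as_panel(newdata)
  vk <- object$variant_keys
  if (n_variants(g) != nrow(vk) ||
      !all(g$variants$id == vk$id) ||
      !all(g$variants$a1 == vk$a1) ||
      !all(g$variants$a2 == vk$a2))
    stop("target is not harmonized to the model's variants; run harmonize()")

  degrees <- NULL
  if (object$method == "sugibs") {
    if (is.null(reference))
      stop("SUGIBS projection requires the reference panel for cross degrees")
    cross <- cross_ibs_degrees(reference, g)
    degrees <- cross$degrees
    if (any(degrees <= 0))
      stop("target sample(s) share no observed genotypes with the reference: ",
           paste(g$samples$iid[degrees <= 0], collapse = ", "))
    scores <- crossprod(geno_zero(g), object$loadings) / degrees
  } else if (object$method == "pca") {
    z <- (g$genotypes - object$center) / object$scale
    z[is.na(z)] <- 0
    scores <- crossprod(z, object$loadings)
  } else {
    scores <- crossprod(geno_zero(g), object$loadings)
  }
  dimnames(scores) <- list(g$samples$iid, colnames(object$loadings))
  structure(list(scores = scores, method = object$method, degrees = degrees,
                 samples = g$samples[, c("fid", "iid")]),
            class = "ancestry_projection")
}

#' @export
print.ancestry_space <- function(x, ...) {
  cat(sprintf("ancestry_space [%s]: %d components, %d variants, %d reference samples\n",
              toupper(x$method), x$k, nrow(x$loadings), nrow(x$scores)))
  cat("singular values:", format(signif(x$singular_values, 4)), "\n")
  invisible(x)
}

#' @export
summary.ancestry_space <- function(object, ...) {
  v <- object$singular_values^2
  out <- list(method = object$method, k = object$k,
              singular_values = object$singular_values,
              variance_share = v / sum(v),
              n_variants = nrow(object$loadings),
              n_samples = nrow(object$scores))
  class(out) <- "summary.ancestry_space"
  out
}

#' @export
print.summary.ancestry_space <- function(x, ...) {
  cat(sprintf("%s ancestry space: %d components (%d variants, %d samples)\n",
              toupper(x$method), x$k, x$n_variants, x$n_samples))
  tab <- rbind(`singular value` = x$singular_values,
               `share of retained variance` = x$variance_share)
  colnames(tab) <- paste0("C", seq_len(x$k))
  print(signif(tab, 4))
  invisible(x)
}

#' @export
coef.ancestry_space <- function(object, ...) object$loadings

#' @export
print.ancestry_projection <- function(x, ...) {
  cat(sprintf("ancestry_projection [%s]: %d samples x %d components\n",
              toupper(x$method), nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Scatter plot of the first two ancestry components
#'
#' @param x an `ancestry_space`.
#' @param dims two component indices to plot.
#' @param col point colours (e.g. population labels).
#' @param ... passed to [graphics::plot].
#' @export
plot.ancestry_space <- function(x, dims = c(1, 2), col = 1, ...) {
  s <- x$scores[, dims, drop = FALSE]
  graphics::plot(s[, 1], s[, 2], col = col,
                 xlab = colnames(s)[1], ylab = colnames(s)[2],
                 main = sprintf("%s ancestry space", toupper(x$method)), ...)
  invisible(x)
}

#' Suggest a number of ancestry components
#'
#' Parallel-analysis-style rule: the observed SUGIBS spectrum is compared
#' with the spectra of simulated homogeneous panels with the same per-SNP
#' allele frequencies, drawn under Hardy-Weinberg and linkage equilibrium.
#' The suggestion is the number of leading observed singular values
#' exceeding the pointwise 95th percentile of the null spectra, capped at
#' `max_k`.
#'
#' @param x an [snp_panel].
#' @param max_k maximum number of components considered.
#' @param n_null number of null panels (default 20).
#' @param quantile null-spectrum percentile (default 0.95).
#' @param seed integer seed.
#' @return integer suggested component count.
#' @export
suggest_component_count <- function(x, max_k = 8, n_null = 20,
                                    quantile = 0.95, seed = 1L) {
  g <- as_panel(x)
  if (max_k < 1) stop("`max_k` must be >= 1")
  m <- n_variants(g); n <- n_samples(g)
  max_k <- min(max_k, min(m, n) - 1L)
  obs <- .sugibs_spectrum(g, max_k, seed)
  p <- (rowMeans(g$genotypes, na.rm = TRUE) + 1) / 2
  p[is.nan(p)] <- 0.5
  seeds <- child_seeds(seed, n_null)
  null <- vapply(seq_len(n_null), function(i) {
    geno <- with_seed(seeds[i],
                      matrix(.rgeno(rep(p, n)), m, n))
    .sugibs_spectrum(snp_panel(geno), max_k, seeds[i])
  }, numeric(max_k))
  thresh <- apply(matrix(null, nrow = max_k), 1L, stats::quantile,
                  probs = quantile)
  above <- obs > thresh
  if (!above[1]) return(0L)
  which.min(c(above, FALSE)) - 1L
}

# Component singular values (first generalized eigenvector excluded).
.sugibs_spectrum <- function(g, k, seed) {
  d <- ibs_degrees(g)
  A <- sweep(geno_zero(g), 2L, sqrt(d), "/")
  sv <- .svd_auto(A, k + 1L, seed = seed)
  sv$d[-1L]
}

#' Write / read an ancestry-space model directory
#'
#' Serializes a fit as plain TSV: `loadings.tsv` (variant id, alleles, PCA
#' normalization constants when present, k loading columns),
#' `singular_values.tsv`, `scores.tsv` (FID/IID plus k columns) and a
#' `meta.dcf` key-value file.
#'
#' @param object an `ancestry_space`.
#' @param dir directory to create/fill.
#' @return `dir` (for the writer) or an `ancestry_space` (for the reader).
#' @export
write_ancestry_space <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  load_tab <- object$variant_keys
  if (!is.null(object$center))
    load_tab <- cbind(load_tab, center = object$center, scale = object$scale)
  load_tab <- cbind(load_tab, as.data.frame(object$loadings))
  utils::write.table(load_tab, file.path(dir, "loadings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(singular_value = object$singular_values),
                     file.path(dir, "singular_values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc <- cbind(object$samples, as.data.frame(object$scores))
  if (!is.null(object$degrees)) sc$degree <- object$degrees
  utils::write.table(sc, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(method = object$method, k = object$k, seed = object$seed,
                     svd_method = object$svd_method)
  write.dcf(meta, file.path(dir, "meta.dcf"))
  invisible(dir)
}

#' @rdname write_ancestry_space
#' @export
read_ancestry_space <- function(dir) {
  meta <- read.dcf(file.path(dir, "meta.dcf"))
  k <- as.integer(meta[1, "k"])
  lt <- utils::read.table(file.path(dir, "loadings.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(id = "character", a1 = "character",
                                         a2 = "character"))
  sc <- utils::read.table(file.path(dir, "scores.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(fid = "character", iid = "character"))
  sv <- utils::read.table(file.path(dir, "singular_values.tsv"), header = TRUE,
                          sep = "\t")
  lcols <- paste0("C", seq_len(k))
  loadings <- as.matrix(lt[, lcols])
  rownames(loadings) <- lt$id
  scores <- as.matrix(sc[, lcols])
  rownames(scores) <- sc$iid
  structure(list(
    method = meta[1, "method"], k = k,
    loadings = loadings,
    singular_values = sv$singular_value,
    scores = scores,
    variant_keys = lt[, c("id", "a1", "a2")],
    samples = sc[, c("fid", "iid")],
    center = if ("center" %in% names(lt)) lt$center,
    scale = if ("scale" %in% names(lt)) lt$scale,
    degrees = if ("degree" %in% names(sc)) sc$degree,
    seed = as.integer(meta[1, "seed"]),
    svd_method = meta[1, "svd_method"]
  ), class = "ancestry_space")
}
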