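#' Per-SNP logistic likelihood-ratio association scan
#'
#' For each SNP, compares the logistic model
#' `logit P(case) = b0 + gamma' c + b g` against the covariate-only null by
#' a likelihood-ratio test with one degree of freedom.  The null model is
#' fitted once; the per-SNP alternative models are fitted by a batched,
#' vectorized IRLS (all SNPs share the covariate columns and differ only in
#' the dosage column, so the per-SNP normal equations are solved by a
#' batched Cholesky).  Missing dosages are mean-imputed per SNP.
#' Monomorphic SNPs carry no information and get LRT 0, p 1.  SNPs that do
#' not converge within `maxit` IRLS iterations are flagged and reported
#' with `p = NA`.
#'
#' @param genotypes an [snp_panel] or M x N genotype matrix.
#' @param status binary vector of length N with both classes present.
#' @param covariates optional N x c numeric matrix of finite covariates.
#' @param threshold significance threshold recorded in the result metadata.
#' @param maxit maximum IRLS iterations per SNP (default 50).
#' @param tol convergence tolerance on the coefficient update (default 1e-8).
#' @return An object of class `gwas_scan`: data frame with columns
#'   `variant_id`, `stat` (chi-square, 1 df), `p`, plus attributes
#'   `threshold`, `n_covariates`, `n_nonconverged`.
#' @export
logistic_lrt_scan <- function(genotypes, status, covariates = NULL,
                              threshold = 1e-4, maxit = 50L, tol = 1e-6) {
  g <- as_panel(genotypes)
  y <- as.numeric(status)
  n <- n_samples(g)
  if (length(y) != n) stop("`status` length must equal the sample count")
  if (!all(y %in% c(0, 1))) stop("`status` must be binary 0/1")
  if (length(unique(y)) < 2) stop("`status` has a single class")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must equal the sample count")
    if (!all(is.finite(covariates))) stop("covariates must be finite")
  }
  Xc <- cbind(`(Intercept)` = rep(1, n), covariates)
  q <- ncol(Xc)

  null_fit <- stats::glm.fit(Xc, y, family = stats::binomial())
  eta0 <- drop(Xc %*% null_fit$coefficients)
  ll0 <- sum(y * eta0 - .log1pexp(eta0))
  beta0 <- null_fit$coefficients

  m <- n_variants(g)
  stat <- numeric(m)
  pval <- numeric(m)
  nonconv <- logical(m)

  chunk <- max(1L, floor(4e6 / n))
  for (s0 in seq(1L, m, by = chunk)) {
    rows <- s0:min(s0 + chunk - 1L, m)
    G <- t(g$genotypes[rows, , drop = FALSE])     # n x s
    storage.mode(G) <- "double"
    if (anyNA(G)) {
      mu_g <- colMeans(G, na.rm = TRUE)
      na <- which(is.na(G))
      G[na] <- mu_g[(na - 1L) %/% n + 1L]
    }
    v <- .colVars(G)
    mono <- v < .Machine$double.eps
    res <- .lrt_chunk(G[, !mono, drop = FALSE], y, Xc, beta0, ll0, maxit, tol)
    st <- numeric(length(rows)); pv <- rep(1, length(rows)); nc <- logical(length(rows))
    st[!mono] <- res$stat
    pv[!mono] <- res$p
    nc[!mono] <- res$nonconv
    stat[rows] <- st; pval[rows] <- pv; nonconv[rows] <- nc
  }
  pval[nonconv] <- NA_real_

  out <- data.frame(variant_id = g$variants$id, stat = stat, p = pval,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "n_covariates") <- q - 1L
  attr(out, "n_nonconverged") <- sum(nonconv)
  class(out) <- c("gwas_scan", "data.frame")
  out
}

.log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

.colVars <- function(x) {
  n <- nrow(x)
  (colSums(x * x) - colSums(x)^2 / n) / max(1, n - 1)
}

# Batched IRLS over the SNPs of one chunk.  G: n x s mean-imputed dosages.
# Per-SNP normal-equation moments that pair the IRLS weights with fixed
# covariate columns are accumulated as single BLAS crossproducts.
.lrt_chunk <- function(G, y, Xc, beta0, ll0, maxit, tol) {
  s <- ncol(G)
  if (s == 0L)
    return(list(stat = numeric(), p = numeric(), nonconv = logical()))
  n <- nrow(G)
  q <- ncol(Xc)
  p <- q + 1L
  # products of the shared covariate columns, as an n x (q(q+1)/2) block
  pairs <- which(upper.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  CP <- Xc[, pairs[, 1], drop = FALSE] * Xc[, pairs[, 2], drop = FALSE]

  beta <- matrix(0, p, s)
  beta[seq_len(q), ] <- beta0
  active <- seq_len(s)

  for (it in seq_len(maxit)) {
    Ga <- G[, active, drop = FALSE]
    sa <- length(active)
    A <- array(0, c(sa, p, p))
    U <- matrix(0, sa, p)
    if (it == 1L) {
      # every SNP starts at the null fit, so the IRLS weights and
      # residuals of the first iteration are the null model's n-vectors
      # and the moments reduce to thin matrix products
      eta0v <- pmin(pmax(drop(Xc %*% beta0), -30), 30)
      mu0 <- 1 / (1 + exp(-eta0v))
      w0 <- mu0 * (1 - mu0)
      r0 <- y - mu0
      Acov <- colSums(w0 * CP)
      for (kk in seq_len(nrow(pairs)))
        A[, pairs[kk, 1], pairs[kk, 2]] <- A[, pairs[kk, 2], pairs[kk, 1]] <-
          Acov[kk]
      Axg <- crossprod(Ga, w0 * Xc)        # sa x q
      for (a in seq_len(q)) A[, a, p] <- A[, p, a] <- Axg[, a]
      A[, p, p] <- drop(crossprod(Ga * Ga, w0))
      U[, seq_len(q)] <- matrix(colSums(r0 * Xc), sa, q, byrow = TRUE)
      U[, p] <- drop(crossprod(Ga, r0))
    } else {
      eta <- Xc %*% beta[seq_len(q), active, drop = FALSE] +
        Ga * rep(beta[p, active], each = n)
      eta <- pmin(pmax(eta, -30), 30)
      mu <- 1 / (1 + exp(-eta))
      w <- mu * (1 - mu)
      r <- y - mu
      Acov <- crossprod(w, CP)             # sa x q(q+1)/2
      for (kk in seq_len(nrow(pairs)))
        A[, pairs[kk, 1], pairs[kk, 2]] <- A[, pairs[kk, 2], pairs[kk, 1]] <-
          Acov[, kk]
      wG <- w * Ga
      Axg <- crossprod(wG, Xc)             # sa x q
      for (a in seq_len(q)) A[, a, p] <- A[, p, a] <- Axg[, a]
      A[, p, p] <- colSums(wG * Ga)
      U[, seq_len(q)] <- crossprod(r, Xc)
      U[, p] <- colSums(r * Ga)
    }

    delta <- .batch_chol_solve(A, U)
    bad <- !is.finite(rowSums(delta))
    delta[bad, ] <- 0
    beta[, active] <- beta[, active] + t(delta)
    done <- apply(abs(delta), 1L, max) < tol
    done[bad] <- FALSE
    still <- active[!done]
    if (it == maxit) {
      nonconv_idx <- still
      break
    }
    active <- still
    if (!length(active)) {
      nonconv_idx <- integer()
      break
    }
  }

  # final linear predictor and log-likelihood per SNP
  eta <- Xc %*% beta[seq_len(q), , drop = FALSE] + G * rep(beta[p, ], each = n)
  eta <- pmin(pmax(eta, -30), 30)
  ll1 <- colSums(y * eta - .log1pexp(eta))
  stat <- pmax(0, 2 * (ll1 - ll0))
  nonconv <- logical(s)
  nonconv[nonconv_idx] <- TRUE
  list(stat = stat, p = stats::pchisq(stat, 1L, lower.tail = FALSE),
       nonconv = nonconv)
}

# Solve s independent SPD systems A[i,,] x = b[i,] by batched Cholesky.
# Returns an s x p matrix; rows of singular systems come back NaN.
.batch_chol_solve <- function(A, B) {
  s <- dim(A)[1]; p <- dim(A)[2]
  L <- array(0, dim(A))
  for (j in seq_len(p)) {
    acc <- A[, j, j]
    for (k in seq_len(j - 1L)) acc <- acc - L[, j, k]^2
    acc[acc <= 0] <- NaN
    L[, j, j] <- sqrt(acc)
    if (j < p) for (i in seq.int(j + 1L, p)) {
      acc <- A[, i, j]
      for (k in seq_len(j - 1L)) acc <- acc - L[, i, k] * L[, j, k]
      L[, i, j] <- acc / L[, j, j]
    }
  }
  Yf <- matrix(0, s, p)
  for (i in seq_len(p)) {
    acc <- B[, i]
    for (k in seq_len(i - 1L)) acc <- acc - L[, i, k] * Yf[, k]
    Yf[, i] <- acc / L[, i, i]
  }
  X <- matrix(0, s, p)
  for (i in rev(seq_len(p))) {
    acc <- Yf[, i]
    if (i < p) for (k in seq.int(i + 1L, p)) acc <- acc - L[, k, i] * X[, k]
    X[, i] <- acc / L[, i, i]
  }
  X
}

#' Fraction of significant SNPs per category
#'
#' @param scan a `gwas_scan` from [logistic_lrt_scan].
#' @param categories per-SNP labels (length = SNP count) from
#'   \{random, differentiated, causal\}.
#' @param threshold significance threshold (default: the scan's).
#' @return data frame with `category`, `proportion` (of converged SNPs with
#'   `p < threshold`), `n_snps`, `n_excluded` (non-converged).
#' @export
summarize_by_category <- function(scan, categories,
                                  threshold = attr(scan, "threshold")) {
  if (length(categories) != nrow(scan))
    stop("`categories` length must match the SNP count")
  known <- c("random", "differentiated", "causal")
  if (!all(categories %in% known))
    stop("unknown category label(s): ",
         paste(setdiff(unique(categories), known), collapse = ", "))
  cats <- intersect(known, unique(categories))
  out <- do.call(rbind, lapply(cats, function(cc) {
    p <- scan$p[categories == cc]
    ok <- !is.na(p)
    data.frame(category = cc,
               proportion = mean(p[ok] < threshold),
               n_snps = length(p), n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Stratification-correction benchmark on a simulated cohort
#'
#' Reproduces the Table-1 design: ancestry structure is inferred from the
#' cohort's random-category SNPs only (monomorphic SNPs dropped first), each
#' correction method contributes its top components as covariates (naive =
#' none), and every SNP is scanned by the logistic LRT at the stated
#' threshold.
#'
#' @param cohort a `case_control_cohort` from [simulate_case_control].
#' @param methods subset of `"naive"`, `"pca"`, `"mds"`, `"sugibs"`.
#' @param n_components ancestry components used as covariates (default 1:
#'   the simulated structure is one-dimensional).
#' @param threshold significance threshold (default 1e-4).
#' @param seed integer seed (randomized SVD sketch).
#' @return data frame with `method`, `category`, `proportion`, `n_snps`,
#'   `n_excluded`.
#' @export
run_correction_benchmark <- function(cohort,
                                     methods = c("naive", "pca", "mds", "sugibs"),
                                     n_components = 1L, threshold = 1e-4,
                                     seed = 1L) {
  methods <- match.arg(methods, c("naive", "pca", "mds", "sugibs"),
                       several.ok = TRUE)
  if (!any(cohort$categories == "random"))
    stop("cohort has no random-category SNPs")
  rand <- cohort$panel[cohort$categories == "random" & maf(cohort$panel) > 0, ]

  covs <- list()
  for (meth in setdiff(methods, "naive")) {
    covs[[meth]] <- switch(meth,
      pca = ancestry_space(rand, k = n_components, method = "pca",
                           seed = seed)$scores,
      sugibs = ancestry_space(rand, k = n_components, method = "sugibs",
                              seed = seed)$scores,
      mds = ibs_mds(rand, k = n_components)$coordinates)
  }

  out <- lapply(methods, function(meth) {
    cv <- if (meth == "naive") NULL else covs[[meth]]
    scan <- logistic_lrt_scan(cohort$panel, cohort$status, covariates = cv,
                              threshold = threshold)
    cbind(method = meth,
          summarize_by_category(scan, cohort$categories, threshold))
  })
  do.call(rbind, out)
}
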