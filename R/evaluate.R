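#' Normalized root-mean-square deviation between score matrices
#'
#' Per axis `a`: `sqrt(mean((orig[, a] - mod[, a])^2))` divided by the range
#' `max(orig[, a]) - min(orig[, a])` of the original scores, making the
#' deviation comparable across methods with different score scales.
#'
#' @param original_scores,modified_scores matrices of equal shape.
#' @return numeric vector, one NRMSD per axis.
#' @export
nrmsd <- function(original_scores, modified_scores) {
  o <- as.matrix(original_scores)
  m <- as.matrix(modified_scores)
  if (!all(dim(o) == dim(m))) stop("score matrices must have equal shape")
  rng <- apply(o, 2L, function(col) diff(range(col)))
  if (any(rng <= 0)) stop("zero range on an original axis; NRMSD undefined")
  sqrt(colMeans((o - m)^2)) / rng
}

#' Theoretical finest detectable divergence
#'
#' Phase-transition bound for detecting structure between two isolated
#' populations from `m` SNPs and `n` samples: `1 / sqrt(m n / 2)`.
#'
#' @param m number of SNPs.
#' @param n number of samples.
#' @return the Fst detection threshold.
#' @examples
#' detectable_fst(3200, 200)  # ~0.002
#' @export
detectable_fst <- function(m, n) {
  if (m < 1 || n < 1) stop("`m` and `n` must be >= 1")
  1 / sqrt(m * n / 2)
}

#' Absolute correlation between the first component and ancestry
#'
#' @param model_scores N x k score matrix (or `ancestry_space` /
#'   `ibs_mds` / `ancestry_projection` object).
#' @param alpha simulated ancestry proportions, length N.
#' @return `|Pearson correlation|` between component 1 and `alpha`.
#' @export
ancestry_correlation <- function(model_scores, alpha) {
  s <- .first_component(model_scores)
  if (stats::sd(s) == 0 || stats::sd(alpha) == 0)
    stop("zero variance; correlation undefined")
  abs(stats::cor(s, alpha))
}

.first_component <- function(x) {
  if (inherits(x, "ancestry_space")) return(x$scores[, 1])
  if (inherits(x, "ancestry_projection")) return(x$scores[, 1])
  if (inherits(x, "ibs_mds")) return(x$coordinates[, 1])
  as.matrix(x)[, 1]
}

#' Admixture-detection experiment
#'
#' For each divergence in `fst_list` and each replicate: simulate two
#' drifted populations, an admixed cohort of `n` individuals over `m`
#' independent SNPs, fit PCA, MDS and SUGIBS, and record the absolute
#' correlation of each method's first component with the simulated ancestry
#' proportion.  Monomorphic SNPs (possible by drift fixation) are dropped
#' before fitting, as PCA requires.
#'
#' @param fst_list numeric vector of target divergences.
#' @param n_reps replicates per divergence.
#' @param m SNPs per replicate (default 3200).
#' @param n individuals per replicate (default 200).
#' @param methods methods to run (default PCA, MDS, SUGIBS).
#' @param tau generations of drift (default 20).
#' @param seed integer seed.
#' @return data frame with `fst`, `rep`, `seed`, `method`, `abs_r`.
#' @export
run_experiment_admixture <- function(fst_list, n_reps = 100, m = 3200, n = 200,
                                     methods = c("pca", "mds", "sugibs"),
                                     tau = 20, seed = 1L) {
  seeds <- matrix(child_seeds(seed, 2L * length(fst_list) * n_reps),
                  ncol = 2L)
  row <- 0L
  out <- list()
  for (fst in fst_list) {
    for (rep in seq_len(n_reps)) {
      row <- row + 1L
      dr <- simulate_drift(m, fst, tau, seed = seeds[row, 1])
      sim <- simulate_admixed(dr, n, seed = seeds[row, 2])
      panel <- sim$panel[maf(sim$panel) > 0, ]
      for (meth in methods) {
        fit <- if (meth == "mds") ibs_mds(panel, k = 1)
        else ancestry_space(panel, k = 1, method = meth, seed = seeds[row, 1])
        out[[length(out) + 1L]] <- data.frame(
          fst = fst, rep = rep, seed = seeds[row, 1], method = meth,
          abs_r = ancestry_correlation(fit, sim$alpha),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Multi-population panel pair for projection experiments
#'
#' Simulates `n_pops` populations drifting independently from a shared
#' ancestral frequency vector at a common divergence, and draws a reference
#' and a disjoint target panel with samples spread evenly over the
#' populations.  With `n_pops` populations the reference spectrum carries
#' `n_pops - 1` structured axes, so corruption effects on the top axes are
#' not drowned by pure-noise axes.
#'
#' @param m SNPs.
#' @param n_ref,n_target panel sizes.
#' @param n_pops number of populations (default 10).
#' @param fst per-population divergence from the ancestral frequencies.
#' @param tau generations of drift.
#' @param seed integer seed.
#' @return list with `reference` and `target` [snp_panel]s and their
#'   population index vectors.
#' @keywords internal
.multi_pop_pair <- function(m, n_ref, n_target, n_pops = 10, fst = 0.1,
                            tau = 20, seed = 1L) {
  seeds <- child_seeds(seed, n_pops + 2L)
  p_anc <- with_seed(seeds[1], stats::runif(m, 0.1, 0.9))
  ne <- fst_to_ne(fst, tau)
  freqs <- vapply(seq_len(n_pops), function(i)
    with_seed(seeds[1L + i], .drift(p_anc, ne, tau)), numeric(m))
  draw <- function(n, seed) {
    pop <- rep_len(seq_len(n_pops), n)
    geno <- with_seed(seed,
      matrix(.rgeno(freqs[, pop]), m, n))
    list(panel = snp_panel(geno), pop = pop)
  }
  r <- draw(n_ref, seeds[n_pops + 2L])
  t <- draw(n_target, seeds[n_pops + 2L] + 1L)
  list(reference = r$panel, target = t$panel, ref_pop = r$pop, tgt_pop = t$pop)
}

#' Projection-robustness experiment
#'
#' Synthetic analogue of the reference/target projection design: per
#' replicate, `n_pops` populations drift at `fst` from shared ancestral
#' frequencies; a reference panel and a disjoint target panel are sampled
#' evenly across populations; PCA, UPCA and SUGIBS spaces are fitted on the
#' reference (after a MAF filter); the target is projected twice, once from
#' the clean genotypes and once from a corrupted copy (byte-style group
#' corruption); the per-axis NRMSD between the two projections is recorded
#' over the top `k` axes.
#'
#' @param corruption `"none"`, `"missing"` (5\% masked) or `"errors"` (5\%
#'   of calls changed at SNPs with reference MAF < `maf_ceiling`).
#' @param n_reps replicates.
#' @param m SNPs per replicate.
#' @param n_ref,n_target reference / target panel sizes.
#' @param n_pops simulated populations (default 10, so that all of the
#'   default `k = 8` axes are structured).
#' @param fst per-population divergence (default 0.1).
#' @param k axes evaluated (default 8).
#' @param rate corruption rate (default 0.05).
#' @param maf_ceiling rare-SNP ceiling for error injection (default 0.05).
#' @param group_size consecutive-sample corruption group (default 4).
#' @param maf_filter reference MAF filter before fitting (default 0.01).
#' @param methods methods to run.
#' @param seed integer seed.
#' @return data frame with `corruption`, `rep`, `method`, `axis`, `nrmsd`.
#' @export
run_experiment_projection <- function(corruption = c("missing", "errors", "none"),
                                      n_reps = 10, m = 10000, n_ref = 300,
                                      n_target = 200, n_pops = 10, fst = 0.1,
                                      k = 8, rate = 0.05, maf_ceiling = 0.05,
                                      group_size = 4L, maf_filter = 0.01,
                                      methods = c("pca", "upca", "sugibs"),
                                      seed = 1L) {
  corruption <- match.arg(corruption)
  seeds <- matrix(child_seeds(seed, 3L * n_reps), ncol = 3L)
  out <- list()
  for (rep in seq_len(n_reps)) {
    pair <- .multi_pop_pair(m, n_ref, n_target, n_pops = n_pops, fst = fst,
                            seed = seeds[rep, 1])
    ref <- pair$reference
    tgt <- pair$target
    keep <- maf(ref) >= maf_filter
    ref <- ref[keep, ]; tgt <- tgt[keep, ]

    tgt_bad <- switch(corruption,
      none = tgt,
      missing = inject_missing(tgt, rate, group_size, seed = seeds[rep, 3]),
      errors = {
        rare <- maf(ref) < maf_ceiling   # eligibility from the reference panel
        corrupted <- inject_errors(tgt[rare, ], rate, maf_ceiling = 1,
                                   group_size = group_size,
                                   seed = seeds[rep, 3])
        merged <- tgt
        merged$genotypes[rare, ] <- corrupted$genotypes
        merged
      })

    for (meth in methods) {
      fit <- ancestry_space(ref, k = k, method = meth, seed = seeds[rep, 1])
      clean <- predict(fit, tgt, reference = ref)$scores
      dirty <- predict(fit, tgt_bad, reference = ref)$scores
      val <- nrmsd(clean, dirty)
      out[[length(out) + 1L]] <- data.frame(
        corruption = corruption, rep = rep, method = meth,
        axis = seq_len(k), nrmsd = val, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Outlier-robustness experiment
#'
#' Fits PCA, MDS, UPCA and SUGIBS on a panel of two close populations plus
#' single-individual outliers ([simulate_outlier_scenario]) and reports, per
#' method, the maximum over the top two components of the absolute
#' correlation between the component and the main-population label,
#' computed on non-outlier samples only.
#'
#' @param n_main individuals per main population.
#' @param fst_close divergence of the main populations (default 0.004).
#' @param outlier_fsts outlier-population divergences.
#' @param m SNPs (default 20000).
#' @param methods methods to run.
#' @param seed integer seed.
#' @return data frame with `method`, `separation` (max |corr|), plus the
#'   scenario parameters.
#' @export
run_experiment_outliers <- function(n_main = 100, fst_close = 0.004,
                                    outlier_fsts = c(0.05, 0.1, 0.1, 0.15),
                                    m = 20000,
                                    methods = c("pca", "mds", "upca", "sugibs"),
                                    seed = 1L) {
  sc <- simulate_outlier_scenario(n_main, fst_close, outlier_fsts, m = m,
                                  seed = seed)
  panel <- sc$panel[maf(sc$panel) > 0, ]
  main <- !sc$labels$outlier
  lab <- as.numeric(sc$labels$population[main] == "pop1")
  out <- lapply(methods, function(meth) {
    sc2 <- if (meth == "mds") ibs_mds(panel, k = 2)$coordinates
    else ancestry_space(panel, k = 2, method = meth, seed = seed)$scores
    sep <- max(abs(apply(sc2[main, , drop = FALSE], 2L, stats::cor, y = lab)))
    data.frame(method = meth, separation = sep, n_main = n_main,
               fst_close = fst_close, n_outliers = length(outlier_fsts),
               m = m, seed = seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
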