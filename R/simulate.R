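#' Effective population size for a target Fst
#'
#' Inverts the drift relation `Fst = -log(1 - tau / (2 Ne))` for `Ne` given
#' a divergence target and a number of generations:
#' `Ne = round(tau / (2 (1 - exp(-Fst))))`.
#'
#' @param fst target divergence (> 0).
#' @param tau number of generations (>= 1).
#' @return integer effective population size.
#' @examples
#' fst_to_ne(0.05, 20)  # 205
#' @export
fst_to_ne <- function(fst, tau = 20) {
  if (fst <= 0) stop("`fst` must be > 0")
  if (tau < 1) stop("`tau` must be >= 1")
  as.integer(round(tau / (2 * (1 - exp(-fst)))))
}

#' Two-population Balding-Nichols-style drift frequencies
#'
#' Ancestral frequencies are drawn i.i.d. Uniform(0.1, 0.9); two populations
#' then drift independently for `tau` generations in a Wright-Fisher
#' population of effective size `Ne = fst_to_ne(fst, tau)`: each generation
#' the allele count is resampled `z ~ Binomial(2 Ne, p)` and `p <- z/(2 Ne)`.
#' Frequencies may fix at 0 or 1 (absorbing) and such SNPs are retained.
#'
#' @param m number of SNPs.
#' @param fst target divergence.
#' @param tau generations of drift (default 20); `tau = 0` returns the
#'   ancestral frequencies unchanged.
#' @param seed integer seed.
#' @return An object of class `drift_pair`: list with `p_anc`, `p1`, `p2`,
#'   `fst`, `ne`, `tau`.
#' @export
simulate_drift <- function(m, fst, tau = 20, seed = 1L) {
  if (m < 1) stop("`m` must be >= 1")
  ne <- fst_to_ne(fst, max(tau, 1))
  with_seed(seed, {
    p_anc <- stats::runif(m, 0.1, 0.9)
    p1 <- .drift(p_anc, ne, tau)
    p2 <- .drift(p_anc, ne, tau)
    structure(list(p_anc = p_anc, p1 = p1, p2 = p2, fst = fst, ne = ne,
                   tau = tau),
              class = "drift_pair")
  })
}

.drift <- function(p, ne, tau) {
  for (i in seq_len(tau)) p <- stats::rbinom(length(p), 2L * ne, p) / (2 * ne)
  p
}

# Binomial(2, p) - 1 genotype draws as two Bernoulli trials (identical
# distribution, substantially faster than rbinom at changing probabilities).
.rgeno <- function(p) {
  (stats::runif(length(p)) < p) + (stats::runif(length(p)) < p) - 1L
}

#' Simulate an admixed cohort from drifted population frequencies
#'
#' Ancestry proportions `alpha ~ Beta(0.5, 0.5)` (mean 0.5) unless supplied;
#' the individual allele frequency of SNP `i` for individual `j` is
#' `alpha_j p1_i + (1 - alpha_j) p2_i` and the genotype is
#' `Binomial(2, p_ij) - 1` on the -1/0/+1 coding.
#'
#' @param drift a `drift_pair` from [simulate_drift].
#' @param n number of individuals.
#' @param alpha optional fixed ancestry proportions (length n, in [0, 1]).
#' @param seed integer seed.
#' @return An object of class `admixed_cohort`: list with `panel`
#'   ([snp_panel]), `alpha`, and the `drift` input.
#' @export
simulate_admixed <- function(drift, n, alpha = NULL, seed = 1L) {
  if (n < 1) stop("`n` must be >= 1")
  m <- length(drift$p1)
  with_seed(seed, {
    if (is.null(alpha)) alpha <- stats::rbeta(n, 0.5, 0.5)
    stopifnot(length(alpha) == n, all(alpha >= 0 & alpha <= 1))
    pf <- outer(drift$p1, alpha) + outer(drift$p2, 1 - alpha)
    geno <- matrix(.rgeno(pf), m, n)
    structure(list(panel = snp_panel(geno), alpha = alpha, drift = drift),
              class = "admixed_cohort")
  })
}

#' Ancestry-dependent disease probability
#'
#' `P(case | alpha) = log(r) r^alpha / (2 (r - 1))`, which integrates to
#' exactly 0.5 over alpha in [0, 1] for any ancestral risk `r > 1`.
#'
#' @param alpha ancestry proportion(s) in [0, 1].
#' @param r ancestral relative risk (> 1).
#' @return numeric probability vector.
#' @export
disease_probability <- function(alpha, r = 3) {
  if (r <= 1) stop("`r` must be > 1")
  if (any(alpha < 0 | alpha > 1)) stop("`alpha` must be in [0, 1]")
  log(r) * r^alpha / (2 * (r - 1))
}

#' Case allele-frequency update under a multiplicative risk model
#'
#' `p* = R p / (1 - p + R p)`: the allele frequency among cases for a causal
#' SNP with genotype relative risk `R`.  Monotone in `p` with fixed points
#' at 0 and 1; `R = 1` is the identity.
#'
#' @param p allele frequency in [0, 1].
#' @param R relative risk (> 0).
#' @return updated frequency.
#' @export
risk_update <- function(p, R = 3) {
  if (any(p < 0 | p > 1)) stop("`p` must be in [0, 1]")
  if (R <= 0) stop("`R` must be > 0")
  R * p / (1 - p + R * p)
}

#' Simulate a stratified case-control cohort
#'
#' Cohort individuals come from an admixture of two drifted ancestral
#' populations (`alpha ~ Beta(0.5, 0.5)`); case-control status is drawn
#' first with `P(case) = disease_probability(alpha, r)`.  Three SNP
#' categories are generated: \emph{random} SNPs drift at the given Fst and
#' are sampled from the individual frequency regardless of status;
#' \emph{differentiated} SNPs use fixed population frequencies 0.8 / 0.2;
#' \emph{causal} SNPs drift at the same Fst, and for cases both population
#' frequencies are updated with [risk_update] (relative risk `R`) before the
#' admixture mixing, while controls use the un-updated frequencies.
#'
#' @param m_random,m_diff,m_causal SNP counts per category.
#' @param n number of individuals (>= 2).
#' @param fst drift divergence for random and causal SNPs.
#' @param r ancestral disease risk (default 3).
#' @param R causal-SNP relative risk (default 3).
#' @param tau generations of drift (default 20).
#' @param seed integer seed.
#' @return An object of class `case_control_cohort`: list with `panel`,
#'   `alpha`, `status` (0/1), `categories` (per-SNP labels in
#'   random/differentiated/causal order).
#' @export
simulate_case_control <- function(m_random, m_diff, m_causal, n, fst,
                                  r = 3, R = 3, tau = 20, seed = 1L) {
  if (n < 2) stop("`n` must be >= 2")
  stopifnot(m_random >= 0, m_diff >= 0, m_causal >= 0)
  m <- m_random + m_diff + m_causal
  if (m < 1) stop("no SNPs requested")
  seeds <- child_seeds(seed, 5L)
  alpha <- with_seed(seeds[1], stats::rbeta(n, 0.5, 0.5))
  status <- with_seed(seeds[2],
                      stats::rbinom(n, 1L, disease_probability(alpha, r)))

  p1 <- numeric(m); p2 <- numeric(m)
  if (m_random + m_causal > 0) {
    dr <- simulate_drift(m_random + m_causal, fst, tau, seed = seeds[3])
    if (m_random > 0) {
      p1[seq_len(m_random)] <- dr$p1[seq_len(m_random)]
      p2[seq_len(m_random)] <- dr$p2[seq_len(m_random)]
    }
    if (m_causal > 0) {
      ci <- m_random + m_diff + seq_len(m_causal)
      p1[ci] <- dr$p1[m_random + seq_len(m_causal)]
      p2[ci] <- dr$p2[m_random + seq_len(m_causal)]
    }
  }
  if (m_diff > 0) {
    di <- m_random + seq_len(m_diff)
    p1[di] <- 0.8
    p2[di] <- 0.2
  }
  categories <- rep(c("random", "differentiated", "causal"),
                    c(m_random, m_diff, m_causal))

  causal <- categories == "causal"
  geno <- with_seed(seeds[4], {
    out <- matrix(0L, m, n)
    chunk <- max(1L, floor(2e7 / n))
    for (s in seq(1L, m, by = chunk)) {
      rows <- s:min(s + chunk - 1L, m)
      pf <- outer(p1[rows], alpha) + outer(p2[rows], 1 - alpha)
      cz <- causal[rows]
      if (any(cz) && any(status == 1L)) {
        pf_case <- outer(risk_update(p1[rows][cz], R), alpha[status == 1L]) +
          outer(risk_update(p2[rows][cz], R), 1 - alpha[status == 1L])
        pf[cz, status == 1L] <- pf_case
      }
      out[rows, ] <- matrix(.rgeno(pf), nrow = length(rows))
    }
    out
  })
  structure(list(panel = snp_panel(geno), alpha = alpha, status = status,
                 categories = categories, fst = fst, r = r, R = R),
            class = "case_control_cohort")
}

#' Inject missing genotypes in byte-style sample groups
#'
#' Selects (SNP, sample-group) cells at the given rate, with groups of
#' `group_size` consecutive samples (PLINK packs four samples per byte;
#' `group_size = 4` emulates byte-level corruption), and sets every genotype
#' in a selected cell to missing.
#'
#' @param g an [snp_panel].
#' @param rate expected masked fraction in [0, 1].
#' @param group_size consecutive samples per group (default 4).
#' @param seed integer seed.
#' @return corrupted [snp_panel].
#' @export
inject_missing <- function(g, rate, group_size = 4L, seed = 1L) {
  g <- as_panel(g)
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]")
  if (group_size < 1) stop("`group_size` must be >= 1")
  if (rate == 0) return(g)
  m <- n_variants(g); n <- n_samples(g)
  ngrp <- ceiling(n / group_size)
  grp <- rep(seq_len(ngrp), each = group_size)[seq_len(n)]
  sel <- with_seed(seed, matrix(stats::runif(m * ngrp) < rate, m, ngrp))
  mask <- sel[, grp, drop = FALSE]
  g$genotypes[mask] <- NA_integer_
  g
}

#' Inject genotype errors into rare SNPs in byte-style sample groups
#'
#' Restricted to SNPs with MAF below `maf_ceiling`; in selected (SNP,
#' sample-group) cells each non-missing call is changed to a uniformly
#' chosen \emph{different} genotype in \{-1, 0, +1\}.
#'
#' @param g an [snp_panel].
#' @param rate expected changed fraction among eligible SNPs, in [0, 1].
#' @param maf_ceiling eligibility ceiling on MAF (default 0.05).
#' @param group_size consecutive samples per group (default 4).
#' @param seed integer seed.
#' @return corrupted [snp_panel].
#' @export
inject_errors <- function(g, rate, maf_ceiling = 0.05, group_size = 4L,
                          seed = 1L) {
  g <- as_panel(g)
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]")
  if (rate == 0) return(g)
  eligible <- maf(g) < maf_ceiling
  if (!any(eligible)) return(g)
  m <- n_variants(g); n <- n_samples(g)
  ngrp <- ceiling(n / group_size)
  grp <- rep(seq_len(ngrp), each = group_size)[seq_len(n)]
  with_seed(seed, {
    sel <- matrix(stats::runif(m * ngrp) < rate, m, ngrp)
    sel[!eligible, ] <- FALSE
    mask <- sel[, grp, drop = FALSE] & !is.na(g$genotypes)
    idx <- which(mask)
    if (length(idx)) {
      shift <- sample(c(1L, 2L), length(idx), replace = TRUE)
      g$genotypes[idx] <- (g$genotypes[idx] + 1L + shift) %% 3L - 1L
    }
  })
  g
}

#' Two close populations plus single-individual outliers
#'
#' Builds the outlier-robustness scenario: two main populations at a small
#' divergence (`fst_close`, a CEU/TSI-like pair) with `n_main` individuals
#' each, plus one individual from each of several additional, deeply
#' diverged populations.  Each outlier population (i) drifts from the
#' shared ancestral frequencies at its listed divergence and (ii) carries
#' population-private variants — `round(m * private_load * fst)` extra SNPs
#' absent from the main populations, segregating in the outlier population
#' at Uniform(0.05, 0.3) frequency.  Private variation is the defining
#' genomic signature of deep divergence and is what drives the documented
#' sensitivity of frequency-normalized PCA to single outliers; pure
#' binomial drift scales differences by `p (1 - p) Fst` and cannot express
#' it.  An outlier divergence of 0 means a sample from the ancestral
#' population (no drift, no private variants).
#'
#' @param n_main individuals per main population.
#' @param fst_close divergence of the two main populations.
#' @param outlier_fsts numeric vector of outlier-population divergences
#'   (possibly empty).
#' @param m number of shared (non-private) SNPs.
#' @param private_load private variants per outlier population as a
#'   multiple of `m * fst` (default 1).
#' @param tau generations of drift (default 20).
#' @param seed integer seed.
#' @return list with `panel` ([snp_panel]; private blocks appended after
#'   the `m` shared SNPs) and `labels` (data frame with `population` and
#'   logical `outlier`).
#' @export
simulate_outlier_scenario <- function(n_main, fst_close, outlier_fsts = numeric(),
                                      m = 20000, private_load = 1, tau = 20,
                                      seed = 1L) {
  no <- length(outlier_fsts)
  seeds <- child_seeds(seed, 3L + 2L * no)
  dr <- simulate_drift(m, fst_close, tau, seed = seeds[1])
  with_seed(seeds[2], {
    g1 <- matrix(.rgeno(rep(dr$p1, n_main)), m, n_main)
    g2 <- matrix(.rgeno(rep(dr$p2, n_main)), m, n_main)
  })
  gout <- lapply(seq_len(no), function(i) {
    with_seed(seeds[3L + i], {
      p <- if (outlier_fsts[i] > 0)
        .drift(dr$p_anc, fst_to_ne(outlier_fsts[i], tau), tau) else dr$p_anc
      matrix(stats::rbinom(m, 2L, p) - 1L, m, 1L)
    })
  })
  geno <- do.call(cbind, c(list(g1, g2), gout))
  priv <- lapply(seq_len(no), function(i) {
    np <- round(m * private_load * outlier_fsts[i])
    if (np < 1) return(NULL)
    with_seed(seeds[3L + no + i], {
      pfreq <- stats::runif(np, 0.05, 0.3)
      block <- matrix(-1L, np, 2L * n_main + no)
      block[, 2L * n_main + i] <- stats::rbinom(np, 2L, pfreq) - 1L
      block
    })
  })
  geno <- do.call(rbind, c(list(geno), priv))
  labels <- data.frame(
    population = c(rep("pop1", n_main), rep("pop2", n_main),
                   if (no) paste0("outlier", seq_len(no))),
    outlier = c(rep(FALSE, 2L * n_main), rep(TRUE, no)),
    stringsAsFactors = FALSE
  )
  list(panel = snp_panel(geno), labels = labels)
}
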