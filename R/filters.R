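#' Minor allele frequencies of a panel
#'
#' Allele-2 frequency is estimated from non-missing genotypes; the MAF is the
#' smaller of the two allele frequencies.  An all-missing variant has MAF 0.
#'
#' @param g an [snp_panel] or genotype matrix.
#' @return numeric vector of length `n_variants(g)`.
#' @export
maf <- function(g) {
  g <- as_panel(g)
  alt <- rowSums(g$genotypes + 1L, na.rm = TRUE)      # allele-2 copies
  nobs <- rowSums(!is.na(g$genotypes))
  p <- ifelse(nobs > 0, alt / (2 * nobs), 0)
  pmin(p, 1 - p)
}

#' Filter variants by minor allele frequency
#'
#' Retains variants with MAF >= `threshold` (ties kept).  Variant order is
#' preserved.
#'
#' @param g an [snp_panel].
#' @param threshold proportion in [0, 0.5).
#' @return filtered [snp_panel].
#' @export
filter_maf <- function(g, threshold = 0.01) {
  if (threshold < 0 || threshold >= 0.5)
    stop("`threshold` must be in [0, 0.5)")
  g <- as_panel(g)
  g[maf(g) >= threshold, ]
}

#' Remove samples with excessive missingness
#'
#' Drops samples whose missing-genotype fraction exceeds `sample_threshold`
#' (strictly greater).  Sample order is preserved.
#'
#' @param g an [snp_panel].
#' @param sample_threshold proportion in (0, 1].
#' @return filtered [snp_panel].
#' @export
filter_missingness <- function(g, sample_threshold = 0.1) {
  if (sample_threshold <= 0 || sample_threshold > 1)
    stop("`sample_threshold` must be in (0, 1]")
  g <- as_panel(g)
  frac <- colMeans(is.na(g$genotypes))
  keep <- frac <= sample_threshold
  if (!any(keep))
    stop("all samples exceed the missingness threshold")
  g[, keep]
}

#' Harmonize a target panel to a reference panel
#'
#' Restricts both panels to the intersection of variant ids after excluding
#' indels (any allele longer than one character or coded `0`/`.`),
#' reference-monomorphic variants, and duplicated ids; target variants whose
#' alleles are swapped relative to the reference have their genotype signs
#' flipped (and allele metadata swapped); variants with irreconcilable
#' allele sets are dropped and reported.  No strand flipping is attempted:
#' an A/T vs T/A mismatch that is not an exact swap is a conflict.  Output
#' variant order follows the reference and is identical in both panels.
#'
#' @param reference,target [snp_panel] objects with variant metadata.
#' @return list with elements `reference`, `target` (harmonized panels) and
#'   `report` (a list of dropped/flipped variant ids by reason).
#' @export
harmonize <- function(reference, target) {
  reference <- as_panel(reference)
  target <- as_panel(target)
  rv <- reference$variants
  tv <- target$variants

  is_indel <- function(v) nchar(v$a1) > 1L | nchar(v$a2) > 1L |
    v$a1 %in% c("0", ".") | v$a2 %in% c("0", ".")

  drop_ref <- is_indel(rv) | duplicated(rv$id) | duplicated(rv$id, fromLast = TRUE)
  mono <- maf(reference) == 0
  report <- list(
    indels = sort(unique(c(rv$id[is_indel(rv)], tv$id[is_indel(tv)]))),
    monomorphic = rv$id[!drop_ref & mono],
    conflicts = character(),
    flipped = character()
  )
  drop_ref <- drop_ref | mono
  drop_tgt <- is_indel(tv) | duplicated(tv$id) | duplicated(tv$id, fromLast = TRUE)

  ridx <- which(!drop_ref & rv$id %in% tv$id[!drop_tgt])
  tmap <- match(rv$id[ridx], tv$id)
  ra1 <- rv$a1[ridx]; ra2 <- rv$a2[ridx]
  ta1 <- tv$a1[tmap]; ta2 <- tv$a2[tmap]
  same <- ta1 == ra1 & ta2 == ra2
  swapped <- ta1 == ra2 & ta2 == ra1 & !same
  conflict <- !(same | swapped)
  report$conflicts <- rv$id[ridx][conflict]
  report$flipped <- rv$id[ridx][swapped]

  ridx <- ridx[!conflict]
  tmap <- tmap[!conflict]
  swapped <- swapped[!conflict]
  if (!length(ridx))
    stop("no compatible variants shared between panels")

  ref_out <- reference[ridx, ]
  tgt_out <- target[tmap, ]
  if (any(swapped)) {
    tgt_out$genotypes[swapped, ] <- -tgt_out$genotypes[swapped, , drop = FALSE]
    a1 <- tgt_out$variants$a1[swapped]
    tgt_out$variants$a1[swapped] <- tgt_out$variants$a2[swapped]
    tgt_out$variants$a2[swapped] <- a1
  }
  list(reference = ref_out, target = tgt_out, report = report)
}

#' LD pruning by sliding-window pairwise r-squared
#'
#' Within each sliding window of `window` variants advanced by `step`
#' variants, greedily removes the later variant of any pair whose squared
#' Pearson correlation of genotype dosages exceeds `r2_threshold` (missing
#' genotypes excluded pairwise).  The sweep is repeated until no variant is
#' removed (fixed point).  Variant order is preserved.
#'
#' @param g an [snp_panel].
#' @param window window size in variants (>= 2).
#' @param step window advance in variants (1 <= step < window).
#' @param r2_threshold squared-correlation threshold in (0, 1].
#' @return pruned [snp_panel].
#' @export
ld_prune <- function(g, window = 50, step = 5, r2_threshold = 0.2) {
  if (window < 2) stop("`window` must be >= 2")
  if (step < 1 || step >= window) stop("`step` must satisfy 1 <= step < window")
  if (r2_threshold <= 0 || r2_threshold > 1) stop("`r2_threshold` must be in (0, 1]")
  g <- as_panel(g)
  x <- g$genotypes
  storage.mode(x) <- "double"
  keep <- rep(TRUE, nrow(x))
  repeat {
    removed <- FALSE
    idx <- which(keep)
    if (length(idx) < 2) break
    starts <- seq(1L, max(1L, length(idx) - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r <- suppressWarnings(stats::cor(t(x[win, , drop = FALSE]),
                                       use = "pairwise.complete.obs"))
      r2 <- r * r
      for (a in seq_len(length(win) - 1L)) {
        if (!keep[win[a]]) next
        for (b in seq(a + 1L, length(win))) {
          if (!keep[win[b]]) next
          v <- r2[a, b]
          if (!is.na(v) && v > r2_threshold) {
            keep[win[b]] <- FALSE
            removed <- TRUE
          }
        }
      }
    }
    if (!removed) break
  }
  g[keep, ]
}
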