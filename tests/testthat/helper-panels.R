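# Shared fixtures and independent oracles.

random_panel <- function(m, n, seed = 1, missing_rate = 0) {
  withr::with_seed(seed, {
    g <- matrix(sample(c(-1L, 0L, 1L), m * n, replace = TRUE), m, n)
    if (missing_rate > 0)
      g[runif(m * n) < missing_rate] <- NA_integer_
    snp_panel(g)
  })
}

# Brute-force IBS: explicit double loop over the allele-sharing table.
brute_ibs <- function(a, b = a) {
  ga <- a$genotypes; gb <- b$genotypes
  share <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    2 - abs(x - y)
  }
  W <- matrix(0, ncol(gb), ncol(ga))
  for (i in seq_len(ncol(gb))) for (j in seq_len(ncol(ga)))
    W[i, j] <- sum(mapply(share, gb[, i], ga[, j]))
  W
}

# Brute-force UG relationship matrix (triple loop).
brute_ug <- function(p) {
  g <- p$genotypes
  g[is.na(g)] <- 0L
  m <- nrow(g); n <- ncol(g)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(m)) s <- s + g[k, i] * g[k, j]
    G[i, j] <- s / m
  }
  G
}

# Independently pack a genotype matrix into .bed body bytes (per-element
# loop, no vectorized sharing with the implementation).
brute_pack_bed <- function(geno) {
  code <- function(g) {
    if (is.na(g)) return(1L)
    switch(as.character(g), `-1` = 0L, `0` = 2L, `1` = 3L)
  }
  m <- nrow(geno); n <- ncol(geno)
  bpv <- ceiling(n / 4)
  out <- raw(0)
  for (v in seq_len(m)) {
    codes <- integer(4 * bpv)
    for (s in seq_len(n)) codes[s] <- code(geno[v, s])
    for (b in seq_len(bpv)) {
      i <- (b - 1) * 4
      out <- c(out, as.raw(codes[i + 1] + 4 * codes[i + 2] +
                             16 * codes[i + 3] + 64 * codes[i + 4]))
    }
  }
  out
}

# Greedy LD-pruning oracle for a single window covering all variants:
# scan ordered pairs, drop the later variant of any violating pair,
# repeat to a fixed point.
brute_ld_prune <- function(p, r2_threshold) {
  x <- p$genotypes
  storage.mode(x) <- "double"
  keep <- rep(TRUE, nrow(x))
  repeat {
    removed <- FALSE
    idx <- which(keep)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        if (!keep[i] || !keep[j]) next
        r <- suppressWarnings(stats::cor(x[i, ], x[j, ],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_threshold) {
          keep[j] <- FALSE
          removed <- TRUE
        }
      }
    }
    if (!removed) break
  }
  which(keep)
}
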