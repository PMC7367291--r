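test_that("randomized SVD is exact on diagonals, accurate on decaying spectra, deterministic", {
  A <- diag(c(5, 4, 3, 2, 1))
  s <- randomized_svd(A, k = 2, seed = 1)
  expect_equal(s$d, c(5, 4))

  # well-separated spectrum: top singular values to 1e-6 relative
  withr::with_seed(31, {
    u <- qr.Q(qr(matrix(rnorm(100 * 20), 100, 20)))
    v <- qr.Q(qr(matrix(rnorm(80 * 20), 80, 20)))
    A2 <- u %*% diag(2^(10:-9)) %*% t(v)
  })
  s2 <- randomized_svd(A2, k = 5, seed = 2)
  d_ref <- svd(A2)$d[1:5]
  expect_lt(max(abs(s2$d - d_ref) / d_ref), 1e-6)

  # same seed twice -> bit-identical
  s3 <- randomized_svd(A2, k = 5, seed = 2)
  expect_identical(s2, s3)
  expect_false(identical(randomized_svd(A2, k = 5, seed = 3)$u, s2$u))
  expect_error(randomized_svd(A2, k = 90), "exceeds")
})

test_that("SUGIBS solves the generalized eigenproblem of (G, D)", {
  p <- random_panel(30, 40, seed = 32, missing_rate = 0.05)
  fit <- ancestry_space(p, k = 3, method = "sugibs")
  G <- ug_relationship(p)
  d <- ibs_degrees(p)
  # dense generalized symmetric eigensolver on (G, D)
  B <- diag(1 / sqrt(d)) %*% G %*% diag(1 / sqrt(d))
  ee <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- ee$values[2:4]
  expect_lt(max(abs(fit$singular_values^2 / 30 - lam)), 1e-8)
  V <- diag(1 / sqrt(d)) %*% ee$vectors[, 2:4]
  for (j in 1:3) {
    err <- min(sum((fit$scores[, j] - V[, j])^2), sum((fit$scores[, j] + V[, j])^2))
    expect_lt(err, 1e-16)
  }
  # direct residual of the generalized eigen identity
  lamhat <- fit$singular_values^2 / n_variants(p)
  resid <- G %*% fit$scores - (d * fit$scores) %*% diag(lamhat)
  expect_lt(max(abs(resid)), 1e-8)
  # generalized orthonormality V' D V = I
  expect_lt(max(abs(crossprod(fit$scores, d * fit$scores) - diag(3))), 1e-8)
})

test_that("randomized and dense SUGIBS paths agree on structured axes", {
  # three well-separated populations: both retained components stand clear
  # of the noise bulk, where sketching converges fast
  withr::with_seed(9, {
    p_anc <- runif(2000, 0.1, 0.9)
    ne <- fst_to_ne(0.2, 20)
    f <- vapply(1:3, function(i) sugibs:::.drift(p_anc, ne, 20), numeric(2000))
    panel <- snp_panel(matrix(sugibs:::.rgeno(f[, rep(1:3, each = 30)]), 2000, 90))
  })
  dense <- ancestry_space(panel, k = 2, method = "sugibs", svd_method = "dense")
  rnd <- ancestry_space(panel, k = 2, method = "sugibs", svd_method = "randomized",
                        seed = 5, power_iters = 4)
  expect_lt(max(abs(rnd$singular_values - dense$singular_values) /
                  dense$singular_values), 1e-6)
  expect_gt(min(abs(diag(stats::cor(rnd$scores, dense$scores)))), 0.99999)
})

test_that("SUGIBS separates simulated populations and self-projection is exact", {
  dr <- simulate_drift(2000, 0.1, seed = 35)
  sim <- simulate_admixed(dr, 80, seed = 36)
  panel <- sim$panel[maf(sim$panel) > 0, ]
  fit <- ancestry_space(panel, k = 1, method = "sugibs")
  expect_gt(ancestry_correlation(fit, sim$alpha), 0.99)

  proj <- predict(fit, panel, reference = panel)
  expect_lt(max(abs(proj$scores - fit$scores)), 1e-10)
  expect_error(predict(fit, panel), "reference")

  # duplicated target sample gets an identical score row
  tgt <- snp_panel(panel$genotypes[, c(1, 1, 2)], variants = panel$variants)
  pr <- predict(fit, tgt, reference = panel)
  expect_equal(pr$scores[1, ], pr$scores[2, ], ignore_attr = TRUE)

  # an all-missing target sample has zero reference degree -> error names it
  tgt$genotypes[, 3] <- NA_integer_
  expect_error(predict(fit, tgt, reference = panel), "I3")

  expect_error(predict(fit, panel[-1, ], reference = panel), "harmonized")
  expect_error(ancestry_space(panel, k = 200), "exceeds")
})

test_that("duplicating every SNP leaves SUGIBS scores unchanged up to normalization", {
  # G and the singular values are invariant; degrees double, so scores (which
  # satisfy V' D V = I) carry a global 1/sqrt(2) rescaling
  p <- random_panel(40, 25, seed = 37)
  doubled <- snp_panel(rbind(p$genotypes, p$genotypes))
  f1 <- ancestry_space(p, k = 2, method = "sugibs")
  f2 <- ancestry_space(doubled, k = 2, method = "sugibs")
  expect_equal(f2$singular_values, f1$singular_values, tolerance = 1e-10)
  expect_lt(max(abs(abs(f1$scores) - sqrt(2) * abs(f2$scores))), 1e-10)
})

test_that("PCA normalizes with allele frequencies and matches a dense SVD oracle", {
  p <- random_panel(20, 25, seed = 38)
  p <- p[maf(p) > 0, ]
  fit <- ancestry_space(p, k = 3, method = "pca")
  # oracle: explicit standardization + LAPACK svd
  g <- p$genotypes
  ph <- (rowMeans(g) + 1) / 2
  z <- (g - (2 * ph - 1)) / sqrt(2 * ph * (1 - ph))
  sv <- svd(z)
  expect_equal(abs(unname(fit$scores)), abs(sv$v[, 1:3]), tolerance = 1e-10)
  expect_equal(fit$singular_values, sv$d[1:3])
  # scores are centered because Z has zero row means
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
  # monomorphic SNPs are rejected with advice
  mono <- snp_panel(rbind(matrix(1L, 1, 25), g))
  expect_error(ancestry_space(mono, k = 2, method = "pca"), "filter_maf")
})

test_that("PCA projection shrinks under missingness; UPCA shifts under missingness but resists rare errors", {
  dr <- simulate_drift(3000, 0.1, seed = 39)
  half <- rep(c(1, 0), each = 40)
  ref <- simulate_admixed(dr, 80, alpha = half, seed = 40)$panel
  tgt <- simulate_admixed(dr, 60, alpha = rep(c(1, 0), each = 30), seed = 41)$panel
  keep <- maf(ref) >= 0.01
  ref <- ref[keep, ]; tgt <- tgt[keep, ]

  pca <- ancestry_space(ref, k = 2, method = "pca")
  clean <- predict(pca, tgt)$scores
  # an uncorrupted target drawn from the reference populations lands inside
  # the reference score range on the structured axis
  expect_true(all(clean[, 1] >= min(pca$scores[, 1]) - 0.05 &
                    clean[, 1] <= max(pca$scores[, 1]) + 0.05))
  half_missing <- inject_missing(tgt, 0.5, seed = 42)
  shrunk <- predict(pca, half_missing)$scores
  expect_lt(mean(abs(shrunk[, 1])), 0.6 * mean(abs(clean[, 1])))
  # an all-missing sample projects exactly to the origin under PCA
  allmiss <- tgt
  allmiss$genotypes[, 1] <- NA_integer_
  expect_equal(unname(predict(pca, allmiss)$scores[1, ]), c(0, 0))

  upca <- ancestry_space(ref, k = 2, method = "upca")
  uc <- predict(upca, tgt)$scores
  # rare-SNP errors barely move UPCA scores
  rare <- maf(ref) < 0.05
  err <- tgt
  err$genotypes[rare, ] <- inject_errors(tgt[rare, ], 0.05, maf_ceiling = 1,
                                         seed = 43)$genotypes
  ue <- predict(upca, err)$scores
  expect_lt(max(nrmsd(uc, ue)), 0.02)
  # 5% missing displaces UPCA scores by an order of magnitude more
  um <- predict(upca, inject_missing(tgt, 0.05, seed = 44))$scores
  expect_gt(max(nrmsd(uc, um)), 5 * max(nrmsd(uc, ue)))
})

test_that("UPCA separates two populations on its first retained component", {
  dr <- simulate_drift(2000, 0.1, seed = 45)
  sim <- simulate_admixed(dr, 80, seed = 46)
  fit <- ancestry_space(sim$panel, k = 1, method = "upca")
  expect_gt(ancestry_correlation(fit, sim$alpha), 0.99)
  # dense oracle: components 2..k+1 of the raw genotype SVD
  p <- random_panel(20, 25, seed = 47)
  f <- ancestry_space(p, k = 2, method = "upca")
  g <- p$genotypes; storage.mode(g) <- "double"
  sv <- svd(g)
  expect_equal(abs(unname(f$loadings)),
               abs(sv$u[, 2:3] %*% diag(1 / sv$d[2:3])), tolerance = 1e-10)
})

test_that("classical MDS on IBS distances recovers structure and the Gram identity", {
  dr <- simulate_drift(2000, 0.1, seed = 48)
  sim <- simulate_admixed(dr, 60, seed = 49)
  mds <- ibs_mds(sim$panel, k = 1)
  expect_gt(ancestry_correlation(mds, sim$alpha), 0.99)

  p <- random_panel(300, 10, seed = 50, missing_rate = 0.05)
  full <- ibs_mds(p, k = 9)
  expect_lt(max(abs(colMeans(full$coordinates))), 1e-10)  # centered
  expect_true(all(diff(full$eigenvalues) <= 1e-9))        # descending
  # coordinates reproduce the positive part of the double-centered matrix
  D2 <- full$distances^2
  J <- diag(10) - 1 / 10
  Bmat <- -0.5 * J %*% D2 %*% J
  ee <- eigen((Bmat + t(Bmat)) / 2, symmetric = TRUE)
  pos <- ee$values > 1e-12
  Bpos <- ee$vectors[, pos] %*% diag(ee$values[pos]) %*% t(ee$vectors[, pos])
  expect_equal(tcrossprod(full$coordinates[, full$eigenvalues > 1e-12]),
               Bpos, tolerance = 1e-8, ignore_attr = TRUE)
  # and the reconstructed distances agree closely
  dhat <- as.matrix(dist(full$coordinates[, full$eigenvalues > 1e-12]))
  expect_gt(cor(dhat[upper.tri(dhat)], full$distances[upper.tri(dhat)]), 0.99)

  # identical samples sit at distance zero
  q <- snp_panel(matrix(rep(c(-1L, 1L), 50), 100, 2))
  mq <- ibs_mds(q, k = 1)
  expect_equal(mq$distances[1, 2], 0)
  expect_equal(mq$coordinates[1, 1], mq$coordinates[2, 1])
  expect_error(ibs_mds(q, k = 5), "N - 1")
})

test_that("component-count suggestion finds no structure in homogeneous panels", {
  dr <- simulate_drift(1200, 0.1, seed = 51)
  hom <- simulate_admixed(dr, 60, alpha = rep(1, 60), seed = 52)$panel
  expect_equal(suggest_component_count(hom, max_k = 4, n_null = 10, seed = 1), 0L)
  two <- simulate_admixed(dr, 60, alpha = rep(c(1, 0), 30), seed = 53)$panel
  expect_gte(suggest_component_count(two, max_k = 4, n_null = 10, seed = 1), 1L)
})

test_that("model directories round-trip through TSV serialization", {
  dr <- simulate_drift(500, 0.1, seed = 54)
  sim <- simulate_admixed(dr, 40, seed = 55)
  panel <- sim$panel[maf(sim$panel) > 0, ]
  for (meth in c("sugibs", "pca", "upca")) {
    fit <- ancestry_space(panel, k = 2, method = meth)
    dir <- tempfile()
    write_ancestry_space(fit, dir)
    back <- read_ancestry_space(dir)
    expect_equal(back$loadings, fit$loadings, tolerance = 1e-12)
    expect_equal(back$singular_values, fit$singular_values, tolerance = 1e-12)
    pr1 <- predict(fit, panel, reference = panel)
    pr2 <- predict(back, panel, reference = panel)
    expect_equal(pr1$scores, pr2$scores, tolerance = 1e-10)
  }
})

test_that("print, summary, coef and plot methods behave", {
  p <- random_panel(50, 20, seed = 56)
  fit <- ancestry_space(p, k = 2, method = "upca")
  expect_output(print(fit), "UPCA")
  expect_output(print(summary(fit)), "share of retained variance")
  expect_identical(coef(fit), fit$loadings)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  expect_output(print(ibs_mds(p, k = 2)), "ibs_mds")
  expect_output(print(predict(fit, p)), "ancestry_projection")
  expect_output(print(p), "snp_panel")
})
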