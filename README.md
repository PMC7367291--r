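# sugibs

Robust genome-wide ancestry inference for heterogeneous genotype datasets.

`sugibs` builds reference ancestry spaces from SNP genotypes by a
**s**pectral decomposition of the **u**nnormalized **g**enomic relationship
matrix, generalized by **IBS** similarity degrees (SUGIBS), and projects new
samples onto such spaces with a per-individual correction that is robust to
missing genotypes and genotyping/imputation errors.  It is aimed at
population and statistical geneticists who need one consistent ancestry
space across datasets produced by different genotyping and imputation
protocols — including low-quality profiles such as ancient DNA — without the
aggressive variant filtering that frequency-normalized PCA requires.

## The method

With `X` the M×N additively coded genotype matrix (aa = −1, Aa = 0, AA = +1,
missing → 0), `G = (1/M)XᵀX` the unnormalized relationship matrix, and `D`
the diagonal matrix of IBS similarity degrees `d_i = Σ_j W_ij` (allele-sharing
counts, no missingness normalization), SUGIBS components are generalized
eigenvectors

```
G v_k = λ_k D v_k ,
```

computed from the SVD of `X D^(−1/2)` (randomized SVD at scale); the first
eigenvector only carries the average SNP pattern and is discarded.  A new
cohort `X̃` is projected as

```
Ṽ = D̃^(−1) X̃ᵀ L ,    L = U_k Σ_k^(−1) ,
```

where the reference degree `d̃_i` is target sample i's summed IBS similarity
to the reference panel.  Errors and missingness move `X̃ᵀL` and `d̃_i` in the
same direction, so the weighting cancels artefacts individual by individual.
Because neither fit nor projection uses allele frequencies, single outliers
do not hijack the top components the way they do in PCA.

The package also provides the comparator methods (frequency-standardized
PCA, unnormalized PCA, classical MDS on IBS distances), PLINK 1 binary
input/output with dataset harmonization and the recommended variant filters,
drift/admixture/case-control/outlier simulators, a vectorized per-SNP
logistic likelihood-ratio scan, and the evaluation harnesses used by the
test suite.

## Worked example

```r
library(sugibs)

# two populations at Fst = 0.1, an admixed cohort of 200 individuals
drift <- simulate_drift(m = 3200, fst = 0.1, seed = 1)
cohort <- simulate_admixed(drift, n = 200, seed = 2)
panel <- cohort$panel[maf(cohort$panel) > 0, ]

fit <- ancestry_space(panel, k = 2, method = "sugibs", seed = 1)
fit
#> ancestry_space [SUGIBS]: 2 components, 3196 variants, 200 reference samples
#> singular values: 0.12500 0.04531

# the first component tracks the simulated ancestry proportion
ancestry_correlation(fit, cohort$alpha)
#> [1] 0.9968555

# project a corrupted copy of the cohort: 5% of calls masked, byte-style
corrupt <- inject_missing(panel, rate = 0.05, seed = 3)
proj <- predict(fit, corrupt, reference = panel)
round(nrmsd(fit$scores, proj$scores), 4)
#>     C1     C2
#> 0.0074 0.0101
```

The corrupted copy projects within ~1% of the clean axis ranges
(`nrmsd` is the root-mean-square score deviation normalized by the clean
axis range).  The first singular value dominating the second reflects the
single admixture dimension in the simulated cohort; repeating the projection
through `method = "pca"` on the same corrupted panel gives NRMSD 0.0185 on
the structured axis — two and a half times larger, the classic shrinkage —
and the gap widens with error-type corruption and on real multi-population
panels (see the projection experiment in the test suite).

Fitting from PLINK files works the same way
(`ancestry_space(read_plink("cohort"), ...)`), and a thin command-line
wrapper around the package functions is installed at
`system.file("cli", "sugibs", package = "sugibs")` with `fit`, `project`,
`simulate` and `benchmark` subcommands.

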