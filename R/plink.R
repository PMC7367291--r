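#' Read a PLINK 1 binary fileset
#'
#' Reads a `.bed`/`.bim`/`.fam` triplet into an [snp_panel].  Only the
#' SNP-major layout (mode byte 0x01) is supported.  Two-bit codes are decoded
#' as 00 = homozygous allele1 = -1, 10 = heterozygous = 0, 11 = homozygous
#' allele2 = +1, 01 = missing, reading bit pairs from the low bits of each
#' byte upward; pad bits in the trailing byte of each variant are ignored.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return An [snp_panel].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "))

  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"),
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"),
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  m <- nrow(bim)
  n <- nrow(fam)
  bpv <- ceiling(n / 4)  # bytes per variant

  sz <- file.size(paths[1])
  raw <- readBin(paths[1], "raw", n = sz)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files (mode byte 0x01) are supported")
  if (length(raw) != 3 + bpv * m)
    stop(sprintf(".bed length %d inconsistent with %d variants x %d samples (expected %d)",
                 length(raw), m, n, 3 + bpv * m))

  if (m == 0L || n == 0L)
    return(snp_panel(matrix(integer(), m, n), bim, fam))

  body <- as.integer(raw[-(1:3)])
  # 256 x 4 lookup: genotype of each 2-bit slot for every byte value
  lut <- .plink_decode_lut()
  codes <- lut[body + 1L, , drop = FALSE]        # (bpv*m) x 4, byte fastest
  arr <- array(codes, dim = c(bpv, m, 4L))
  arr <- aperm(arr, c(3L, 1L, 2L))               # slot, byte, variant
  geno <- matrix(arr, nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  geno <- t(geno)
  snp_panel(geno, bim, fam)
}

.plink_decode_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      # 2-bit code -> genotype: 00 -> -1, 01 -> NA, 10 -> 0, 11 -> +1
      code_map <- c(-1L, NA_integer_, 0L, 1L)
      b <- 0:255
      lut <<- cbind(code_map[b %% 4L + 1L],
                    code_map[(b %/% 4L) %% 4L + 1L],
                    code_map[(b %/% 16L) %% 4L + 1L],
                    code_map[(b %/% 64L) %% 4L + 1L])
    }
    lut
  }
})

#' Write a PLINK 1 binary fileset
#'
#' Writes an [snp_panel] as a SNP-major `.bed` plus `.bim`/`.fam` text files.
#' `read_plink(write_plink(g, p))` is an identity (bit-exact on the `.bed`
#' body; pad bits are written as zero).
#'
#' @param g an [snp_panel].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  g <- as_panel(g)
  m <- n_variants(g)
  n <- n_samples(g)
  bpv <- ceiling(n / 4)

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0L && n > 0L) {
    # genotype -> 2-bit code: -1 -> 0, NA -> 1, 0 -> 2, +1 -> 3
    enc <- g$genotypes + 2L          # -1/0/1 -> 1/2/3
    enc <- c(0L, 2L, 3L)[enc]
    enc[is.na(enc)] <- 1L
    e <- matrix(0L, 4L * bpv, m)
    e[seq_len(n), ] <- matrix(enc, nrow = n, byrow = TRUE)  # sample-major per variant
    i1 <- seq(1L, 4L * bpv, by = 4L)
    bytes <- e[i1, , drop = FALSE] + 4L * e[i1 + 1L, , drop = FALSE] +
      16L * e[i1 + 2L, , drop = FALSE] + 64L * e[i1 + 3L, , drop = FALSE]
    writeBin(as.raw(bytes), con)
  }

  utils::write.table(g$variants, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(g$samples, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
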