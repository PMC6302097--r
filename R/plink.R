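# PLINK 1 binary (bed/bim/fam) interchange, SNP-major bed v1.
# Two-bit codes per genotype: 00 = hom A1 (dosage 2), 10 = het (1),
# 11 = hom A2 (0), 01 = missing; individuals packed 4 per byte, lowest
# bits first.

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix (writes `prefix.bed`, `.bim`, `.fam`).
#' @return Invisibly, the three file paths.
#' @export
write_plink <- function(geno, prefix) {
  d <- geno$dosages
  n <- nrow(d); m <- ncol(d)
  bim <- data.frame(chr = geno$snps$chr, id = geno$snps$id, cm = 0,
                    bp = geno$snps$bp, a1 = geno$snps$a1, a2 = geno$snps$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = geno$samples$id, iid = geno$samples$id,
                    pat = 0, mat = 0,
                    sex = ifelse(geno$samples$sex == "male", 1L, 2L),
                    pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  code <- matrix(3L, n, m)                     # 11 = dosage 0
  code[d == 2] <- 0L; code[d == 1] <- 2L       # 00 = dosage 2, 10 = het
  code[is.na(d)] <- 1L                         # 01 = missing
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4 - n
  if (pad > 0) code <- rbind(code, matrix(3L, pad, m))  # pad with hom A2
  # pack 4 individuals per byte, first individual in the two lowest bits
  idx <- matrix(seq_len(bytes_per_snp * 4), nrow = 4)
  packed <- code[idx[1, ], , drop = FALSE] +
    code[idx[2, ], , drop = FALSE] * 4L +
    code[idx[3, ], , drop = FALSE] * 16L +
    code[idx[4, ], , drop = FALSE] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(packed)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a PLINK bed/bim/fam triplet
#'
#' Only the SNP-major bed dialect (v1, third magic byte `0x01`) is
#' supported; sample-major files raise an error. fam sex codes 1/2 map to
#' male/female.
#'
#' @param prefix path prefix of the `.bed`, `.bim`, `.fam` files.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chr", "id", "cm", "bp", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes)", call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("sample-major bed files are not supported", call. = FALSE)
  body <- as.integer(raw[-(1:3)])
  bytes_per_snp <- ceiling(n / 4)
  if (length(body) != bytes_per_snp * m)
    stop("bed size inconsistent with bim/fam dimensions", call. = FALSE)
  # unpack two-bit codes
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  codes <- matrix(as.vector(codes), nrow = bytes_per_snp * 4)[seq_len(n), , drop = FALSE]
  d <- matrix(NA_integer_, n, m)
  d[codes == 0L] <- 2L; d[codes == 2L] <- 1L; d[codes == 3L] <- 0L
  genotype_matrix(
    dosages = d,
    snps = data.frame(id = bim$id, chr = bim$chr, bp = bim$bp,
                      a1 = bim$a1, a2 = bim$a2, stringsAsFactors = FALSE),
    samples = data.frame(id = fam$iid,
                         sex = ifelse(fam$sex == 1L, "male", "female"),
                         stringsAsFactors = FALSE)
  )
}
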