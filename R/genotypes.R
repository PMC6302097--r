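#' Genotype container
#'
#' An individuals-by-SNPs dosage matrix with its SNP map and sample sheet.
#' Dosages count copies of allele 1 and are `0`, `1`, `2` or `NA`; male
#' non-pseudo-autosomal X genotypes are hemizygous and stored as `{0, 2}`
#' (chromosome 23).
#'
#' @param dosages n x m numeric/integer matrix (`NA` = missing).
#' @param snps data.frame with columns `id`, `chr`, `bp`, `a1`, `a2`.
#' @param samples data.frame with columns `id`, `sex` (`"male"`/`"female"`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snps, samples) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(snps)) stop("dosages/snps dimension mismatch", call. = FALSE)
  if (nrow(dosages) != nrow(samples)) stop("dosages/samples dimension mismatch", call. = FALSE)
  if (anyDuplicated(snps$id)) stop("SNP ids must be unique", call. = FALSE)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  male_x <- dosages[samples$sex == "male", snps$chr == 23L, drop = FALSE]
  if (any(male_x == 1, na.rm = TRUE))
    stop("male X dosages must be {0, 2} (hemizygous coding)", call. = FALSE)
  structure(list(dosages = dosages, snps = as.data.frame(snps),
                 samples = as.data.frame(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d X-linked, %d male)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$snps$chr == 23L),
              sum(x$samples$sex == "male")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by SNP index or id
#' @param geno a [genotype_matrix()].
#' @param snps integer indices, logical mask, or character SNP ids.
#' @return A [genotype_matrix()] restricted to those SNPs.
#' @export
subset_snps <- function(geno, snps) {
  if (is.character(snps)) snps <- match(snps, geno$snps$id)
  if (anyNA(snps)) stop("unknown SNP ids", call. = FALSE)
  genotype_matrix(geno$dosages[, snps, drop = FALSE],
                  geno$snps[snps, , drop = FALSE], geno$samples)
}

#' Subset a genotype matrix by sample index or id
#' @param geno a [genotype_matrix()].
#' @param samples integer indices, logical mask, or character sample ids.
#' @return A [genotype_matrix()] restricted to those samples.
#' @export
subset_samples <- function(geno, samples) {
  if (is.character(samples)) samples <- match(samples, geno$samples$id)
  if (anyNA(samples)) stop("unknown sample ids", call. = FALSE)
  genotype_matrix(geno$dosages[samples, , drop = FALSE], geno$snps,
                  geno$samples[samples, , drop = FALSE])
}

#' Allele-1 frequency per SNP
#'
#' On the X chromosome a male contributes a single allele (his `{0, 2}`
#' dosage divided by 2); autosomal frequencies use two alleles per
#' individual. Missing genotypes are excluded.
#'
#' @param geno a [genotype_matrix()].
#' @return Numeric vector of allele-1 frequencies.
#' @export
snp_freq <- function(geno) {
  d <- geno$dosages
  male <- geno$samples$sex == "male"
  is_x <- geno$snps$chr == 23L
  freq <- numeric(ncol(d))
  if (any(!is_x)) {
    da <- d[, !is_x, drop = FALSE]
    freq[!is_x] <- colMeans(da, na.rm = TRUE) / 2
  }
  if (any(is_x)) {
    dx <- d[, is_x, drop = FALSE]
    num <- colSums(dx[male, , drop = FALSE] / 2, na.rm = TRUE) +
      colSums(dx[!male, , drop = FALSE], na.rm = TRUE)
    den <- colSums(!is.na(dx[male, , drop = FALSE])) +
      2 * colSums(!is.na(dx[!male, , drop = FALSE]))
    freq[is_x] <- num / den
  }
  freq
}

#' Minor allele frequency per SNP
#' @param geno a [genotype_matrix()].
#' @return Numeric vector of MAFs.
#' @export
snp_maf <- function(geno) {
  f <- snp_freq(geno)
  pmin(f, 1 - f)
}

#' Per-SNP missing genotype rate
#' @param geno a [genotype_matrix()].
#' @return Numeric vector of missingness proportions.
#' @export
snp_missing_rate <- function(geno) colMeans(is.na(geno$dosages))

# column-standardized dosages: (x - mean)/sd with NA -> 0 after centering.
# This empirical standardization is what the X-GRM uses; the autosomal GRM
# uses 2p(1-p) scaling instead (see make_grm).
standardize_dosages <- function(geno, snps = NULL) {
  d <- geno$dosages
  if (!is.null(snps)) d <- d[, snps, drop = FALSE]
  mu <- colMeans(d, na.rm = TRUE)
  sdv <- sqrt(colMeans(d^2, na.rm = TRUE) - mu^2)   # population SD
  if (any(sdv == 0 | is.na(sdv)))
    stop("monomorphic SNP cannot be standardized", call. = FALSE)
  z <- sweep(sweep(d, 2, mu), 2, sdv, "/")
  z[is.na(z)] <- 0
  z
}
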