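#' Hard-call genotypes from posterior probabilities
#'
#' The most probable genotype is called only when its probability exceeds
#' the threshold; otherwise the genotype is set missing.
#'
#' @param probabilities n x m x 3 array of genotype probabilities for
#'   dosages 0, 1, 2 (each triple summing to about 1).
#' @param threshold calling threshold; a maximum probability `<= threshold`
#'   gives a missing call.
#' @param snps,samples optional SNP map and sample sheet for the result
#'   (defaults are generated).
#' @return A [genotype_matrix()].
#' @export
hard_call <- function(probabilities, threshold = 0.9, snps = NULL, samples = NULL) {
  stopifnot(length(dim(probabilities)) == 3, dim(probabilities)[3] == 3)
  if (any(probabilities < 0)) stop("negative probabilities", call. = FALSE)
  n <- dim(probabilities)[1]; m <- dim(probabilities)[2]
  flat <- matrix(probabilities, n * m, 3)
  best <- max.col(flat, ties.method = "first")
  pmax_ <- flat[cbind(seq_len(n * m), best)]
  dos <- ifelse(pmax_ > threshold, best - 1L, NA_integer_)
  d <- matrix(as.integer(dos), n, m)
  if (is.null(snps))
    snps <- data.frame(id = sprintf("snp%d", seq_len(m)), chr = 1L,
                       bp = seq_len(m), a1 = "A", a2 = "G")
  if (is.null(samples))
    samples <- data.frame(id = sprintf("ind%d", seq_len(n)), sex = "male")
  genotype_matrix(d, snps, samples)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: enumerates all heterozygote counts compatible with
#' the observed allele counts and sums the probabilities of configurations
#' no more likely than the observed one (plain tail sum, no mid-p
#' correction).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return The exact two-sided p-value.
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all-zero genotype counts", call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)   # feasible heterozygote counts
  # log-probability of each het count given allele counts (Levene/Haldane)
  logp <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    AA <- n - h - aa
    h * log(2) - lfactorial(AA) - lfactorial(h) - lfactorial(aa)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Filter SNPs on MAF, missingness and Hardy-Weinberg equilibrium
#'
#' A SNP survives when `MAF > maf_min`, missing rate `< miss_max` and
#' exact-HWE `p > hwe_min`. With `sex_aware = TRUE`, HWE on non-PAR X SNPs
#' is evaluated in females only (males are haploid there); MAF uses both
#' sexes. X SNPs are exempt from the HWE filter when no females are
#' present.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min,miss_max,hwe_min thresholds.
#' @param sex_aware evaluate X-chromosome HWE in females only.
#' @return The filtered [genotype_matrix()] (possibly with zero SNPs).
#' @export
qc_filter <- function(geno, maf_min = 1e-4, miss_max = 0.05, hwe_min = 1e-6,
                      sex_aware = TRUE) {
  stopifnot(maf_min >= 0, maf_min < 0.5, miss_max >= 0, miss_max <= 1,
            hwe_min >= 0, hwe_min <= 1)
  keep <- rep(TRUE, ncol(geno$dosages))
  if (maf_min > 0) keep <- keep & snp_maf(geno) > maf_min
  if (miss_max < 1) keep <- keep & snp_missing_rate(geno) < miss_max

  if (hwe_min > 0) {
    is_x <- geno$snps$chr == 23L
    female <- geno$samples$sex == "female"
    hwe_p <- vapply(seq_len(ncol(geno$dosages)), function(j) {
      x <- geno$dosages[, j]
      if (is_x[j] && sex_aware) {
        if (!any(female)) return(1)   # all-male sample: males are haploid
        x <- x[female]
      }
      x <- x[!is.na(x)]
      if (length(x) == 0) return(1)
      hwe_exact(sum(x == 2), sum(x == 1), sum(x == 0))
    }, numeric(1))
    keep <- keep & hwe_p > hwe_min
  }
  subset_snps(geno, which(keep))
}
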