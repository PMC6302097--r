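#' Squared LD correlation between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete individuals (missing
#' genotypes are dropped pairwise, never mean-imputed).
#'
#' @param x_i,x_j dosage vectors for the same individuals.
#' @param adjusted apply the small-sample bias adjustment
#'   `r2_adj = r2 - (1 - r2)/(n - 2)`; the default is the raw squared
#'   correlation.
#' @return The r-squared value.
#' @export
ld_r2 <- function(x_i, x_j, adjusted = FALSE) {
  if (length(x_i) != length(x_j)) stop("vectors must cover the same individuals", call. = FALSE)
  ok <- !is.na(x_i) & !is.na(x_j)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete individuals", call. = FALSE)
  x <- x_i[ok]; y <- x_j[ok]
  if (var(x) == 0 || var(y) == 0)
    stop("zero-variance dosage vector: r2 undefined", call. = FALSE)
  r2 <- cor(x, y)^2
  if (adjusted) r2 <- r2 - (1 - r2) / (sum(ok) - 2)
  r2
}

# correlation between two column sets: BLAS path for complete data,
# pairwise-complete otherwise
cor_cols <- function(A, B = NULL) {
  if (anyNA(A) || (!is.null(B) && anyNA(B)))
    return(suppressWarnings(cor(A, B, use = "pairwise.complete.obs")))
  n <- nrow(A)
  Za <- scale(A)
  Zb <- if (is.null(B)) Za else scale(B)
  suppressWarnings(crossprod(Za, Zb) / (n - 1))
}

#' Per-SNP LD scores
#'
#' The LD score of SNP i is the sum of squared dosage correlations with all
#' SNPs on the same chromosome within a window of `window_bp` centred on it
#' (i.e. within `window_bp/2` either side), including the SNP itself, so
#' scores are at least 1.
#'
#' @param geno a [genotype_matrix()] with SNPs sorted by (chr, bp).
#' @param window_bp full window width in base pairs (default 20 Mb).
#' @param adjusted use bias-adjusted r-squared (see [ld_r2()]).
#' @return Numeric vector of LD scores.
#' @export
ld_scores <- function(geno, window_bp = 2e7, adjusted = FALSE) {
  snps <- geno$snps
  ord <- order(snps$chr, snps$bp)
  if (!identical(ord, seq_len(nrow(snps))))
    stop("SNP map must be sorted by chromosome and position", call. = FALSE)
  half <- window_bp / 2
  m <- nrow(snps)
  l <- numeric(m)
  n_used <- nrow(geno$dosages)
  for (ch in unique(snps$chr)) {
    idx <- which(snps$chr == ch)
    d <- geno$dosages[, idx, drop = FALSE]
    bp <- snps$bp[idx]
    block <- 512L
    for (s in seq(1, length(idx), by = block)) {
      e <- min(s + block - 1L, length(idx))
      lo <- findInterval(bp[s] - half, bp) + 1L
      hi <- findInterval(bp[e] + half, bp)
      r <- cor_cols(d[, s:e, drop = FALSE], d[, lo:hi, drop = FALSE])
      r2 <- r^2
      if (adjusted) r2 <- r2 - (1 - r2) / (n_used - 2)
      # zero out pairs outside the bp window
      inwin <- abs(outer(bp[s:e], bp[lo:hi], "-")) <= half
      r2[!inwin] <- 0
      r2[is.na(r2)] <- 0
      l[idx[s:e]] <- rowSums(r2)
    }
  }
  l
}

#' Assign SNPs to MAF x LD-score components
#'
#' MAF bins use half-open intervals `(b, b']` as given by `maf_breaks`
#' (default: rare `(1.5e-5, 1e-3]`, low-frequency `(1e-3, 0.01]`, common
#' `(0.01, 0.5)`); MAFs below the lowest break fall in the first bin.
#' LD-score quartiles are genome-wide and rank-based, ties broken by input
#' order, so quartile sizes differ by at most one.
#'
#' @param maf per-SNP minor allele frequencies in (0, 0.5].
#' @param ld_score per-SNP LD scores.
#' @param maf_breaks MAF bin edges (length `n_bins + 1`).
#' @param n_ld_quartiles number of LD-score groups (default quartiles).
#' @return A data.frame with `maf`, `ld_score`, `maf_bin`, `ld_quartile`
#'   and the combined `component` index (bin-major:
#'   `(maf_bin - 1) * n_ld_quartiles + ld_quartile`).
#' @export
assign_ldms_bins <- function(maf, ld_score,
                             maf_breaks = c(1.5e-5, 1e-3, 0.01, 0.5),
                             n_ld_quartiles = 4) {
  if (any(maf <= 0) || any(maf > 0.5))
    stop("MAF must lie in (0, 0.5]", call. = FALSE)
  stopifnot(length(maf) == length(ld_score))
  bin <- cut(pmax(maf, maf_breaks[1] * (1 + 1e-9)), breaks = maf_breaks,
             labels = FALSE, right = TRUE, include.lowest = TRUE)
  r <- rank(ld_score, ties.method = "first")
  q <- ceiling(r * n_ld_quartiles / length(ld_score))
  data.frame(maf = maf, ld_score = ld_score,
             maf_bin = as.integer(bin), ld_quartile = as.integer(q),
             component = (as.integer(bin) - 1L) * n_ld_quartiles + as.integer(q))
}

#' Prune SNPs in high LD
#'
#' Sliding-window pruning: within each window of `window_snps` SNPs the
#' later member of any retained pair with `r2 > r2_max` is removed; the
#' window then advances by `step` SNPs. Deterministic given input order.
#'
#' @param geno a [genotype_matrix()] with a sorted SNP map.
#' @param r2_max r-squared threshold above which the later SNP is dropped.
#' @param window_snps window size in SNPs.
#' @param step window step in SNPs.
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(geno, r2_max = 0.9, window_snps = 1000, step = 100) {
  snps <- geno$snps
  ord <- order(snps$chr, snps$bp)
  if (!identical(ord, seq_len(nrow(snps))))
    stop("SNP map must be sorted by chromosome and position", call. = FALSE)
  m <- nrow(snps)
  keep <- rep(TRUE, m)
  for (ch in unique(snps$chr)) {
    idx <- which(snps$chr == ch)
    s <- 1L
    repeat {
      e <- min(s + window_snps - 1L, length(idx))
      win <- idx[s:e][keep[idx[s:e]]]
      if (length(win) > 1) {
        r2 <- cor_cols(geno$dosages[, win, drop = FALSE])^2
        r2[is.na(r2)] <- 0
        for (a in seq_along(win)) {
          if (!keep[win[a]]) next
          hit <- which(r2[a, ] > r2_max)
          hit <- hit[hit > a & keep[win[hit]]]
          if (length(hit)) keep[win[hit]] <- FALSE
        }
      }
      if (e >= length(idx)) break
      s <- s + step
    }
  }
  snps$id[keep]
}
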