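# LD score regression: univariate SNP-heritability and bivariate genetic
# correlation, with block-jackknife uncertainty over contiguous SNP blocks.

# weighted least squares of y on (1, x); returns c(intercept, slope)
wls_line <- function(x, y, w) {
  sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  slope <- sum(w * (x - mx) * (y - my)) / sum(w * (x - mx)^2)
  c(my - slope * mx, slope)
}

# leave-one-block-out estimates of a statistic computed by f(idx_keep)
block_jackknife <- function(m, n_blocks, f) {
  n_blocks <- min(n_blocks, m)
  edges <- floor(seq(0, m, length.out = n_blocks + 1))
  est <- vapply(seq_len(n_blocks), function(b) {
    keep <- setdiff(seq_len(m), (edges[b] + 1):edges[b + 1])
    f(keep)
  }, numeric(1))
  list(values = est,
       se = sqrt((n_blocks - 1) / n_blocks * sum((est - mean(est))^2)))
}

#' SNP-heritability by LD score regression
#'
#' Regresses per-SNP association chi-squared statistics on LD scores with a
#' free intercept; the slope times `M / N` estimates the SNP-heritability.
#' Heteroskedasticity weights `1 / l_j` with the over-counting correction
#' `1 / (1 + N h2 l_j / M)^2` are applied in a second pass (first pass
#' unweighted to obtain a provisional slope). Standard errors come from a
#' leave-one-block-out jackknife over contiguous SNP blocks.
#'
#' @param sumstats summary statistics ([validate_sumstats()] format).
#' @param ld_scores data.frame with columns `SNP`, `l` (or a numeric vector
#'   aligned to `sumstats`).
#' @param m_total number of SNPs the LD scores sum over (defaults to the
#'   number of regression SNPs).
#' @param n_blocks jackknife block count.
#' @return An object of class `ldsc_fit`: `intercept`, `slope`, `h2`,
#'   `se_h2`, `se_intercept`, `n_blocks`, `n_snps`, `n_eff`.
#' @export
ldsc_h2 <- function(sumstats, ld_scores, m_total = NULL, n_blocks = 200) {
  sumstats <- validate_sumstats(sumstats)
  if (is.data.frame(ld_scores)) {
    idx <- match(sumstats$SNP, ld_scores$SNP)
    if (anyNA(idx)) stop("missing LD scores for some SNPs", call. = FALSE)
    l <- ld_scores$l[idx]
  } else l <- as.numeric(ld_scores)
  stopifnot(length(l) == nrow(sumstats))
  m <- nrow(sumstats)
  if (m < 2 || n_blocks < 2) stop("need at least 2 SNPs and 2 blocks", call. = FALSE)
  if (any(is.na(sumstats$N))) stop("sample size N required", call. = FALSE)
  M <- m_total %||% m
  nbar <- mean(sumstats$N)
  chi2 <- (sumstats$b / sumstats$se)^2

  fit0 <- wls_line(l, chi2, rep(1, m))
  h2_0 <- max(fit0[2] * M / nbar, 0)
  w <- 1 / (pmax(l, 1) * (1 + nbar * h2_0 * pmax(l, 1) / M)^2)
  est_fun <- function(keep) wls_line(l[keep], chi2[keep], w[keep])[2] * M / nbar
  fit <- wls_line(l, chi2, w)
  h2 <- fit[2] * M / nbar
  jk <- block_jackknife(m, n_blocks, est_fun)
  jk_int <- block_jackknife(m, n_blocks,
                            function(keep) wls_line(l[keep], chi2[keep], w[keep])[1])
  structure(list(intercept = fit[1], slope = fit[2], h2 = h2, se_h2 = jk$se,
                 se_intercept = jk_int$se, n_blocks = length(jk$values),
                 n_snps = m, n_eff = nbar, m_total = M,
                 weights = "1/l with over-counting correction"),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("ldsc_fit: h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), %d SNPs\n",
              x$h2, x$se_h2, x$intercept, x$se_intercept, x$n_snps))
  invisible(x)
}

#' Genetic correlation by bivariate LD score regression
#'
#' After allele harmonization on shared SNPs, the product of the two
#' traits' z-scores is regressed on LD scores; the slope times
#' `M / sqrt(N1 N2)` estimates the genetic covariance, and the genetic
#' correlation divides it by the geometric mean of the two
#' SNP-heritabilities. The standard error and p-value come from a block
#' jackknife of the genetic-correlation estimate.
#'
#' @param sumstats1,sumstats2 summary statistics for the two traits.
#' @param ld_scores data.frame (`SNP`, `l`) covering the shared SNPs.
#' @param m_total number of SNPs the LD scores sum over.
#' @param n_blocks jackknife block count.
#' @param h2_min traits with estimated h2 below this trigger a warning
#'   (results are poorly determined); non-positive h2 is an error.
#' @return An object of class `rg_result`: `rg`, `se`, `p`,
#'   `cross_intercept`, `gcov`, `h2_1`, `h2_2`, `n_snps`.
#' @export
ldsc_rg <- function(sumstats1, sumstats2, ld_scores, m_total = NULL,
                    n_blocks = 200, h2_min = 0.05) {
  s1 <- validate_sumstats(sumstats1)
  s2 <- validate_sumstats(sumstats2)
  idx <- match(s1$SNP, s2$SNP)
  keep <- !is.na(idx)
  s1 <- s1[keep, , drop = FALSE]; s2 <- s2[idx[keep], , drop = FALSE]
  same <- s1$A1 == s2$A1 & s1$A2 == s2$A2
  swap <- s1$A1 == s2$A2 & s1$A2 == s2$A1
  s2$b[swap] <- -s2$b[swap]
  s1 <- s1[same | swap, , drop = FALSE]
  s2 <- s2[same | swap, , drop = FALSE]
  m <- nrow(s1)
  if (m < 2) stop("no shared SNPs after harmonization", call. = FALSE)
  if (is.data.frame(ld_scores)) {
    li <- match(s1$SNP, ld_scores$SNP)
    if (anyNA(li)) stop("missing LD scores for some SNPs", call. = FALSE)
    l <- ld_scores$l[li]
  } else l <- as.numeric(ld_scores)[keep][same | swap]
  M <- m_total %||% m

  f1 <- ldsc_h2(s1, l, m_total = M, n_blocks = n_blocks)
  f2 <- ldsc_h2(s2, l, m_total = M, n_blocks = n_blocks)
  if (f1$h2 <= 0 || f2$h2 <= 0)
    stop("non-positive heritability estimate: rg undefined", call. = FALSE)
  if (f1$h2 < h2_min || f2$h2 < h2_min)
    warning(sprintf("observed-scale h2 below %.2f for a trait; rg poorly determined", h2_min))

  z12 <- (s1$b / s1$se) * (s2$b / s2$se)
  nbar <- sqrt(mean(s1$N) * mean(s2$N))
  w <- 1 / pmax(l, 1)
  rg_fun <- function(keep_idx) {
    sl <- wls_line(l[keep_idx], z12[keep_idx], w[keep_idx])[2]
    gc <- sl * M / nbar
    h1 <- wls_line(l[keep_idx], (s1$b[keep_idx] / s1$se[keep_idx])^2,
                   w[keep_idx])[2] * M / mean(s1$N)
    h2_ <- wls_line(l[keep_idx], (s2$b[keep_idx] / s2$se[keep_idx])^2,
                    w[keep_idx])[2] * M / mean(s2$N)
    gc / sqrt(max(h1, 1e-12) * max(h2_, 1e-12))
  }
  fit <- wls_line(l, z12, w)
  gcov <- fit[2] * M / nbar
  # same weights for numerator and denominators so self-correlation is exactly 1
  rg <- rg_fun(seq_len(m))
  jk <- block_jackknife(m, n_blocks, rg_fun)
  se <- jk$se
  z <- rg / se
  structure(list(rg = rg, se = se, p = 2 * pnorm(-abs(z)),
                 cross_intercept = fit[1], gcov = gcov,
                 h2_1 = f1$h2, h2_2 = f2$h2, n_snps = m,
                 n_blocks = length(jk$values)),
            class = "rg_result")
}

#' @export
print.rg_result <- function(x, ...) {
  cat(sprintf("rg_result: rg = %.3f (SE %.3f, p = %.3g) from %d SNPs; h2 = %.3f / %.3f\n",
              x$rg, x$se, x$p, x$n_snps, x$h2_1, x$h2_2))
  invisible(x)
}
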