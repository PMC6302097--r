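# Conditional-and-joint SNP selection from GWAS summary statistics with
# reference-panel LD, and a secondary joint-regression pruning pass.
#
# Joint least-squares systems are reconstructed from per-SNP marginal
# statistics: X'y_j = b_j * S_jj with S_jj the centred sum of squares of the
# reference dosages, and y'y from the implied per-SNP residual variance
# (median over SNPs). Cross-products between SNPs farther apart than the
# window, or on different chromosomes, are treated as zero.

# align summary stats to the reference panel; flips b and freq when the
# allele pair is swapped; drops mismatches and large frequency discrepancies
align_sumstats <- function(sumstats, ref_geno, freq_diff_max = 0.2) {
  sumstats <- validate_sumstats(sumstats)
  idx <- match(sumstats$SNP, ref_geno$snps$id)
  keep <- !is.na(idx)
  if (any(!keep)) message(sum(!keep), " SNPs absent from reference panel dropped")
  ss <- sumstats[keep, , drop = FALSE]; idx <- idx[keep]
  ref <- ref_geno$snps[idx, , drop = FALSE]
  same <- ss$A1 == ref$a1 & ss$A2 == ref$a2
  swap <- ss$A1 == ref$a2 & ss$A2 == ref$a1
  bad <- !(same | swap)
  if (any(bad)) message(sum(bad), " SNPs with mismatched alleles dropped")
  ss$b[swap] <- -ss$b[swap]
  ss$freq[swap] <- 1 - ss$freq[swap]
  ss <- ss[!bad, , drop = FALSE]; idx <- idx[!bad]
  rf <- snp_freq(ref_geno)[idx]
  fd <- abs(ss$freq - rf) > freq_diff_max
  if (any(fd)) message(sum(fd), " SNPs with frequency discrepancy > ",
                       freq_diff_max, " excluded")
  list(sumstats = ss[!fd, , drop = FALSE], ref_idx = idx[!fd])
}

# centred, mean-imputed reference dosages plus window metadata
cojo_workspace <- function(sumstats, ref_geno, window_bp) {
  al <- align_sumstats(sumstats, ref_geno)
  ss <- al$sumstats
  if (nrow(ss) == 0) stop("no usable SNPs after alignment", call. = FALSE)
  d <- ref_geno$dosages[, al$ref_idx, drop = FALSE]
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  G <- sweep(d, 2, colMeans(d))
  Sjj <- colSums(G^2)
  Xy <- ss$b * Sjj
  nn <- median(ss$N)
  yty <- median(ss$b^2 * Sjj + ss$se^2 * Sjj * (ss$N - 2))
  list(ss = ss, G = G, Sjj = Sjj, Xy = Xy, n = nn, yty = yty,
       chr = ref_geno$snps$chr[al$ref_idx], bp = ref_geno$snps$bp[al$ref_idx],
       window_bp = window_bp)
}

# masked cross-product matrix between selected SNP columns
cojo_xtx <- function(ws, idx) {
  A <- crossprod(ws$G[, idx, drop = FALSE])
  far <- outer(ws$chr[idx], ws$chr[idx], "!=") |
    abs(outer(ws$bp[idx], ws$bp[idx], "-")) > ws$window_bp
  A[far] <- 0
  diag(A) <- ws$Sjj[idx]
  A
}

# joint fit of the SNPs in idx; returns NULL on a singular system
cojo_joint <- function(ws, idx) {
  k <- length(idx)
  A <- cojo_xtx(ws, idx)
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(NULL)
  beta <- drop(Ai %*% ws$Xy[idx])
  rss <- ws$yty - sum(beta * ws$Xy[idx])
  df <- max(ws$n - k - 1, 1)
  s2 <- max(rss, 1e-12) / df
  se <- sqrt(pmax(s2 * diag(Ai), .Machine$double.xmin))
  z <- beta / se
  list(beta = beta, se = se, p = 2 * pnorm(-abs(z)), rss = rss, Ai = Ai,
       s2 = s2)
}

#' Stepwise conditional-joint SNP selection from summary statistics
#'
#' Forward selection seeded with the most significant SNP: at each step the
#' conditional statistics of all remaining SNPs given the selected set are
#' computed from the marginal summary statistics and reference LD, the best
#' SNP is added if its conditional p-value passes the cutoff and its LD
#' with every selected SNP stays below the collinearity bound, the joint
#' model is refitted, and any selected SNP whose joint p-value has risen
#' above the cutoff is dropped. Terminates when no addition is possible.
#'
#' @param sumstats summary statistics (see [validate_sumstats()]).
#' @param ref_geno reference-panel [genotype_matrix()] supplying LD.
#' @param p_cutoff selection threshold (genome-wide significance).
#' @param collinearity_r2 maximum allowed r-squared between a candidate and
#'   any selected SNP.
#' @param window_bp SNPs farther apart than this (or on different
#'   chromosomes) are treated as uncorrelated.
#' @return An object of class `cojo_result`: `selected` (data.frame with
#'   marginal and joint statistics in selection order), `conditional`
#'   (conditional statistics of non-selected SNPs given the final set),
#'   `ld_r` (correlation matrix of the selected set), plus the inputs
#'   needed by [joint_regression_prune()].
#' @export
cojo_select <- function(sumstats, ref_geno, p_cutoff = 5e-8,
                        collinearity_r2 = 0.9, window_bp = 1e7) {
  ws <- cojo_workspace(sumstats, ref_geno, window_bp)
  m <- nrow(ws$ss)
  sel <- integer(0)
  sel_order <- integer(0)
  seen <- character(0)

  cand_best <- which.min(ws$ss$p)
  if (ws$ss$p[cand_best] < p_cutoff) {
    sel <- cand_best; sel_order <- cand_best
  }
  while (length(sel) > 0) {
    jf <- cojo_joint(ws, sel)
    # backward drop of SNPs no longer jointly significant
    while (!is.null(jf) && length(sel) > 1 && max(jf$p) >= p_cutoff) {
      worst <- sel[which.max(jf$p)]
      sel <- setdiff(sel, worst)
      sel_order <- setdiff(sel_order, worst)
      jf <- cojo_joint(ws, sel)
    }
    key <- paste(sort(sel), collapse = ",")
    if (key %in% seen) break
    seen <- c(seen, key)

    # conditional screen of all remaining SNPs given the selected set
    rem <- setdiff(seq_len(m), sel)
    if (length(rem) == 0 || is.null(jf)) break
    Vm <- crossprod(ws$G[, rem, drop = FALSE], ws$G[, sel, drop = FALSE])
    far <- outer(ws$chr[rem], ws$chr[sel], "!=") |
      abs(outer(ws$bp[rem], ws$bp[sel], "-")) > ws$window_bp
    Vm[far] <- 0
    VAi <- Vm %*% jf$Ai
    s_t <- ws$Sjj[rem] - rowSums(VAi * Vm)
    r2max <- apply(Vm^2 / outer(ws$Sjj[rem], ws$Sjj[sel]), 1, max)
    beta_t <- (ws$Xy[rem] - drop(Vm %*% (jf$Ai %*% ws$Xy[sel]))) / s_t
    rss_t <- jf$rss - beta_t^2 * s_t
    df_t <- max(ws$n - length(sel) - 2, 1)
    s2_t <- pmax(rss_t, 1e-12) / df_t
    z_t <- beta_t * sqrt(pmax(s_t, 0) / s2_t)
    p_t <- 2 * pnorm(-abs(z_t))
    ok <- r2max < collinearity_r2 & s_t / ws$Sjj[rem] > 1e-8
    p_t[!ok] <- 1
    best <- which.min(p_t)
    if (p_t[best] >= p_cutoff) break
    sel <- c(sel, rem[best])
    sel_order <- c(sel_order, rem[best])
  }

  cojo_finalize(ws, sel_order, p_cutoff)
}

# assemble a cojo_result for a given selected index set
cojo_finalize <- function(ws, sel, p_cutoff) {
  if (length(sel) > 0) {
    jf <- cojo_joint(ws, sel)
    A <- cojo_xtx(ws, sel)
    Dinv <- 1 / sqrt(ws$Sjj[sel])
    ld_r <- A * outer(Dinv, Dinv)
    selected <- data.frame(
      SNP = ws$ss$SNP[sel], chr = ws$chr[sel], bp = ws$bp[sel],
      freq = ws$ss$freq[sel], b = ws$ss$b[sel], se = ws$ss$se[sel],
      p = ws$ss$p[sel], b_joint = jf$beta, se_joint = jf$se,
      p_joint = jf$p, stringsAsFactors = FALSE)
    selected$r2_max_selected <- if (length(sel) > 1) {
      r2 <- ld_r^2; diag(r2) <- 0; apply(r2, 1, max)
    } else 0
    rem <- setdiff(seq_len(nrow(ws$ss)), sel)
    conditional <- NULL
    if (length(rem) > 0) {
      Vm <- crossprod(ws$G[, rem, drop = FALSE], ws$G[, sel, drop = FALSE])
      far <- outer(ws$chr[rem], ws$chr[sel], "!=") |
        abs(outer(ws$bp[rem], ws$bp[sel], "-")) > ws$window_bp
      Vm[far] <- 0
      VAi <- Vm %*% jf$Ai
      s_t <- ws$Sjj[rem] - rowSums(VAi * Vm)
      beta_t <- (ws$Xy[rem] - drop(Vm %*% (jf$Ai %*% ws$Xy[sel]))) / s_t
      rss_t <- jf$rss - beta_t^2 * s_t
      s2_t <- pmax(rss_t, 1e-12) / max(ws$n - length(sel) - 2, 1)
      z_t <- beta_t * sqrt(pmax(s_t, 0) / s2_t)
      conditional <- data.frame(SNP = ws$ss$SNP[rem], b_cond = beta_t,
                                p_cond = 2 * pnorm(-abs(z_t)),
                                stringsAsFactors = FALSE)
    }
  } else {
    selected <- data.frame(SNP = character(0), chr = integer(0), bp = integer(0),
                           freq = numeric(0), b = numeric(0), se = numeric(0),
                           p = numeric(0), b_joint = numeric(0),
                           se_joint = numeric(0), p_joint = numeric(0),
                           r2_max_selected = numeric(0))
    ld_r <- matrix(numeric(0), 0, 0)
    conditional <- data.frame(SNP = ws$ss$SNP, b_cond = ws$ss$b, p_cond = ws$ss$p)
  }
  structure(list(selected = selected, conditional = conditional, ld_r = ld_r,
                 p_cutoff = p_cutoff, sumstats = ws$ss),
            class = "cojo_result")
}

#' @export
print.cojo_result <- function(x, ...) {
  cat(sprintf("cojo_result: %d SNPs selected at p < %g\n",
              nrow(x$selected), x$p_cutoff))
  if (nrow(x$selected)) print(x$selected[, c("SNP", "b", "p", "b_joint", "p_joint")])
  invisible(x)
}

#' Secondary joint-regression pruning of a selected SNP set
#'
#' Backward elimination on the joint model of all selected SNPs: while any
#' SNP's joint p-value is at or above `alpha`, the least significant one is
#' removed and the model refitted. A singular joint system drops the
#' higher-index member of the offending dependency first.
#'
#' @param cojo a [cojo_select()] result.
#' @param ref_geno reference-panel [genotype_matrix()].
#' @param alpha joint significance threshold each SNP must survive.
#' @param window_bp LD window (as in [cojo_select()]).
#' @return A pruned `cojo_result`.
#' @export
joint_regression_prune <- function(cojo, ref_geno, alpha = 5e-8,
                                   window_bp = 1e7) {
  stopifnot(inherits(cojo, "cojo_result"))
  if (nrow(cojo$selected) == 0) return(cojo)
  ws <- cojo_workspace(cojo$sumstats, ref_geno, window_bp)
  sel <- match(cojo$selected$SNP, ws$ss$SNP)
  repeat {
    if (length(sel) == 0) break
    jf <- cojo_joint(ws, sel)
    if (is.null(jf)) { sel <- sel[-length(sel)]; next }  # drop higher index
    if (max(jf$p) < alpha) break
    sel <- sel[-which.max(jf$p)]
  }
  cojo_finalize(ws, sel, alpha)
}
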