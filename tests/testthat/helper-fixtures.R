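# shared fixtures and small oracles, all built in code at test time

flat_enrichment <- rbind(0, 0, rep(0.25, 4))

# tiny genotype matrix fixture
toy_geno <- function(dosages, chr = 1L, sex = "male") {
  dosages <- as.matrix(dosages)
  genotype_matrix(
    dosages,
    snps = data.frame(id = sprintf("s%d", seq_len(ncol(dosages))),
                      chr = chr, bp = seq_len(ncol(dosages)) * 1000L,
                      a1 = "A", a2 = "G"),
    samples = data.frame(id = sprintf("i%d", seq_len(nrow(dosages))),
                         sex = sex))
}

# per-SNP ordinary least squares summary statistics (independent of the
# package's mixed-model scan); the reference route for COJO/LDSC checks
ols_sumstats <- function(y, geno) {
  G <- geno$dosages
  Gc <- scale(G, scale = FALSE)
  S <- colSums(Gc^2)
  n <- nrow(G)
  yc <- y - mean(y)
  b <- drop(crossprod(Gc, yc)) / S
  sse <- sum(yc^2) - b^2 * S
  se <- sqrt(pmax(sse, 1e-12) / (n - 2) / S)
  p <- pmax(2 * pnorm(-abs(b / se)), 1e-300)
  data.frame(SNP = geno$snps$id, A1 = geno$snps$a1, A2 = geno$snps$a2,
             freq = snp_freq(geno), b = b, se = se, p = p, N = n,
             stringsAsFactors = FALSE)
}

# restricted log-likelihood evaluated directly (oracle for REML fits)
reml_loglik_direct <- function(theta, y, A_list, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(A_list)) V <- V + theta[i] * A_list[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  P <- Vi - ViX %*% solve(XtViX, t(ViX))
  -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus +
            drop(crossprod(y, P %*% y)))
}

# individual-level stepwise regression oracle mirroring the conditional-joint
# selection rules (forward by conditional p, backward at the cutoff)
stepwise_oracle <- function(y, G, cutoff = 5e-8) {
  Gc <- scale(G, scale = FALSE)
  m <- ncol(Gc)
  marg <- vapply(seq_len(m), function(j) {
    f <- summary(lm(y ~ Gc[, j]))$coefficients
    c(f[2, 1], 2 * pnorm(-abs(f[2, 1] / f[2, 2])))
  }, numeric(2))
  sel <- which.min(marg[2, ])
  if (marg[2, sel] >= cutoff) return(list(sel = integer(0), beta = numeric(0)))
  repeat {
    repeat {
      f <- summary(lm(y ~ Gc[, sel, drop = FALSE]))$coefficients
      ps <- 2 * pnorm(-abs(f[-1, 1] / f[-1, 2]))
      if (length(sel) > 1 && max(ps) >= cutoff) sel <- sel[-which.max(ps)]
      else break
    }
    rem <- setdiff(seq_len(m), sel)
    if (length(rem) == 0) break
    pc <- vapply(rem, function(t) {
      f <- summary(lm(y ~ Gc[, c(sel, t), drop = FALSE]))$coefficients
      k <- nrow(f)
      2 * pnorm(-abs(f[k, 1] / f[k, 2]))
    }, numeric(1))
    best <- which.min(pc)
    if (pc[best] >= cutoff) break
    sel <- c(sel, rem[best])
  }
  beta <- coef(lm(y ~ Gc[, sel, drop = FALSE]))[-1]
  list(sel = sel, beta = unname(beta))
}
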