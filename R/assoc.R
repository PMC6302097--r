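#' Adjust an ordinal phenotype for covariates
#'
#' Least-squares residuals of the scores on the covariate design (with
#' intercept); aliased columns are dropped with a message. With no
#' covariates the scores are simply centred.
#'
#' @param scores numeric phenotype vector.
#' @param covariates data.frame or matrix of covariates (factors allowed
#'   in a data.frame), or `NULL`.
#' @return Residuals with mean 0, orthogonal to the fitted covariates.
#' @export
adjust_phenotype <- function(scores, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(scores - mean(scores))
  df <- as.data.frame(covariates)
  fit <- lm(scores ~ ., data = df)
  if (any(is.na(coef(fit))))
    message("dropped aliased covariate columns: ",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  as.numeric(residuals(fit))
}

#' Fit the null mixed model for association testing
#'
#' Constrained single-GRM REML fit of `y = g + e` with the GRM built from
#' model (calibration) SNPs, typically an LD-pruned set. The returned
#' object carries the projection matrix used by [mlm_assoc()].
#'
#' @param y_adj covariate-adjusted phenotype.
#' @param model_snp_grm a [grm()] from the model SNPs.
#' @param X optional fixed effects (intercept always included).
#' @return An object of class `mlm_null` with the `vc_fit`, the projection
#'   matrix `P` and `Py`.
#' @export
fit_null_mlm <- function(y_adj, model_snp_grm, X = NULL) {
  fit <- reml_fit(y_adj, list(g = model_snp_grm), X = X, constrain = TRUE)
  n <- length(y_adj)
  if (is.null(X)) X <- matrix(1, n, 1)
  V <- fit$sigma2[1] * model_snp_grm$values + diag(fit$sigma2[2], n)
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  structure(list(fit = fit, P = P, Py = drop(P %*% y_adj), y = y_adj, n = n),
            class = "mlm_null")
}

#' Mixed-linear-model association scan
#'
#' Per-SNP generalized least squares with the null-model variance
#' structure held fixed: `beta = x'Py / x'Px`, `se = (x'Px)^{-1/2}`,
#' `chi2 = (beta/se)^2`. X-chromosome SNPs are tested on the hemizygous
#' `{0, 2}` coding, so their per-allele effect is half the reported one
#' (see [per_allele_effect_x()]). Missing genotypes are mean-imputed for
#' testing; monomorphic SNPs are skipped.
#'
#' @param null an `mlm_null` from [fit_null_mlm()].
#' @param geno a [genotype_matrix()] over the same individuals (same order).
#' @return A summary-statistics data.frame (`SNP A1 A2 freq b se p N`)
#'   validated by [validate_sumstats()].
#' @export
mlm_assoc <- function(null, geno) {
  stopifnot(inherits(null, "mlm_null"))
  if (nrow(geno$dosages) != null$n)
    stop("genotypes/null sample mismatch", call. = FALSE)
  d <- geno$dosages
  nmiss <- colSums(!is.na(d))
  mu <- colMeans(d, na.rm = TRUE)
  G <- d
  for (j in which(colSums(is.na(d)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  mono <- apply(G, 2, var) == 0
  if (any(mono)) message(sum(mono), " monomorphic SNPs skipped")
  PG <- null$P %*% G
  xPx <- colSums(G * PG)
  xPy <- drop(crossprod(G, null$Py))
  b <- ifelse(mono, NA_real_, xPy / xPx)
  se <- ifelse(mono, NA_real_, 1 / sqrt(xPx))
  chi2 <- (b / se)^2
  p <- pchisq(chi2, 1, lower.tail = FALSE)
  out <- data.frame(SNP = geno$snps$id, A1 = geno$snps$a1, A2 = geno$snps$a2,
                    freq = snp_freq(geno), b = b, se = se,
                    p = pmin(pmax(p, .Machine$double.xmin), 1), N = nmiss,
                    stringsAsFactors = FALSE)
  out <- out[!mono, , drop = FALSE]
  rownames(out) <- NULL
  validate_sumstats(out)
}

#' Per-allele effect size for hemizygous X SNPs
#'
#' Under the `{0, 2}` male dosage coding one allele is counted twice, so
#' the per-allele effect is half the reported regression coefficient.
#'
#' @param beta_reported effect size from the `{0, 2}`-coded scan.
#' @return The per-allele effect.
#' @export
per_allele_effect_x <- function(beta_reported) beta_reported / 2

#' Variance explained by a SNP set via GRM + REML
#'
#' Builds a relationship matrix from the selected SNPs only (autosomal and
#' hemizygous-X columns standardized separately) and estimates the
#' proportion of phenotypic variance it explains with a single-component
#' REML fit on (nominally unrelated) individuals.
#'
#' @param snp_ids character vector of selected SNP ids (may be empty).
#' @param geno a [genotype_matrix()] for the estimation sample.
#' @param y_adj adjusted phenotype, same order.
#' @return A list with `R2`, `se`, and the underlying `fit` (NULL when the
#'   set is empty).
#' @export
variance_explained_by_set <- function(snp_ids, geno, y_adj) {
  if (length(snp_ids) == 0) return(list(R2 = 0, se = NA_real_, fit = NULL))
  idx <- match(snp_ids, geno$snps$id)
  if (anyNA(idx)) stop("unknown SNP ids", call. = FALSE)
  f <- snp_freq(geno)[idx]
  if (any(f <= 0 | f >= 1)) {
    message(sum(f <= 0 | f >= 1), " monomorphic SNPs dropped from the set")
    idx <- idx[f > 0 & f < 1]
    if (length(idx) == 0) return(list(R2 = 0, se = NA_real_, fit = NULL))
  }
  is_x <- geno$snps$chr[idx] == 23L
  parts <- list()
  if (any(!is_x)) parts <- c(parts, list(make_grm(geno, idx[!is_x])))
  if (any(is_x)) {
    gx <- make_grm_x_male(subset_snps(geno, idx[is_x]))
    parts <- c(parts, list(gx))
  }
  g <- if (length(parts) == 1) parts[[1]] else do.call(grm_combine, parts)
  fit <- reml_fit(y_adj, list(set = g), constrain = TRUE)
  list(R2 = fit$h2$h2[1], se = fit$h2$se[1], fit = fit)
}
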