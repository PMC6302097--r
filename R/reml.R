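#' Multi-component average-information REML
#'
#' Fits the variance-component model `V = sum_c sigma2_c A_c + sigma2_e I`
#' by restricted maximum likelihood. The first accepted update is an
#' EM-REML step for stability; subsequent iterations use
#' average-information updates with step-halving whenever a proposal
#' lowers the restricted likelihood (falling back to EM when halving
#' fails). The sampling covariance of the estimates is the inverse of the
#' average-information matrix at convergence.
#'
#' Convergence requires `|delta logL| < 1e-6` and
#' `max |delta sigma2| / Vp < 1e-8` within `max_iter` iterations; a
#' non-converged fit is returned flagged rather than raised.
#'
#' @param y phenotype vector (typically pre-adjusted residuals).
#' @param grms list of [grm()] objects (or plain matrices) over the same
#'   individuals, in phenotype order.
#' @param X fixed-effect design matrix; an intercept is always included.
#' @param constrain floor variance components at `1e-6 * Vp` (FALSE allows
#'   negative estimates, as in unconstrained MAF/LD-stratified fits).
#' @param max_iter iteration cap.
#' @param tol_loglik,tol_sigma convergence tolerances.
#' @param init optional starting values for `sigma2` (length: number of
#'   GRMs + 1); the default splits the phenotypic variance equally.
#' @return An object of class `vc_fit`: `sigma2` (named, residual last),
#'   `covariance` (AI inverse), `loglik`, `h2` (data.frame of proportions
#'   and delta-method SEs), `converged`, `n_iter`, `constrained`.
#' @export
reml_fit <- function(y, grms, X = NULL, constrain = FALSE, max_iter = 100L,
                     tol_loglik = 1e-6, tol_sigma = 1e-8, init = NULL) {
  if (inherits(grms, "grm")) grms <- list(grms)
  if (length(grms) < 1) stop("at least one GRM required", call. = FALSE)
  A <- lapply(grms, function(g) if (inherits(g, "grm")) g$values else as.matrix(g))
  nms <- names(grms)
  if (is.null(nms) || any(nms == ""))
    nms <- paste0("V", seq_along(A))
  n <- length(y)
  for (a in A) if (!all(dim(a) == n)) stop("GRM dimension mismatch with phenotype", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1) else {
    X <- as.matrix(X)
    if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0)))
      X <- cbind(1, X)
  }
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  C <- length(A)
  Vp <- var(y)
  if (!is.null(init) && length(init) != C + 1) init <- NULL  # shape mismatch: ignore
  theta <- if (is.null(init)) rep(Vp / (C + 1), C + 1) else as.numeric(init)
  floor_val <- if (constrain) 1e-6 * Vp else -Inf

  eval_parts <- function(theta) {
    V <- diag(theta[C + 1], n)
    for (c in seq_len(C)) V <- V + theta[c] * A[[c]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vi - ViX %*% chol2inv(chx) %*% t(ViX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, loglik = ll)
  }

  parts <- eval_parts(theta)
  if (is.null(parts)) stop("initial variance matrix is singular", call. = FALSE)
  ll_old <- parts$loglik
  converged <- FALSE
  AI <- NULL
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    P <- parts$P; Py <- parts$Py
    # per-component quantities; residual treated as A = I
    trPA <- numeric(C + 1)
    W <- matrix(0, n, C + 1)
    for (c in seq_len(C)) {
      trPA[c] <- sum(P * A[[c]])
      W[, c] <- A[[c]] %*% Py
    }
    trPA[C + 1] <- sum(diag(P))
    W[, C + 1] <- Py
    yPAPy <- drop(crossprod(Py, W))
    grad <- -0.5 * (trPA - yPAPy)
    PW <- P %*% W
    AI <- 0.5 * crossprod(W, PW)

    if (iter == 1L) {
      delta <- theta^2 * (yPAPy - trPA) / n    # EM-REML step
    } else {
      delta <- tryCatch(solve(AI, grad), error = function(e) NULL)
      if (is.null(delta)) delta <- theta^2 * (yPAPy - trPA) / n
    }

    step <- 1
    repeat {
      prop <- pmax(theta + step * delta, floor_val)
      new_parts <- eval_parts(prop)
      if (!is.null(new_parts) && new_parts$loglik >= ll_old - 1e-10) break
      step <- step / 2
      if (step < 1e-8) {   # EM fallback
        prop <- pmax(theta + theta^2 * (yPAPy - trPA) / n, floor_val)
        new_parts <- eval_parts(prop)
        if (is.null(new_parts)) { new_parts <- parts; prop <- theta }
        break
      }
    }
    d_theta <- max(abs(prop - theta))
    d_ll <- abs(new_parts$loglik - ll_old)
    theta <- prop; parts <- new_parts; ll_old <- new_parts$loglik
    if (d_ll < tol_loglik && d_theta / Vp < tol_sigma) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations", call. = FALSE)

  covar <- tryCatch(solve(AI), error = function(e) matrix(NA, C + 1, C + 1))
  covar <- (covar + t(covar)) / 2
  names(theta) <- c(nms, "residual")
  dimnames(covar) <- list(names(theta), names(theta))
  fit <- structure(list(sigma2 = theta, covariance = covar, loglik = ll_old,
                        converged = converged, n_iter = iter,
                        constrained = constrain, n = n),
                   class = "vc_fit")
  fit$h2 <- h2_from_fit(fit)
  fit
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("vc_fit: logL = %.4f, %s in %d iterations\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(cbind(sigma2 = x$sigma2, se = sqrt(pmax(diag(x$covariance), 0)),
              proportion = x$h2$h2, prop_se = x$h2$se))
  invisible(x)
}

#' Variance proportions (heritabilities) from a fitted model
#'
#' `h2_c = sigma2_c / sum(sigma2)` for every component including the
#' residual; standard errors by the delta method from the REML sampling
#' covariance.
#'
#' @param fit a `vc_fit`.
#' @return A data.frame with `component`, `h2`, `se`.
#' @export
h2_from_fit <- function(fit) {
  th <- fit$sigma2
  s <- sum(th)
  if (s <= 0) stop("total variance is non-positive", call. = FALSE)
  k <- length(th)
  h <- th / s
  se <- rep(NA_real_, k)
  if (all(is.finite(fit$covariance))) {
    for (i in seq_len(k)) {
      g <- -th[i] / s^2
      g <- rep(g, k)
      g[i] <- (s - th[i]) / s^2
      se[i] <- sqrt(max(drop(t(g) %*% fit$covariance %*% g), 0))
    }
  }
  data.frame(component = names(th), h2 = as.numeric(h), se = se,
             row.names = NULL, stringsAsFactors = FALSE)
}

# covariance matrix of the h2 proportions (delta method), used by the
# enrichment test
h2_proportion_cov <- function(fit) {
  th <- fit$sigma2; s <- sum(th); k <- length(th)
  J <- matrix(-th / s^2, k, k)        # d h_i / d theta_j = -th_i/s^2 + delta/s
  diag(J) <- diag(J) + 1 / s
  J %*% fit$covariance %*% t(J)
}

#' Joint close-relative / SNP variance partition ("big K small K")
#'
#' Fits the full GRM together with its close-relative thresholded copy
#' (and optionally an X-chromosome GRM), separating SNP-tagged variance
#' from variance shared only among close relatives. The total
#' pedigree-scale heritability is the sum of the genetic proportions.
#'
#' @param y phenotype vector.
#' @param grm_full the genome-wide [grm()].
#' @param cutoff relatedness threshold for the big K matrix.
#' @param grm_x optional X-chromosome [grm()].
#' @param X optional fixed-effect design.
#' @param constrain passed to [reml_fit()].
#' @param ... further arguments passed to [reml_fit()].
#' @return A `vc_fit` with an added `h2_ped_total` element (sum of genetic
#'   proportions with delta-method SE).
#' @export
big_k_small_k_fit <- function(y, grm_full, cutoff = 0.05, grm_x = NULL,
                              X = NULL, constrain = FALSE, ...) {
  bigk <- threshold_bigk(grm_full, cutoff)
  off <- bigk$values; diag(off) <- 0
  if (all(off == 0))
    warning("no pair exceeds the big K cutoff; components may not be identifiable")
  grms <- list(snp = grm_full, bigK = bigk)
  if (!is.null(grm_x)) grms$x <- grm_x
  fit <- reml_fit(y, grms, X = X, constrain = constrain, ...)
  ng <- length(grms)
  hcov <- h2_proportion_cov(fit)
  tot <- sum(fit$h2$h2[seq_len(ng)])
  se <- sqrt(max(sum(hcov[seq_len(ng), seq_len(ng)]), 0))
  fit$h2_ped_total <- c(h2 = tot, se = se)
  fit
}

#' MAF/LD-stratified REML (GREML-LDMS)
#'
#' Builds one GRM per non-empty MAF-bin x LD-quartile component and fits
#' them jointly, unconstrained by default so component estimates may be
#' negative.
#'
#' @param y phenotype vector.
#' @param geno a [genotype_matrix()] (autosomal SNPs).
#' @param annotations per-SNP annotation from [assign_ldms_bins()].
#' @param X optional fixed-effect design.
#' @param constrain passed to [reml_fit()].
#' @param min_snps components with fewer SNPs are dropped with a message.
#' @param ... further arguments passed to [reml_fit()].
#' @return A `vc_fit` with added `m_snps` (per-component SNP counts, same
#'   order as the genetic components) and `components` (component labels).
#' @export
ldms_fit <- function(y, geno, annotations, X = NULL, constrain = FALSE,
                     min_snps = 2L, ...) {
  stopifnot(nrow(annotations) == ncol(geno$dosages))
  p <- snp_freq(geno)
  poly <- p > 0 & p < 1
  comp <- annotations$component
  comp[!poly] <- NA   # monomorphic within this sample: unusable
  labs <- sort(unique(comp))
  grms <- list(); m_c <- integer(0); kept <- integer(0)
  labs <- labs[!is.na(labs)]
  for (k in labs) {
    idx <- which(!is.na(comp) & comp == k)
    if (length(idx) < min_snps) {
      message(sprintf("LDMS component %d dropped (%d SNPs)", k, length(idx)))
      next
    }
    grms[[paste0("comp", k)]] <- make_grm(geno, idx)
    m_c <- c(m_c, length(idx)); kept <- c(kept, k)
  }
  if (length(grms) == 0) stop("no non-empty LDMS components", call. = FALSE)
  fit <- reml_fit(y, grms, X = X, constrain = constrain, ...)
  fit$m_snps <- m_c
  fit$components <- kept
  fit
}

#' Write an hsq-style variance-component report
#'
#' @param fit a `vc_fit`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_hsq <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("component\tvariance\tse\tproportion\tproportion_se", con)
  se <- sqrt(pmax(diag(fit$covariance), 0))
  for (i in seq_along(fit$sigma2)) {
    writeLines(sprintf("%s\t%.6g\t%.6g\t%.6g\t%.6g", names(fit$sigma2)[i],
                       fit$sigma2[i], se[i], fit$h2$h2[i], fit$h2$se[i]), con)
  }
  writeLines(sprintf("logL\t%.6f", fit$loglik), con)
  writeLines(sprintf("n\t%d", fit$n), con)
  writeLines("covariance", con)
  utils::write.table(format(fit$covariance, digits = 8), con, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
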