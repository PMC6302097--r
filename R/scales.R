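#' Ordinal scale specification under the liability-threshold model
#'
#' For an ordinal trait observed in `n` categories with frequencies
#' `pi_j` and scores `w_j`, computes the liability thresholds
#' (standard-normal quantiles of the cumulative frequencies), the normal
#' densities `z_j` at those thresholds, and the observed-scale variance
#' `V(Y_o) = sum pi_j w_j^2 - (sum pi_j w_j)^2`.
#'
#' @param freqs positive category frequencies summing to 1.
#' @param weights category scores (default `1..n`).
#' @return An object of class `ordinal_scale_spec` with elements `freqs`,
#'   `weights`, `thresholds`, `densities`, `v_obs`.
#' @export
ordinal_scale_spec <- function(freqs, weights = seq_along(freqs)) {
  if (any(freqs <= 0)) stop("all category frequencies must be positive", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-8) stop("category frequencies must sum to 1", call. = FALSE)
  if (length(weights) != length(freqs)) stop("weights/freqs length mismatch", call. = FALSE)
  thr <- qnorm(cumsum(freqs))[-length(freqs)]
  z <- dnorm(thr)
  v_obs <- sum(freqs * weights^2) - sum(freqs * weights)^2
  structure(list(freqs = freqs, weights = weights, thresholds = thr,
                 densities = z, v_obs = v_obs),
            class = "ordinal_scale_spec")
}

#' @export
print.ordinal_scale_spec <- function(x, ...) {
  cat(sprintf("ordinal scale: %d categories, thresholds (%s), V(Y_o) = %.4f\n",
              length(x$freqs), paste(sprintf("%.3f", x$thresholds), collapse = ", "),
              x$v_obs))
  invisible(x)
}

#' Observed-to-liability conversion factor for an ordinal trait
#'
#' The factor `V(Y_o) / (sum_j z_j)^2` by which an observed-scale
#' heritability of the category scores is multiplied to obtain the
#' liability-scale heritability. For 4 categories at frequencies
#' (0.32, 0.23, 0.27, 0.18) with scores 1-4 it is approximately 1.18.
#'
#' @param spec an [ordinal_scale_spec()].
#' @return The conversion factor.
#' @export
liability_factor <- function(spec) {
  stopifnot(inherits(spec, "ordinal_scale_spec"))
  zsum <- sum(spec$densities)
  if (zsum <= 0 || spec$v_obs <= 0) stop("degenerate ordinal scale", call. = FALSE)
  spec$v_obs / zsum^2
}

#' Transform an observed-scale heritability to the liability scale
#'
#' @param h2_observed heritability on the ordinal (observed) scale, in
#'   `[0, 1]`.
#' @param spec an [ordinal_scale_spec()].
#' @return The liability-scale heritability (not clipped; a value above 1
#'   triggers a warning).
#' @export
to_liability <- function(h2_observed, spec) {
  if (h2_observed < 0 || h2_observed > 1)
    stop("h2_observed must lie in [0, 1]", call. = FALSE)
  h2 <- h2_observed * liability_factor(spec)
  if (h2 > 1)
    warning(sprintf("liability-scale estimate %.3f exceeds 1", h2))
  h2
}

#' Per-SNP heritability enrichment of a component set
#'
#' Given per-component heritability estimates (e.g. from an unconstrained
#' MAF/LD-stratified fit), tests whether the per-SNP heritability in a set
#' C of components exceeds that of the remaining SNPs. The fold-enrichment
#' is `h2_C * M / (M_C * h2)`; the test statistic is the per-SNP
#' difference `d = h2_C/M_C - (h2 - h2_C)/(M - M_C)` divided by its
#' delta-method standard error from the joint sampling covariance, against
#' the two-sided standard normal.
#'
#' @param h2_components per-component heritability estimates (genetic
#'   components only), or a `vc_fit` (then `m_snps` defaults to its
#'   per-component SNP counts).
#' @param m_snps per-component SNP counts.
#' @param covariance sampling covariance of `h2_components`.
#' @param set indices (into the components) forming the set C.
#' @return A list of class `enrichment_result`: `h2_c`, `h2_total`, `m_c`,
#'   `m_total`, `fold`, `d`, `se_d`, `z`, `p`.
#' @export
enrichment_test <- function(h2_components, set, m_snps = NULL, covariance = NULL) {
  if (inherits(h2_components, "vc_fit")) {
    fit <- h2_components
    ng <- length(fit$sigma2) - 1L
    if (is.null(m_snps)) m_snps <- fit$m_snps
    if (is.null(m_snps)) stop("m_snps required", call. = FALSE)
    h2_components <- fit$h2$h2[seq_len(ng)]
    covariance <- h2_proportion_cov(fit)[seq_len(ng), seq_len(ng), drop = FALSE]
  }
  k <- length(h2_components)
  stopifnot(length(m_snps) == k, !is.null(covariance))
  covariance <- as.matrix(covariance)
  set <- sort(unique(set))
  if (length(set) == 0 || length(set) >= k)
    stop("set C must be a non-empty proper subset of the components", call. = FALSE)
  m_c <- sum(m_snps[set]); m_total <- sum(m_snps)
  if (m_c == 0 || m_c == m_total) stop("degenerate SNP counts", call. = FALSE)
  h2_c <- sum(h2_components[set]); h2 <- sum(h2_components)
  fold <- h2_c * m_total / (m_c * h2)
  d <- h2_c / m_c - (h2 - h2_c) / (m_total - m_c)
  a <- rep(-1 / (m_total - m_c), k)
  a[set] <- 1 / m_c + 1 / (m_total - m_c)
  se_d <- sqrt(drop(t(a) %*% covariance %*% a))
  z <- d / se_d
  structure(list(h2_c = h2_c, h2_total = h2, m_c = m_c, m_total = m_total,
                 fold = fold, d = d, se_d = se_d, z = z,
                 p = 2 * pnorm(-abs(z))),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: h2_C = %.3f of %.3f over %d/%d SNPs; fold = %.2f, Z = %.2f, p = %.3g\n",
              x$h2_c, x$h2_total, x$m_c, x$m_total, x$fold, x$z, x$p))
  invisible(x)
}

#' Two-sided test for the difference of two independent estimates
#'
#' @param est1,se1,est2,se2 estimates and standard errors.
#' @return A list with `diff`, `se`, `z`, `p` (two-sided normal).
#' @export
estimate_difference_test <- function(est1, se1, est2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive", call. = FALSE)
  d <- est1 - est2
  se <- sqrt(se1^2 + se2^2)
  z <- d / se
  list(diff = d, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

#' Repeatability of a trait from paired measurements
#'
#' Pearson correlation between the two measurement occasions with a
#' Fisher-z confidence interval; an upper bound for broad-sense
#' heritability.
#'
#' @param y1,y2 paired measurements.
#' @param conf confidence level.
#' @return A list with `r`, `ci` (length 2), `n`.
#' @export
repeatability <- function(y1, y2, conf = 0.95) {
  ok <- !is.na(y1) & !is.na(y2)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(y1[ok]) == 0 || var(y2[ok]) == 0)
    stop("zero variance in a measurement", call. = FALSE)
  r <- cor(y1[ok], y2[ok])
  zc <- qnorm(1 - (1 - conf) / 2)
  fz <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  ci <- tanh(fz + c(-1, 1) * zc / sqrt(n - 3))
  list(r = r, ci = ci, n = n)
}

# P(X <= h, Y <= k) for standard bivariate normal with correlation rho
pbvn <- function(h, k, rho) {
  if (rho > 1 - 1e-12) return(pnorm(min(h, k)))
  if (h == -Inf || k == -Inf) return(0)
  f <- function(x) dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2))
  lo <- max(h - 12, -12)
  if (h <= -12) return(0)
  integrate(f, lo, min(h, 12), rel.tol = 1e-10)$value
}

# Pearson correlation of two thresholded ordinal scores whose latent
# liabilities are standard bivariate normal with correlation rho
ordinal_latent_cor <- function(rho, freqs, weights = seq_along(freqs)) {
  spec <- ordinal_scale_spec(freqs, weights)
  thr <- c(-Inf, spec$thresholds, Inf)
  k <- length(freqs)
  mu <- sum(freqs * weights)
  e12 <- 0
  cdf <- matrix(0, k + 1, k + 1)
  for (i in seq_len(k + 1)) for (j in seq_len(k + 1))
    cdf[i, j] <- pbvn(thr[i], thr[j], rho)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pij <- cdf[i + 1, j + 1] - cdf[i, j + 1] - cdf[i + 1, j] + cdf[i, j]
    e12 <- e12 + weights[i] * weights[j] * pij
  }
  (e12 - mu^2) / spec$v_obs
}

#' Ascertainment bias of a case-control liability heritability estimate
#'
#' Simulates an ordinal liability-threshold trait with known liability
#' heritability, forms a case-control design from selected score
#' categories (optionally excluding middle categories), and applies the
#' standard observed-to-liability case-control transformation using the
#' sample-derived "prevalence" (the case proportion among retained
#' individuals, as a naive analysis would). Returns the inflation factor
#' (estimate over truth): excluding a middle category biases the estimate
#' upward.
#'
#' @param freqs category frequencies.
#' @param h2_liability_true simulated liability-scale heritability.
#' @param case_set,control_set,excluded score categories (1-based) defining
#'   cases, controls and exclusions; must not overlap.
#' @param n_sim number of simulated individuals.
#' @param seed RNG seed.
#' @return A list with `factor` (estimate/truth), `h2_liability_est`,
#'   `h2_observed_cc`, `k_star` (sample-derived prevalence), `n_retained`.
#' @export
cc_ascertainment_bias <- function(freqs, h2_liability_true,
                                  case_set = c(3, 4), control_set = 1,
                                  excluded = 2, n_sim = 2e5, seed = 1L) {
  if (length(case_set) == 0 || length(control_set) == 0)
    stop("case and control sets must be non-empty", call. = FALSE)
  if (length(intersect(case_set, control_set)) ||
      length(intersect(case_set, excluded)) ||
      length(intersect(control_set, excluded)))
    stop("case/control/excluded sets must be disjoint", call. = FALSE)
  set.seed(seed)
  h2 <- h2_liability_true
  g <- rnorm(n_sim, 0, sqrt(h2))
  liab <- g + rnorm(n_sim, 0, sqrt(1 - h2))
  score <- liability_to_score(liab, freqs)
  retained <- score %in% c(case_set, control_set)
  y <- as.integer(score[retained] %in% case_set)
  gk <- g[retained]
  h2_obs <- cor(y, gk)^2       # observed-scale variance explained by the
  k_star <- mean(y)            # true genetic value in the retained sample
  zK <- dnorm(qnorm(1 - k_star))
  # observed(0/1) -> liability with prevalence K* and case fraction P = K*
  est <- h2_obs * k_star * (1 - k_star) / zK^2
  list(factor = est / h2, h2_liability_est = est, h2_observed_cc = h2_obs,
       k_star = k_star, n_retained = sum(retained))
}
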