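#' Genomic relationship matrix container
#'
#' @param values symmetric n x n relatedness matrix.
#' @param ids sample ids (length n).
#' @param m_snps number of SNPs used.
#' @param pair_counts optional n x n matrix of per-pair non-missing SNP
#'   counts (defaults to `m_snps` everywhere).
#' @param kind one of `"autosomal"`, `"x_male"`, `"pedigree"`, `"bigK"`,
#'   `"selected_snps"`.
#' @return An object of class `grm`.
#' @export
grm <- function(values, ids, m_snps, pair_counts = NULL,
                kind = c("autosomal", "x_male", "pedigree", "bigK", "selected_snps")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is_symmetric_tol(values)) stop("GRM must be symmetric", call. = FALSE)
  if (length(ids) != nrow(values)) stop("ids/values dimension mismatch", call. = FALSE)
  structure(list(values = values, ids = as.character(ids),
                 m_snps = as.integer(m_snps),
                 pair_counts = pair_counts, kind = kind),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s): %d individuals, %d SNPs, mean diagonal %.3f\n",
              x$kind, nrow(x$values), x$m_snps, mean(diag(x$values))))
  invisible(x)
}

#' Build a genomic relationship matrix from autosomal dosages
#'
#' Dosages are centred at `2p` and scaled by `sqrt(2p(1-p))` with allele
#' frequencies `p` estimated from the sample itself; the relationship of a
#' pair is the average of products over SNPs non-missing in both members.
#'
#' @param geno a [genotype_matrix()].
#' @param snp_subset optional SNP ids or indices.
#' @return A [grm()] of kind `"autosomal"` (or `"selected_snps"` when a
#'   subset is given).
#' @export
make_grm <- function(geno, snp_subset = NULL) {
  g <- if (is.null(snp_subset)) geno else subset_snps(geno, snp_subset)
  if (ncol(g$dosages) == 0) stop("empty SNP subset", call. = FALSE)
  p <- snp_freq(g)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP in GRM subset", call. = FALSE)
  d <- g$dosages
  z <- sweep(d, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  grm_from_z(z, g$samples$id,
             kind = if (is.null(snp_subset)) "autosomal" else "selected_snps")
}

#' X-chromosome GRM for an all-male sample
#'
#' Hemizygous `{0, 2}` dosages are standardized per SNP by their empirical
#' mean and SD, then averaged as in [make_grm()].
#'
#' @param geno a [genotype_matrix()]; all samples must be male. Non-X SNPs
#'   are ignored.
#' @return A [grm()] of kind `"x_male"`.
#' @export
make_grm_x_male <- function(geno) {
  if (any(geno$samples$sex != "male"))
    stop("X-GRM requires an all-male sample", call. = FALSE)
  ix <- which(geno$snps$chr == 23L)
  if (length(ix) == 0) stop("no X-chromosome SNPs", call. = FALSE)
  g <- subset_snps(geno, ix)
  d <- g$dosages
  mu <- colMeans(d, na.rm = TRUE)
  # population (not sample) SD, matching the 2p(1-p) convention of make_grm
  sdv <- sqrt(colMeans(d^2, na.rm = TRUE) - mu^2)
  if (any(sdv == 0 | is.na(sdv))) stop("monomorphic X SNP", call. = FALSE)
  z <- sweep(sweep(d, 2, mu), 2, sdv, "/")
  grm_from_z(z, g$samples$id, kind = "x_male")
}

# average of standardized products over pairwise-complete SNPs
grm_from_z <- function(z, ids, kind) {
  miss <- is.na(z)
  z[miss] <- 0
  a <- tcrossprod(z)
  if (any(miss)) {
    counts <- tcrossprod(!miss)
    a <- a / counts
  } else {
    counts <- NULL
    a <- a / ncol(z)
  }
  grm(a, ids, ncol(z), pair_counts = counts, kind = kind)
}

#' Threshold a GRM to retain close relatives only ("big K")
#'
#' Off-diagonal entries strictly below the cutoff are set to 0; an entry
#' exactly at the cutoff is retained, and the diagonal is untouched.
#'
#' @param x a [grm()].
#' @param cutoff relatedness threshold.
#' @return A [grm()] of kind `"bigK"`.
#' @export
threshold_bigk <- function(x, cutoff = 0.05) {
  v <- x$values
  off <- v
  diag(off) <- NA
  off[!is.na(off) & off < cutoff] <- 0
  diag(off) <- diag(v)
  grm(off, x$ids, x$m_snps, pair_counts = x$pair_counts, kind = "bigK")
}

#' Select a maximal set of mutually unrelated individuals
#'
#' Greedy vertex removal on the relatedness graph (edges where the GRM
#' entry is at least the cutoff): the individual with the most remaining
#' relatives is removed at each step, ties broken by input order.
#'
#' @param x a [grm()].
#' @param cutoff relatedness threshold defining "related".
#' @return Character vector of retained sample ids (input order).
#' @export
select_unrelated <- function(x, cutoff = 0.05) {
  v <- x$values
  diag(v) <- 0
  adj <- v >= cutoff
  keep <- rep(TRUE, nrow(adj))
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (max(deg) == 0) break
    worst <- which.max(deg)   # first index on ties
    keep[worst] <- FALSE
    adj[worst, ] <- FALSE; adj[, worst] <- FALSE
  }
  x$ids[keep]
}

#' Pedigree relationship matrix from first-degree pairs
#'
#' @param ids all sample ids (matrix order).
#' @param pairs data.frame or matrix with two id columns (e.g. the
#'   `pedigree` element of a simulated cohort).
#' @param coefficient relatedness assigned to listed pairs (0.5 for
#'   first-degree relatives); all other off-diagonals are 0 and the
#'   diagonal is 1.
#' @return A [grm()] of kind `"pedigree"`.
#' @export
pedigree_grm <- function(ids, pairs, coefficient = 0.5) {
  n <- length(ids)
  v <- diag(n)
  if (NROW(pairs) > 0) {
    ia <- match(as.character(pairs[[1]]), ids)
    ib <- match(as.character(pairs[[2]]), ids)
    if (anyNA(ia) || anyNA(ib)) stop("pair ids missing from id list", call. = FALSE)
    if (any(ia == ib)) stop("pair ids must be distinct", call. = FALSE)
    v[cbind(ia, ib)] <- coefficient
    v[cbind(ib, ia)] <- coefficient
  }
  grm(v, ids, 0L, kind = "pedigree")
}

#' Read / write a GRM in GCTA binary format
#'
#' The triplet `prefix.grm.bin` (lower triangle including the diagonal,
#' row-wise, single precision), `prefix.grm.N.bin` (per-pair SNP counts,
#' same layout) and `prefix.grm.id` (family/individual id table).
#'
#' @param x a [grm()].
#' @param prefix file path prefix.
#' @return `write_grm_bin()` the paths invisibly; `read_grm_bin()` a [grm()].
#' @export
write_grm_bin <- function(x, prefix) {
  n <- nrow(x$values)
  # row-wise lower triangle: for j in 1..n, k in 1..j
  idx <- unlist(lapply(seq_len(n), function(j) (seq_len(j) - 1L) * n + j))
  tri <- x$values[idx]
  counts <- if (is.null(x$pair_counts)) rep(x$m_snps, length(tri)) else x$pair_counts[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(tri), con, size = 4); close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(counts), con, size = 4); close(con)
  utils::write.table(data.frame(x$ids, x$ids), paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id")))
}

#' @rdname write_grm_bin
#' @param kind GRM kind recorded on read.
#' @export
read_grm_bin <- function(prefix, kind = "autosomal") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")[[2]]
  n <- length(ids)
  n_tri <- n * (n + 1) / 2
  tri <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = n_tri + 1, size = 4)
  if (length(tri) != n_tri)
    stop("grm.bin size inconsistent with id file", call. = FALSE)
  counts <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = n_tri + 1, size = 4)
  if (length(counts) != n_tri)
    stop("grm.N.bin size inconsistent with id file", call. = FALSE)
  v <- matrix(0, n, n); cnt <- matrix(0, n, n)
  k <- 1L
  for (j in seq_len(n)) {
    v[j, seq_len(j)] <- tri[k:(k + j - 1L)]
    cnt[j, seq_len(j)] <- counts[k:(k + j - 1L)]
    k <- k + j
  }
  v <- v + t(v) - diag(diag(v))
  cnt <- cnt + t(cnt) - diag(diag(cnt))
  grm(v, ids, as.integer(round(max(cnt))), pair_counts = cnt, kind = kind)
}

#' Combine GRMs built from disjoint SNP sets
#'
#' The GRM of the union of SNP sets is the SNP-count-weighted average of the
#' per-set GRMs (complete-data case).
#'
#' @param ... [grm()] objects over the same samples.
#' @param kind kind label for the result.
#' @return A [grm()].
#' @export
grm_combine <- function(..., kind = "selected_snps") {
  gs <- list(...)
  stopifnot(length(gs) >= 1)
  ids <- gs[[1]]$ids
  for (g in gs) stopifnot(identical(g$ids, ids))
  w <- vapply(gs, function(g) g$m_snps, numeric(1))
  v <- Reduce(`+`, Map(function(g, wi) g$values * wi, gs, w)) / sum(w)
  grm(v, ids, sum(w), kind = kind)
}
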