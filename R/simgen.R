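#' Simulation configuration for a synthetic male cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' describe a polygenic, sex-limited ordinal trait scored 1-4: category
#' frequencies (0.32, 0.23, 0.27, 0.18), an age effect of 0.02 score units per
#' year over ages 40-73, a repeated measurement with repeatability 0.88, and a
#' genetic architecture with autosomal heritability 0.36, X-linked
#' heritability 0.03, and a further 0.21 of liability variance shared by
#' first-degree relatives but untagged by the simulated SNPs. Offspring counts
#' are Poisson with mean 1.81, weakly negatively coupled to liability.
#'
#' @param n_individuals number of (male) cohort members.
#' @param n_snps_auto,n_snps_x numbers of autosomal and X-chromosome SNPs.
#' @param maf_range allele-frequency range (lo, hi] for simulated SNPs.
#' @param ld_decay probability in `[0, 1)` that a haplotype allele is copied
#'   from the adjacent SNP (first-order haplotype copying).
#' @param block_break_prob probability that the copying chain is broken between
#'   adjacent SNPs, creating LD blocks of geometric length and hence a spread
#'   of LD scores.
#' @param bin_enrichment 3 x 4 matrix of genetic-variance shares per
#'   (MAF bin, LD-score quartile) component; rows are MAF bins (rare,
#'   low-frequency, common), columns LD quartiles 1 (lowest) to 4. Must sum
#'   to 1. The default places all variance in the common bin with quartile
#'   shares (0.35, 0.34, 0.19, 0.13).
#' @param h2_auto,h2_x liability variance explained by autosomal and X SNPs.
#' @param h2_fam additional liability variance shared by first-degree
#'   relatives (correlation 0.5 within pairs) but untagged by simulated SNPs.
#' @param category_freqs the four ordinal category frequencies `pi_j`.
#' @param age_slope expected ordinal-score increase per year of age.
#' @param age_range age range (years), sampled uniformly.
#' @param repeat_error_sd SD (in latent liability SD units) of the measurement
#'   noise added before re-thresholding the repeat score; `NULL` calibrates it
#'   so the expected ordinal repeatability equals `repeat_target`.
#' @param repeat_target target repeatability used when `repeat_error_sd` is
#'   `NULL`.
#' @param fertility_mean mean number of children fathered.
#' @param fertility_slope change in expected children per liability SD;
#'   `NULL` calibrates it so the regression of children on the ordinal score
#'   has slope `fertility_score_slope`.
#' @param fertility_score_slope target children-on-score regression slope used
#'   when `fertility_slope` is `NULL`.
#' @param n_brother_pairs,n_father_son_pairs numbers of first-degree pairs
#'   embedded in the cohort (each pair uses two cohort slots).
#' @param seed root seed; every stage draws from a sub-stream derived from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 2000,
                       n_snps_auto = 5000,
                       n_snps_x = 500,
                       maf_range = c(0.01, 0.5),
                       ld_decay = 0.9,
                       block_break_prob = 0.05,
                       bin_enrichment = NULL,
                       h2_auto = 0.36,
                       h2_x = 0.03,
                       h2_fam = 0.21,
                       category_freqs = c(0.32, 0.23, 0.27, 0.18),
                       age_slope = 0.02,
                       age_range = c(40, 73),
                       repeat_error_sd = NULL,
                       repeat_target = 0.88,
                       fertility_mean = 1.81,
                       fertility_slope = NULL,
                       fertility_score_slope = -0.030,
                       n_brother_pairs = 200,
                       n_father_son_pairs = 200,
                       seed = 1L) {
  if (n_individuals <= 0 || n_snps_auto <= 0 || n_snps_x < 0)
    stop("dimensions must be positive", call. = FALSE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  stop_if_not_scalar_prob(ld_decay, "ld_decay", 0, 1 - 1e-12)
  stop_if_not_scalar_prob(block_break_prob, "block_break_prob")
  if (length(category_freqs) != 4 || any(category_freqs <= 0) ||
      abs(sum(category_freqs) - 1) > 1e-8)
    stop("category_freqs must be 4 positive proportions summing to 1", call. = FALSE)
  if (h2_auto < 0 || h2_x < 0 || h2_fam < 0 || h2_auto + h2_x + h2_fam > 1)
    stop("heritability shares must be non-negative and sum to at most 1", call. = FALSE)
  if (is.null(bin_enrichment)) {
    q_shares <- c(0.35, 0.34, 0.19, 0.13)   # normalized: printed shares sum to 1.01
    bin_enrichment <- rbind(rep(0, 4), rep(0, 4), q_shares / sum(q_shares))
  }
  bin_enrichment <- as.matrix(bin_enrichment)
  if (!all(dim(bin_enrichment) == c(3, 4)) || any(bin_enrichment < 0) ||
      abs(sum(bin_enrichment) - 1) > 1e-8)
    stop("bin_enrichment must be a non-negative 3 x 4 matrix summing to 1", call. = FALSE)
  if (2 * (n_brother_pairs + n_father_son_pairs) > n_individuals)
    stop("pedigree pairs exceed cohort size", call. = FALSE)

  spec <- ordinal_scale_spec(category_freqs)
  if (is.null(repeat_error_sd))
    repeat_error_sd <- repeat_sd_for_target(repeat_target, category_freqs)
  if (is.null(fertility_slope))
    fertility_slope <- fertility_score_slope * spec$v_obs / sum(spec$densities)

  structure(list(
    n_individuals = as.integer(n_individuals),
    n_snps_auto = as.integer(n_snps_auto),
    n_snps_x = as.integer(n_snps_x),
    maf_range = maf_range, ld_decay = ld_decay,
    block_break_prob = block_break_prob,
    bin_enrichment = bin_enrichment,
    h2_auto = h2_auto, h2_x = h2_x, h2_fam = h2_fam,
    category_freqs = category_freqs,
    age_slope = age_slope, age_range = age_range,
    repeat_error_sd = repeat_error_sd,
    fertility_mean = fertility_mean, fertility_slope = fertility_slope,
    n_brother_pairs = as.integer(n_brother_pairs),
    n_father_son_pairs = as.integer(n_father_son_pairs),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Simulate n_hap haplotypes for m SNPs with first-order copying LD.
# copy_prob is a per-adjacent-pair vector (0 breaks the chain).
sim_haplotypes <- function(n_hap, freqs, copy_prob) {
  m <- length(freqs)
  # all fresh draws and copy decisions generated up front (vectorized)
  h <- matrix(rbinom(n_hap * m, 1L, rep(freqs, each = n_hap)), n_hap, m)
  if (m > 1) {
    take <- matrix(runif(n_hap * (m - 1)) <
                     rep(copy_prob, each = n_hap), n_hap, m - 1)
    for (i in seq_len(m)[-1]) {
      ti <- take[, i - 1]
      if (any(ti)) h[ti, i] <- h[ti, i - 1]
    }
  }
  h
}

# SNP map for the simulated genome: autosomes packed 2000 SNPs per
# chromosome at 50 kb spacing, X (chr 23) the same.
sim_snp_map <- function(n_auto, n_x, spacing = 5e4, per_chr = 2000) {
  chr_a <- if (n_auto > 0) ((seq_len(n_auto) - 1L) %/% per_chr) + 1L else integer(0)
  bp_a <- if (n_auto > 0) (((seq_len(n_auto) - 1L) %% per_chr) + 1L) * spacing else integer(0)
  chr_x <- rep(23L, n_x)
  bp_x <- if (n_x > 0) seq_len(n_x) * spacing else integer(0)
  data.frame(
    id = c(sprintf("rsA%05d", seq_len(n_auto)), sprintf("rsX%05d", seq_len(n_x))),
    chr = c(chr_a, chr_x),
    bp = as.integer(c(bp_a, bp_x)),
    a1 = "A", a2 = "G",
    stringsAsFactors = FALSE
  )
}

#' Simulate genotypes for a male cohort
#'
#' Autosomal genotypes are diploid dosages in `{0, 1, 2}`; X-chromosome
#' genotypes are hemizygous and stored as `{0, 2}` (one allele counted
#' twice). Local LD follows first-order haplotype copying with probability
#' `ld_decay`, with chain breaks at random block boundaries.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] of unrelated males.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "genotypes"))
  n <- config$n_individuals
  sim_founder_genotypes(n, config)
}

# founder genotype generation shared by simulate_genotypes and pedigree code;
# uses the current RNG state.
sim_founder_params <- function(config) {
  ma <- config$n_snps_auto; mx <- config$n_snps_x
  map <- sim_snp_map(ma, mx)
  freqs <- runif(ma + mx, config$maf_range[1], config$maf_range[2])
  cp <- rep(config$ld_decay, max(ma + mx - 1, 0))
  # chain breaks: block boundaries and chromosome changes
  brk <- runif(length(cp)) < config$block_break_prob
  chr_change <- map$chr[-1] != map$chr[-nrow(map)]
  cp[brk | chr_change] <- 0
  list(map = map, freqs = freqs, copy_prob = cp)
}

sim_founder_genotypes <- function(n, config, params = NULL) {
  if (is.null(params)) params <- sim_founder_params(config)
  ma <- config$n_snps_auto; mx <- config$n_snps_x
  ia <- seq_len(ma); ix <- ma + seq_len(mx)
  h1 <- sim_haplotypes(n, params$freqs, params$copy_prob)
  h2 <- sim_haplotypes(n, params$freqs, params$copy_prob)
  dos <- matrix(0L, n, ma + mx)
  dos[, ia] <- h1[, ia, drop = FALSE] + h2[, ia, drop = FALSE]
  if (mx > 0) dos[, ix] <- 2L * h1[, ix, drop = FALSE]  # males: one X haplotype
  genotype_matrix(
    dosages = dos, snps = params$map,
    samples = data.frame(id = sprintf("ind%05d", seq_len(n)), sex = "male",
                         stringsAsFactors = FALSE)
  )
}

#' Drop one gamete pair to form a child genotype
#'
#' Autosomal dosage is the sum of one sampled paternal and one sampled
#' maternal allele (independent Mendelian sampling per site). A son receives
#' his single X from his mother only, so father-son pairs share no X-linked
#' alleles by descent; a daughter receives the paternal X allele plus one
#' sampled maternal allele.
#'
#' @param father,mother dosage rows (autosomes in `{0,1,2}`; father's X in
#'   `{0,2}`).
#' @param child_sex `"male"` or `"female"`.
#' @param snps SNP map with a `chr` column (X is chromosome 23).
#' @return An integer dosage row for the child (X as `{0,2}` for sons).
#' @export
gamete_drop <- function(father, mother, child_sex = c("male", "female"), snps) {
  child_sex <- match.arg(child_sex)
  if (length(father) != length(mother) || length(father) != nrow(snps))
    stop("parental rows must share one SNP map", call. = FALSE)
  is_x <- snps$chr == 23L
  pat <- rbinom(length(father), 1L, father / 2)
  mat <- rbinom(length(mother), 1L, mother / 2)
  child <- pat + mat
  if (any(is_x)) {
    if (child_sex == "male") {
      child[is_x] <- 2L * mat[is_x]           # maternal X only, {0,2} coding
    } else {
      child[is_x] <- father[is_x] / 2L + mat[is_x]
    }
  }
  as.integer(child)
}

#' Simulate per-SNP effects and the latent liability
#'
#' Effects act on standardized dosages. Genetic variance is apportioned
#' across (MAF bin, LD quartile) components in the proportions
#' `config$bin_enrichment` for autosomal SNPs (total `h2_auto`), and spread
#' evenly over X SNPs (total `h2_x`). A family component with variance
#' `h2_fam`, correlated 0.5 within first-degree pairs, and an independent
#' residual complete the liability, which has expected variance 1.
#'
#' @param geno a [genotype_matrix()].
#' @param config a [sim_config()].
#' @param annotations optional per-SNP annotation from [assign_ldms_bins()]
#'   for the autosomal SNPs; computed from `geno` when missing.
#' @param pairs optional two-column matrix of row indices for first-degree
#'   pairs sharing the family component.
#' @return A list with `effects` (per-SNP standardized-scale effect),
#'   `liability`, `genetic_value`, its autosomal/X parts, and the annotation
#'   used.
#' @export
simulate_effects_and_liability <- function(geno, config, annotations = NULL,
                                           pairs = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "effects"))
  n <- nrow(geno$dosages)
  is_x <- geno$snps$chr == 23L
  ia <- which(!is_x); ix <- which(is_x)

  if (is.null(annotations) && length(ia) > 0) {
    ga <- subset_snps(geno, ia)
    ann <- assign_ldms_bins(snp_maf(ga), ld_scores(ga))
  } else ann <- annotations

  m_all <- ncol(geno$dosages)
  u <- numeric(m_all)
  if (length(ia) > 0 && config$h2_auto > 0) {
    comp <- (ann$maf_bin - 1L) * 4L + ann$ld_quartile
    share <- as.vector(t(config$bin_enrichment))  # component order: bin-major
    for (k in seq_len(12)) {
      idx <- ia[comp == k]
      if (length(idx) == 0) {
        if (share[k] > 1e-12)
          warning(sprintf("LDMS component %d has no SNPs; its variance share %.3f is dropped",
                          k, share[k]))
        next
      }
      u[idx] <- rnorm(length(idx), 0,
                      sqrt(config$h2_auto * share[k] / length(idx)))
    }
  }
  if (length(ix) > 0 && config$h2_x > 0)
    u[ix] <- rnorm(length(ix), 0, sqrt(config$h2_x / length(ix)))

  Z <- standardize_dosages(geno)
  g_auto <- if (length(ia)) drop(Z[, ia, drop = FALSE] %*% u[ia]) else numeric(n)
  g_x <- if (length(ix)) drop(Z[, ix, drop = FALSE] %*% u[ix]) else numeric(n)

  fam <- numeric(n)
  if (config$h2_fam > 0) {
    fam <- rnorm(n, 0, sqrt(config$h2_fam))
    if (!is.null(pairs) && nrow(pairs) > 0) {
      # correlation 0.5 within first-degree pairs
      shared <- rnorm(nrow(pairs), 0, sqrt(config$h2_fam))
      own <- rnorm(2 * nrow(pairs), 0, sqrt(config$h2_fam))
      fam[pairs[, 1]] <- sqrt(0.5) * shared + sqrt(0.5) * own[seq_len(nrow(pairs))]
      fam[pairs[, 2]] <- sqrt(0.5) * shared + sqrt(0.5) * own[nrow(pairs) + seq_len(nrow(pairs))]
    }
  }
  e_var <- 1 - config$h2_auto - config$h2_x - config$h2_fam
  env <- rnorm(n, 0, sqrt(max(e_var, 0)))
  liability <- g_auto + g_x + fam + env
  list(effects = u, liability = liability, genetic_value = g_auto + g_x,
       g_auto = g_auto, g_x = g_x, family_effect = fam, annotations = ann)
}

#' Convert latent liabilities to ordinal scores
#'
#' Thresholds are the standard-normal quantiles of the cumulative category
#' frequencies; a liability below the first threshold scores 1, and so on.
#'
#' @param liability numeric vector of liabilities (standard-normal scale).
#' @param category_freqs positive category frequencies summing to 1.
#' @return Integer scores in `1..length(category_freqs)`.
#' @export
liability_to_score <- function(liability, category_freqs) {
  if (any(category_freqs <= 0) || abs(sum(category_freqs) - 1) > 1e-8)
    stop("category frequencies must be positive and sum to 1", call. = FALSE)
  thr <- qnorm(cumsum(category_freqs))[-length(category_freqs)]
  findInterval(liability, thr) + 1L
}

#' Add age, a repeat measurement and offspring counts to a cohort
#'
#' Age shifts the liability by `age_slope / sum(z_j)` per year (so the
#' ordinal-score regression on age has slope approximately `age_slope`),
#' after which the final score is thresholded. The repeat measurement
#' re-thresholds the age-shifted liability after adding measurement noise
#' with SD `repeat_error_sd` (latent-SD units). Children are Poisson with an
#' identity-link mean `fertility_mean + fertility_slope * liability`,
#' clipped at 0 and truncated at 20.
#'
#' @param cohort a partially built cohort list with `liability` (and
#'   optionally `genetic_value`).
#' @param config a [sim_config()].
#' @return The cohort with `age`, `score`, `score_repeat`, `children` fields.
#' @export
simulate_ancillary <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "ancillary"))
  n <- length(cohort$liability)
  spec <- ordinal_scale_spec(config$category_freqs)
  zsum <- sum(spec$densities)

  age <- round(runif(n, config$age_range[1], config$age_range[2]))
  age_c <- age - mean(config$age_range)
  lat <- cohort$liability + age_c * config$age_slope / zsum
  score <- liability_to_score(lat, config$category_freqs)

  # repeat: correlation-preserving noisy re-measurement of the latent scale
  sd_e <- config$repeat_error_sd
  if (sd_e > 0) {
    rho <- 1 / sqrt(1 + sd_e^2)
    lat_sd <- sd(lat)
    lat2 <- rho * (lat - mean(lat)) + sqrt(1 - rho^2) * lat_sd * rnorm(n) + mean(lat)
  } else lat2 <- lat
  score_repeat <- liability_to_score(lat2, config$category_freqs)

  lambda <- pmax(0, config$fertility_mean + config$fertility_slope * cohort$liability)
  children <- pmin(rpois(n, lambda), 20L)

  cohort$age <- age
  cohort$score <- score
  cohort$score_repeat <- score_repeat
  cohort$children <- children
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Generates genotypes (with embedded brother and father-son pairs via
#' gene dropping), per-SNP effects, liabilities, ordinal scores, ages,
#' repeat measurements and offspring counts, all from one root seed.
#'
#' @param config a [sim_config()].
#' @return A list of class `cohort` with elements `genotypes`
#'   ([genotype_matrix()]), `pedigree` (data.frame of id pairs and
#'   relationship), `liability`, `genetic_value`, `effects`, `annotations`,
#'   `score`, `age`, `score_repeat`, `children`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "genotypes"))
  n <- config$n_individuals
  nb <- config$n_brother_pairs; nf <- config$n_father_son_pairs
  params <- sim_founder_params(config)
  geno <- sim_founder_genotypes(n, config, params)
  dos <- geno$dosages
  map <- geno$snps

  # overwrite leading rows with pedigree structure:
  # brothers occupy rows 1..2*nb; father-son pairs the next 2*nf rows.
  set.seed(sub_seed(config$seed, "pedigree"))
  ped <- list()
  row <- 1L
  nfam <- nb + nf
  if (nfam > 0) {
    # batch founder simulation: fathers (one X haplotype), mothers (two)
    fathers <- sim_founder_genotypes(nfam, config, params)$dosages
    mothers <- sim_female_rows(nfam, params)
    fam <- 1L
    if (nb > 0) {
      for (p in seq_len(nb)) {
        dos[row, ] <- gamete_drop(fathers[fam, ], mothers[fam, ], "male", map)
        dos[row + 1L, ] <- gamete_drop(fathers[fam, ], mothers[fam, ], "male", map)
        ped[[length(ped) + 1L]] <- c(row, row + 1L, "brother")
        row <- row + 2L; fam <- fam + 1L
      }
    }
    if (nf > 0) {
      for (p in seq_len(nf)) {
        dos[row, ] <- fathers[fam, ]
        dos[row + 1L, ] <- gamete_drop(fathers[fam, ], mothers[fam, ], "male", map)
        ped[[length(ped) + 1L]] <- c(row, row + 1L, "father_son")
        row <- row + 2L; fam <- fam + 1L
      }
    }
  }
  geno$dosages <- dos
  pedigree <- if (length(ped)) {
    m <- do.call(rbind, ped)
    data.frame(id_a = geno$samples$id[as.integer(m[, 1])],
               id_b = geno$samples$id[as.integer(m[, 2])],
               relationship = m[, 3], stringsAsFactors = FALSE)
  } else data.frame(id_a = character(0), id_b = character(0),
                    relationship = character(0))
  pair_idx <- if (length(ped)) {
    m <- do.call(rbind, ped)
    cbind(as.integer(m[, 1]), as.integer(m[, 2]))
  } else matrix(integer(0), 0, 2)

  eff <- simulate_effects_and_liability(geno, config, pairs = pair_idx)
  cohort <- list(genotypes = geno, pedigree = pedigree,
                 liability = eff$liability, genetic_value = eff$genetic_value,
                 g_auto = eff$g_auto, g_x = eff$g_x,
                 effects = eff$effects, annotations = eff$annotations,
                 config = config)
  cohort <- simulate_ancillary(cohort, config)
  class(cohort) <- "cohort"
  cohort
}

# diploid rows (X included) for non-cohort mothers
sim_female_rows <- function(n, params) {
  h1 <- sim_haplotypes(n, params$freqs, params$copy_prob)
  h2 <- sim_haplotypes(n, params$freqs, params$copy_prob)
  h1 + h2
}

#' Measurement-noise SD giving a target ordinal repeatability
#'
#' Solves, on the latent bivariate-normal scale, for the noise SD such that
#' two thresholded measurements of the same liability have the requested
#' Pearson correlation.
#'
#' @param r_target target repeatability (ordinal-scale Pearson correlation).
#' @param category_freqs category frequencies defining the thresholds.
#' @param weights category scores (default 1..k).
#' @return Noise SD in latent-SD units (0 when `r_target = 1`).
#' @export
repeat_sd_for_target <- function(r_target, category_freqs,
                                 weights = seq_along(category_freqs)) {
  stopifnot(r_target > 0, r_target <= 1)
  if (r_target == 1) return(0)
  f <- function(rho) ordinal_latent_cor(rho, category_freqs, weights) - r_target
  rho <- uniroot(f, c(1e-6, 1 - 1e-9), tol = 1e-9)$root
  sqrt(1 / rho^2 - 1)
}

#' Write a cohort to plain-text and PLINK files
#'
#' Writes `<prefix>.bed/.bim/.fam`, a phenotype/covariate TSV
#' (`<prefix>.pheno.tsv`: id, score, age, sex, children, score_repeat) and a
#' truth TSV (`<prefix>.truth.tsv`: per-individual liability and genetic
#' value) plus `<prefix>.effects.tsv` (per-SNP effects).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param prefix output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, prefix) {
  write_plink(cohort$genotypes, prefix)
  ph <- data.frame(id = cohort$genotypes$samples$id, score = cohort$score,
                   age = cohort$age, sex = cohort$genotypes$samples$sex,
                   children = cohort$children, score_repeat = cohort$score_repeat)
  utils::write.table(ph, paste0(prefix, ".pheno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- data.frame(id = cohort$genotypes$samples$id,
                   liability = cohort$liability,
                   genetic_value = cohort$genetic_value)
  utils::write.table(tr, paste0(prefix, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ef <- data.frame(id = cohort$genotypes$snps$id, effect = cohort$effects)
  utils::write.table(ef, paste0(prefix, ".effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam", ".pheno.tsv",
                             ".truth.tsv", ".effects.tsv")))
}
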