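#' Pipeline configuration
#'
#' Bundles the simulation settings with the QC, association, selection and
#' LD-score-regression thresholds used by [run_pipeline()]. Defaults follow
#' the analysis conventions: MAF > 1e-4, missingness < 0.05, HWE p > 1e-6
#' (females only on X), LD pruning at r2 > 0.9 for the model-SNP set,
#' genome-wide significance 5e-8 with COJO collinearity 0.9 and a 10 Mb LD
#' window, a 0.05 relatedness cutoff for the big K matrix and the unrelated
#' subset, and 200 jackknife blocks.
#'
#' @param sim a [sim_config()].
#' @param maf_min,miss_max,hwe_min QC thresholds.
#' @param prune_r2 LD-pruning threshold for the association model SNPs.
#' @param rel_cutoff relatedness threshold (big K, unrelated selection).
#' @param gws_p genome-wide significance threshold.
#' @param collinearity_r2,cojo_window_bp COJO settings.
#' @param ldsc_blocks jackknife block count.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_snps_auto = 8000),
                            maf_min = 1e-4, miss_max = 0.05, hwe_min = 1e-6,
                            prune_r2 = 0.9, rel_cutoff = 0.05,
                            gws_p = 5e-8, collinearity_r2 = 0.9,
                            cojo_window_bp = 1e7, ldsc_blocks = 200) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, maf_min = maf_min, miss_max = miss_max,
                 hwe_min = hwe_min, prune_r2 = prune_r2,
                 rel_cutoff = rel_cutoff, gws_p = gws_p,
                 collinearity_r2 = collinearity_r2,
                 cojo_window_bp = cojo_window_bp, ldsc_blocks = ldsc_blocks),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; the `sim` key holds
#' [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$maf_range)) sim_args$maf_range <- as.numeric(sim_args$maf_range)
  if (!is.null(sim_args$age_range)) sim_args$age_range <- as.numeric(sim_args$age_range)
  if (!is.null(sim_args$bin_enrichment))
    sim_args$bin_enrichment <- matrix(as.numeric(unlist(sim_args$bin_enrichment)),
                                      nrow = 3, byrow = TRUE)
  sim <- do.call(sim_config, sim_args)
  args <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a cohort, applies genotype QC, builds the relationship
#' matrices, runs the variance-component suite (pedigree, big K small K
#' with X, MAF/LD-stratified), converts estimates to the liability scale
#' and tests enrichment, performs the mixed-model GWAS with
#' conditional-joint SNP selection and variance explained, estimates a
#' split-half genetic correlation by LD score regression, and computes
#' the fertility selection gradient. All stage outputs are written under
#' `out_dir` with a manifest; the aggregate report is returned and saved
#' as JSON and Markdown.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return The report, an object of class `pipeline_report` (a nested
#'   list), invisibly also written to `report.json` / `report.md`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE)
  cat("", file = log_path)
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    logf("stage %s: done", name)
    res
  }
  manifest <- character(0)
  emit <- function(files) manifest <<- c(manifest, basename(files))

  co <- stage("simulate", {
    co <- simulate_cohort(config$sim)
    emit(write_cohort(co, file.path(out_dir, "cohort")))
    co
  })
  geno <- stage("qc", qc_filter(co$genotypes, config$maf_min,
                                config$miss_max, config$hwe_min))
  logf("qc: %d of %d SNPs retained", ncol(geno$dosages), ncol(co$genotypes$dosages))

  is_x <- geno$snps$chr == 23L
  geno_a <- subset_snps(geno, which(!is_x))
  ann <- stage("annotate", assign_ldms_bins(snp_maf(geno_a), ld_scores(geno_a)))

  grms <- stage("grm", {
    ga <- make_grm(geno_a)
    gx <- if (any(is_x)) make_grm_x_male(geno) else NULL
    emit(write_grm_bin(ga, file.path(out_dir, "auto")))
    list(auto = ga, x = gx, ped = pedigree_grm(geno$samples$id, co$pedigree))
  })

  y_adj <- stage("adjust", adjust_phenotype(co$score, data.frame(age = co$age)))
  spec <- ordinal_scale_spec(config$sim$category_freqs)

  fits <- stage("reml", {
    ped <- reml_fit(y_adj, list(ped = grms$ped))
    bk <- big_k_small_k_fit(y_adj, grms$auto, cutoff = config$rel_cutoff,
                            grm_x = grms$x)
    unrel <- select_unrelated(grms$auto, config$rel_cutoff)
    ui <- match(unrel, geno$samples$id)
    ldms <- ldms_fit(y_adj[ui], subset_samples(geno_a, ui), ann)
    list(ped = ped, bigk = bk, ldms = ldms, unrel = unrel, unrel_idx = ui)
  })
  for (nm in c("ped", "bigk", "ldms"))
    emit(write_hsq(fits[[nm]], file.path(out_dir, paste0(nm, ".hsq"))))

  scales_out <- stage("scales", {
    h2_ped_obs <- fits$ped$h2$h2[1]
    ng <- length(fits$ldms$sigma2) - 1L
    low_ld <- which(((fits$ldms$components - 1L) %% 4L) + 1L <= 2L)
    common <- which(((fits$ldms$components - 1L) %/% 4L) + 1L == 3L)
    enr_low <- if (length(low_ld) > 0 && length(low_ld) < ng)
      enrichment_test(fits$ldms, low_ld) else NULL
    enr_common <- if (length(common) > 0 && length(common) < ng)
      enrichment_test(fits$ldms, common) else NULL
    list(liability_factor = liability_factor(spec),
         h2_ped_observed = h2_ped_obs,
         h2_ped_liability = to_liability(min(max(h2_ped_obs, 0), 1), spec),
         enrichment_low_ld = enr_low, enrichment_common = enr_common)
  })

  gwas <- stage("gwas", {
    pruned <- ld_prune(geno_a, r2_max = config$prune_r2)
    null <- fit_null_mlm(y_adj, make_grm(geno_a, pruned))
    ss <- mlm_assoc(null, geno)
    emit(write_ma(ss, file.path(out_dir, "gwas.ma")))
    ss
  })

  cojo <- stage("cojo", {
    ref <- subset_samples(geno, fits$unrel_idx)
    sel <- cojo_select(gwas, ref, p_cutoff = config$gws_p,
                       collinearity_r2 = config$collinearity_r2,
                       window_bp = config$cojo_window_bp)
    sel <- joint_regression_prune(sel, ref, alpha = config$gws_p,
                                  window_bp = config$cojo_window_bp)
    utils::write.table(sel$selected, file.path(out_dir, "cojo.jma.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "cojo.jma.tsv"))
    vexp <- variance_explained_by_set(sel$selected$SNP, ref,
                                      y_adj[fits$unrel_idx])
    list(result = sel, vexp = vexp)
  })

  ldsc_out <- stage("ldsc", {
    # split-half genetic correlation among unrelated individuals, autosomes
    ui <- fits$unrel_idx
    half <- seq_along(ui) %% 2 == 0
    mk <- function(idx) {
      g <- subset_samples(geno_a, ui[idx])
      f <- snp_freq(g)
      g <- subset_snps(g, which(f > 0 & f < 1))   # polymorphic in this half
      pruned <- ld_prune(g, r2_max = config$prune_r2)
      null <- fit_null_mlm(y_adj[ui[idx]], make_grm(g, pruned))
      mlm_assoc(null, g)
    }
    ss1 <- mk(which(half)); ss2 <- mk(which(!half))
    lsc <- data.frame(SNP = geno_a$snps$id, l = ann$ld_score)
    h2 <- ldsc_h2(ss1, lsc, n_blocks = min(config$ldsc_blocks, nrow(ss1) %/% 25))
    rg <- tryCatch(
      ldsc_rg(ss1, ss2, lsc, n_blocks = min(config$ldsc_blocks, nrow(ss1) %/% 25)),
      error = function(e) { logf("ldsc rg: %s", conditionMessage(e)); NULL })
    list(h2 = h2, rg = rg)
  })

  sel_grad <- stage("selection", {
    fr <- fertility_regression(co$children, y_adj)
    selection_gradient(fr)
  })

  report <- list(
    seed = config$sim$seed,
    n_individuals = config$sim$n_individuals,
    n_snps = list(simulated = ncol(co$genotypes$dosages),
                  post_qc = ncol(geno$dosages)),
    h2_table = list(
      pedigree = list(h2 = fits$ped$h2$h2[1], se = fits$ped$h2$se[1]),
      big_k_small_k = list(
        snp = fits$bigk$h2$h2[1], snp_se = fits$bigk$h2$se[1],
        pedigree_only = fits$bigk$h2$h2[2], pedigree_only_se = fits$bigk$h2$se[2],
        x = if (!is.null(grms$x)) fits$bigk$h2$h2[3] else NA,
        x_se = if (!is.null(grms$x)) fits$bigk$h2$se[3] else NA,
        total = unname(fits$bigk$h2_ped_total["h2"]),
        total_se = unname(fits$bigk$h2_ped_total["se"])),
      ldms_total = sum(fits$ldms$h2$h2[seq_len(length(fits$ldms$sigma2) - 1)]),
      liability = scales_out[c("liability_factor", "h2_ped_observed",
                               "h2_ped_liability")]),
    enrichment = list(
      low_ld = if (!is.null(scales_out$enrichment_low_ld))
        unclass(scales_out$enrichment_low_ld)[c("fold", "z", "p", "h2_c", "m_c")],
      common = if (!is.null(scales_out$enrichment_common))
        unclass(scales_out$enrichment_common)[c("fold", "z", "p", "h2_c", "m_c")]),
    gwas = list(n_snps_tested = nrow(gwas),
                n_gws = sum(gwas$p < config$gws_p),
                lambda_gc = median((gwas$b / gwas$se)^2) / qchisq(0.5, 1)),
    cojo = list(n_selected = nrow(cojo$result$selected),
                variance_explained = cojo$vexp$R2,
                variance_explained_se = cojo$vexp$se),
    ldsc = list(h2 = ldsc_out$h2$h2, h2_se = ldsc_out$h2$se_h2,
                intercept = ldsc_out$h2$intercept,
                rg_split_half = if (!is.null(ldsc_out$rg)) ldsc_out$rg$rg else NA,
                rg_se = if (!is.null(ldsc_out$rg)) ldsc_out$rg$se else NA),
    selection = list(slope = sel_grad$slope_b, se = sel_grad$se_slope,
                     pearson_r = sel_grad$pearson_r,
                     per_sd = sel_grad$per_sd, gradient = sel_grad$gradient,
                     contrast_4_vs_1 = score_contrast(sel_grad$slope_b)))
  class(report) <- "pipeline_report"

  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  writeLines(format_report_md(report), file.path(out_dir, "report.md"))
  emit(file.path(out_dir, c("report.json", "report.md")))
  writeLines(sort(unique(manifest)), file.path(out_dir, "manifest.txt"))
  invisible(report)
}

format_report_md <- function(r) {
  c("# Synthetic cohort analysis report",
    "",
    sprintf("- seed: %d; n = %d; SNPs simulated/post-QC: %d/%d",
            r$seed, r$n_individuals, r$n_snps$simulated, r$n_snps$post_qc),
    sprintf("- pedigree h2 (observed scale): %.3f (SE %.3f); liability scale: %.3f",
            r$h2_table$pedigree$h2, r$h2_table$pedigree$se,
            r$h2_table$liability$h2_ped_liability),
    sprintf("- big K small K: SNP %.3f, pedigree-only %.3f, X %.3f, total %.3f",
            r$h2_table$big_k_small_k$snp, r$h2_table$big_k_small_k$pedigree_only,
            r$h2_table$big_k_small_k$x, r$h2_table$big_k_small_k$total),
    sprintf("- LDMS total h2: %.3f", r$h2_table$ldms_total),
    if (!is.null(r$enrichment$low_ld))
      sprintf("- low-LD enrichment: fold %.2f (p = %.3g)",
              r$enrichment$low_ld$fold, r$enrichment$low_ld$p) else
        "- low-LD enrichment: not estimable",
    sprintf("- GWAS: %d SNPs, %d genome-wide significant, lambda_GC %.3f",
            r$gwas$n_snps_tested, r$gwas$n_gws, r$gwas$lambda_gc),
    sprintf("- COJO: %d selected SNPs explaining %.3f of variance",
            r$cojo$n_selected, r$cojo$variance_explained),
    sprintf("- LDSC: h2 %.3f (SE %.3f), split-half rg %.3f",
            r$ldsc$h2, r$ldsc$h2_se, r$ldsc$rg_split_half),
    sprintf("- selection: slope %.4f children/score unit, per-SD %.4f, gradient %.4f",
            r$selection$slope, r$selection$per_sd, r$selection$gradient))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(paste(format_report_md(x), collapse = "\n"), "\n")
  invisible(x)
}
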