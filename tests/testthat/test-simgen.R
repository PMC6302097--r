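test_that("configuration validation enforces the documented invariants", {
  expect_error(sim_config(n_individuals = 0), "positive")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(category_freqs = c(0.5, 0.5, 0.2, -0.2)), "category_freqs")
  expect_error(sim_config(h2_auto = 0.8, h2_x = 0.2, h2_fam = 0.2), "heritability")
  expect_error(sim_config(bin_enrichment = matrix(1, 2, 4)), "bin_enrichment")
  expect_error(sim_config(n_individuals = 100, n_brother_pairs = 60), "pedigree")
})

test_that("liability thresholds and score conversion follow the normal quantiles", {
  freqs <- c(0.32, 0.23, 0.27, 0.18)
  spec <- ordinal_scale_spec(freqs)
  expect_equal(spec$thresholds, qnorm(c(0.32, 0.55, 0.82)), tolerance = 1e-12)
  expect_equal(round(spec$thresholds, 3), c(-0.468, 0.126, 0.915))
  # liability below the first threshold scores 1
  expect_equal(liability_to_score(-1, freqs), 1L)
  expect_equal(liability_to_score(c(-3, 0, 3), freqs), c(1L, 2L, 4L))
  # near-degenerate frequencies put essentially all mass in category 1
  eps <- 1e-6
  sc <- liability_to_score(rnorm(5000), c(1 - 3 * eps, eps, eps, eps))
  expect_true(mean(sc == 1) > 0.999)
  expect_error(liability_to_score(0, c(0.5, 0.5, 0, 0)), "positive")
})

test_that("realized category frequencies converge to the target", {
  freqs <- c(0.32, 0.23, 0.27, 0.18)
  set.seed(11)
  sc <- liability_to_score(rnorm(1e4), freqs)
  gof <- chisq.test(tabulate(sc, 4), p = freqs)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated genotypes respect coding, MAF range and LD decay", {
  cfg0 <- sim_config(n_individuals = 400, n_snps_auto = 300, n_snps_x = 60,
                     ld_decay = 0, n_brother_pairs = 0, n_father_son_pairs = 0,
                     seed = 5)
  g0 <- simulate_genotypes(cfg0)
  expect_true(all(g0$dosages %in% 0:2))
  x_cols <- g0$dosages[, g0$snps$chr == 23L]
  expect_true(all(x_cols %% 2 == 0))          # hemizygous {0,2} coding
  maf <- snp_maf(g0)
  expect_true(all(maf > 0.001 & maf <= 0.5))  # within range up to sampling error
  # independent sites: mean adjacent r2 near the 1/(n-1) noise floor
  r2 <- vapply(seq_len(249), function(j)
    ld_r2(g0$dosages[, j], g0$dosages[, j + 1]), numeric(1))
  expect_lt(mean(r2), 3 / (400 - 1))

  cfg1 <- sim_config(n_individuals = 2000, n_snps_auto = 5000, n_snps_x = 0,
                     ld_decay = 0.99, block_break_prob = 0.02,
                     n_brother_pairs = 0, n_father_son_pairs = 0, seed = 6)
  g1 <- simulate_genotypes(cfg1)
  j <- seq(1, 4999, by = 10)
  r2h <- vapply(j, function(i) ld_r2(g1$dosages[, i], g1$dosages[, i + 1]),
                numeric(1))
  expect_gt(median(r2h), 0.5)
})

test_that("gamete dropping follows Mendelian and X-linked inheritance", {
  snps <- data.frame(id = c("a1", "a2", "x1", "x2"), chr = c(1L, 1L, 23L, 23L),
                     bp = c(100L, 200L, 100L, 200L), a1 = "A", a2 = "G")
  father <- c(2L, 0L, 2L, 0L)
  mother <- c(2L, 0L, 2L, 2L)
  set.seed(1)
  son <- gamete_drop(father, mother, "male", snps)
  expect_equal(son[1:2], c(2L, 0L))            # homozygous parents fix dosage
  expect_equal(son[3:4], c(2L, 2L))            # X from mother only
  # father-son X identity-by-descent is exactly zero: son's X never reflects
  # a paternal allele that the mother lacks
  father2 <- c(2L, 0L, 2L, 2L)
  mother2 <- c(2L, 0L, 0L, 0L)
  for (i in 1:20) {
    s <- gamete_drop(father2, mother2, "male", snps)
    expect_equal(s[3:4], c(0L, 0L))
  }
  expect_error(gamete_drop(father, mother[-1], "male", snps), "SNP map")
})

test_that("sib and father-son pairs show the expected genomic relatedness", {
  cfg <- sim_config(n_individuals = 600, n_snps_auto = 2500, n_snps_x = 400,
                    ld_decay = 0, n_brother_pairs = 100, n_father_son_pairs = 100,
                    seed = 21)
  co <- simulate_cohort(cfg)
  ga <- make_grm(subset_snps(co$genotypes, which(co$genotypes$snps$chr != 23L)))
  gx <- make_grm_x_male(co$genotypes)
  bro <- co$pedigree$relationship == "brother"
  ia <- match(co$pedigree$id_a, co$genotypes$samples$id)
  ib <- match(co$pedigree$id_b, co$genotypes$samples$id)
  sib_auto <- ga$values[cbind(ia[bro], ib[bro])]
  fs_x <- gx$values[cbind(ia[!bro], ib[!bro])]
  expect_lt(abs(mean(sib_auto) - 0.5), 3 * sd(sib_auto) / sqrt(sum(bro)))
  expect_lt(abs(mean(fs_x)), 3 * sd(fs_x) / sqrt(sum(!bro)))
})

test_that("effects and liability realize the configured architecture", {
  cfg <- sim_config(n_individuals = 2000, n_snps_auto = 5000, n_snps_x = 500,
                    h2_auto = 0.36, h2_x = 0.03, h2_fam = 0,
                    n_brother_pairs = 0, n_father_son_pairs = 0, seed = 31)
  geno <- simulate_genotypes(cfg)
  eff <- simulate_effects_and_liability(geno, cfg)
  fit <- lm(eff$liability ~ eff$genetic_value)
  share <- summary(fit)$r.squared
  expect_lt(abs(share - 0.39), 0.03)
  # zero heritability leaves liability independent of genotype
  cfg0 <- sim_config(n_individuals = 500, n_snps_auto = 300, n_snps_x = 50,
                     h2_auto = 0, h2_x = 0, h2_fam = 0,
                     n_brother_pairs = 0, n_father_son_pairs = 0, seed = 32)
  g0 <- simulate_genotypes(cfg0)
  e0 <- simulate_effects_and_liability(g0, cfg0)
  expect_true(all(e0$effects == 0))
  expect_lt(abs(cor(e0$liability, g0$dosages[, 1])), 0.15)
  # variance confined to chosen components stays there
  one_bin <- rbind(0, 0, c(1, 0, 0, 0))
  cfg1 <- sim_config(n_individuals = 400, n_snps_auto = 1000, n_snps_x = 0,
                     bin_enrichment = one_bin, h2_x = 0, h2_fam = 0,
                     n_brother_pairs = 0, n_father_son_pairs = 0, seed = 33)
  g1 <- simulate_genotypes(cfg1)
  e1 <- simulate_effects_and_liability(g1, cfg1)
  other <- e1$annotations$ld_quartile > 1
  expect_true(all(e1$effects[which(g1$snps$chr != 23L)][other] == 0))
})

test_that("ancillary traits hit the configured repeatability, age and fertility couplings", {
  # repeatability: no noise gives identity; calibrated noise gives ~0.88
  cfg <- sim_config(seed = 41, repeat_error_sd = 0)
  co0 <- list(liability = rnorm(2000))
  co0 <- simulate_ancillary(co0, cfg)
  expect_identical(co0$score, co0$score_repeat)

  cfg88 <- sim_config(seed = 42)   # default targets repeatability 0.88
  co <- list(liability = rnorm(9603))
  co <- simulate_ancillary(co, cfg88)
  r <- repeatability(co$score, co$score_repeat)$r
  expect_gt(r, 0.87); expect_lt(r, 0.89)

  # ordinal-score regression on age close to the configured slope
  fit <- lm(co$score ~ co$age)
  expect_lt(abs(coef(fit)[2] - 0.02), 0.006)

  # fertility: slope of children on adjusted score near the configured target
  cfgf <- sim_config(seed = 43)
  cof <- list(liability = rnorm(2e5))
  cof <- simulate_ancillary(cof, cfgf)
  y_adj <- adjust_phenotype(cof$score, data.frame(age = cof$age))
  sl <- coef(lm(cof$children ~ y_adj))[2]
  expect_lt(abs(sl - (-0.030)), 0.008)
  expect_true(all(cof$children <= 20))

  # zero coupling gives no children-score correlation
  cfg0 <- sim_config(seed = 44, fertility_slope = 0)
  coz <- simulate_ancillary(list(liability = rnorm(5000)), cfg0)
  expect_lt(abs(cor(coz$children, coz$score)), 0.04)
})

test_that("seeded cohorts are bit-reproducible and writable", {
  cfg <- sim_config(n_individuals = 120, n_snps_auto = 200, n_snps_x = 40,
                    n_brother_pairs = 10, n_father_son_pairs = 10, seed = 51)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$dosages, c2$genotypes$dosages)
  expect_identical(c1$liability, c2$liability)
  expect_identical(c1$children, c2$children)
  td <- withr::local_tempdir()
  files <- write_cohort(c1, file.path(td, "coh"))
  expect_true(all(file.exists(files)))
  back <- read_plink(file.path(td, "coh"))
  expect_equal(unname(back$dosages), unname(c1$genotypes$dosages))
})
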