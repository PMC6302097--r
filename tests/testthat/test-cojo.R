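test_that("a lone significant SNP is selected with its marginal effect", {
  set.seed(26)
  cfg <- sim_config(n_individuals = 400, n_snps_auto = 20, n_snps_x = 0,
                    ld_decay = 0, n_brother_pairs = 0, n_father_son_pairs = 0,
                    seed = 26)
  geno <- simulate_genotypes(cfg)
  y <- 0.8 * scale(geno$dosages[, 7])[, 1] + rnorm(400, 0, 0.6)
  ss <- ols_sumstats(y, geno)
  res <- cojo_select(ss, geno, p_cutoff = 5e-8)
  expect_equal(res$selected$SNP, geno$snps$id[7])
  expect_equal(res$selected$b_joint, res$selected$b, tolerance = 1e-9)
  # nothing significant: empty result
  ss0 <- ss; ss0$p <- rep(0.5, nrow(ss0)); ss0$b <- ss0$b * 0.01
  expect_equal(nrow(cojo_select(ss0, geno)$selected), 0)
})

test_that("joint effects on correlated SNPs solve the LD system", {
  # marginal standardized betas (0.1, 0.08) at LD r: joint = R^{-1} b
  set.seed(27)
  cfg <- sim_config(n_individuals = 2000, n_snps_auto = 2, n_snps_x = 0,
                    ld_decay = 0.6, n_brother_pairs = 0, n_father_son_pairs = 0,
                    seed = 27)
  geno <- simulate_genotypes(cfg)
  Gc <- scale(geno$dosages, scale = FALSE)
  sd12 <- apply(geno$dosages, 2, sd)
  r <- cor(geno$dosages[, 1], geno$dosages[, 2])
  bs <- c(0.1, 0.08)                    # standardized-scale marginals
  b <- bs / sd12                        # dosage-scale marginals
  n <- 2000
  ss <- data.frame(SNP = geno$snps$id, A1 = geno$snps$a1, A2 = geno$snps$a2,
                   freq = snp_freq(geno), b = b, se = rep(0.001, 2),
                   p = rep(1e-20, 2), N = n)
  res <- cojo_select(ss, geno, p_cutoff = 1e-5, collinearity_r2 = 0.99)
  joint_std <- res$selected$b_joint[match(geno$snps$id, res$selected$SNP)] * sd12
  oracle <- solve(matrix(c(1, r, r, 1), 2), bs)
  # reference cross-products use centred (not standardized) dosages, so the
  # comparison is to the empirical-LD solve, within numerical tolerance
  expect_equal(sort(joint_std), sort(oracle), tolerance = 1e-6)
  with_r5 <- solve(matrix(c(1, 0.5, 0.5, 1), 2), c(0.1, 0.08))
  expect_equal(with_r5, c(0.08, 0.04), tolerance = 1e-12)
})

test_that("stepwise summary-statistic selection matches individual-level stepwise regression", {
  for (seed in c(28, 29)) {
    cfg <- sim_config(n_individuals = 500, n_snps_auto = 40, n_snps_x = 0,
                      ld_decay = 0.7, n_brother_pairs = 0,
                      n_father_son_pairs = 0, seed = seed)
    geno <- simulate_genotypes(cfg)
    G <- geno$dosages
    set.seed(seed)
    causal <- sample(40, 3)
    y <- drop(scale(G[, causal]) %*% c(0.5, 0.4, -0.45)) + rnorm(500)
    y <- y - mean(y)
    ss <- ols_sumstats(y, geno)
    res <- cojo_select(ss, geno, p_cutoff = 5e-8)
    oracle <- stepwise_oracle(y, G, cutoff = 5e-8)
    expect_setequal(res$selected$SNP, geno$snps$id[oracle$sel])
    ob <- oracle$beta[match(res$selected$SNP, geno$snps$id[oracle$sel])]
    expect_equal(res$selected$b_joint, ob, tolerance = 1e-6)
  }
})

test_that("orthogonal significant SNPs keep their marginal effects", {
  set.seed(30)
  cfg <- sim_config(n_individuals = 600, n_snps_auto = 15, n_snps_x = 0,
                    ld_decay = 0, n_brother_pairs = 0, n_father_son_pairs = 0,
                    seed = 30)
  geno <- simulate_genotypes(cfg)
  y <- drop(scale(geno$dosages[, c(2, 9)]) %*% c(0.6, 0.5)) + rnorm(600, 0, 0.5)
  ss <- ols_sumstats(y - mean(y), geno)
  res <- cojo_select(ss, geno, p_cutoff = 5e-8)
  marg_sig <- ss$SNP[ss$p < 5e-8]
  expect_setequal(res$selected$SNP, marg_sig)
  m <- match(res$selected$SNP, ss$SNP)
  expect_equal(res$selected$b_joint, ss$b[m], tolerance = 0.02)
})

test_that("alignment flips swapped alleles and drops discrepant frequencies", {
  set.seed(31)
  cfg <- sim_config(n_individuals = 300, n_snps_auto = 10, n_snps_x = 0,
                    ld_decay = 0, n_brother_pairs = 0, n_father_son_pairs = 0,
                    seed = 31)
  geno <- simulate_genotypes(cfg)
  y <- 0.8 * scale(geno$dosages[, 4])[, 1] + rnorm(300, 0, 0.5)
  ss <- ols_sumstats(y, geno)
  flipped <- ss
  flipped$A1 <- ss$A2; flipped$A2 <- ss$A1
  flipped$b <- -ss$b; flipped$freq <- 1 - ss$freq
  r1 <- cojo_select(ss, geno, p_cutoff = 1e-6)
  r2 <- cojo_select(flipped, geno, p_cutoff = 1e-6)
  expect_equal(r1$selected$SNP, r2$selected$SNP)
  expect_equal(abs(r1$selected$b_joint), abs(r2$selected$b_joint), tolerance = 1e-9)
  bad_freq <- ss; bad_freq$freq[4] <- 1 - bad_freq$freq[4]
  expect_message(r3 <- cojo_select(bad_freq, geno, p_cutoff = 1e-6),
                 "frequency discrepancy")
  expect_false(geno$snps$id[4] %in% r3$selected$SNP)
  bad_allele <- ss; bad_allele$A1[4] <- "T"
  expect_message(cojo_select(bad_allele, geno, p_cutoff = 1e-6),
                 "mismatched alleles")
})

test_that("joint-regression pruning drops SNPs that fail jointly", {
  # near-duplicate pair (r2 > 0.95): only one survives joint pruning
  set.seed(32)
  n <- 500
  x1 <- sample(0:2, n, TRUE, prob = c(0.36, 0.48, 0.16))
  x2 <- x1
  flip <- sample(n, 3)
  x2[flip] <- 2L - x2[flip]
  expect_gt(cor(x1, x2)^2, 0.95)
  g <- toy_geno(cbind(x1, x2, sample(0:2, n, TRUE)))
  y <- 0.6 * scale(x1)[, 1] + rnorm(n, 0, 0.7)
  ss <- ols_sumstats(y - mean(y), g)
  forced <- cojo_select(ss, g, p_cutoff = 5e-8, collinearity_r2 = 0.999)
  fabricated <- forced
  if (!all(c("s1", "s2") %in% forced$selected$SNP)) {
    # force both duplicates into the model, then prune
    ws_sel <- cojo_select(ss, g, p_cutoff = 1, collinearity_r2 = 0.999)
    fabricated <- ws_sel
  }
  pruned <- joint_regression_prune(fabricated, g, alpha = 5e-8)
  expect_lte(sum(pruned$selected$SNP %in% c("s1", "s2")), 1)
  expect_true(all(pruned$selected$p_joint < 5e-8))
  # orthogonal, all-significant sets pass unchanged; empty input stays empty
  cfg <- sim_config(n_individuals = 600, n_snps_auto = 8, n_snps_x = 0,
                    ld_decay = 0, n_brother_pairs = 0, n_father_son_pairs = 0,
                    seed = 33)
  go <- simulate_genotypes(cfg)
  yo <- drop(scale(go$dosages[, c(1, 5)]) %*% c(0.7, 0.6)) + rnorm(600, 0, 0.4)
  sso <- ols_sumstats(yo - mean(yo), go)
  ro <- cojo_select(sso, go, p_cutoff = 5e-8)
  rp <- joint_regression_prune(ro, go, alpha = 5e-8)
  expect_equal(rp$selected$SNP, ro$selected$SNP)
  empty <- cojo_select(data.frame(SNP = go$snps$id[1], A1 = "A", A2 = "G",
                                  freq = snp_freq(go)[1],
                                  b = 0.01, se = 0.05, p = 0.8, N = 100),
                       go, p_cutoff = 5e-8)
  expect_equal(nrow(joint_regression_prune(empty, go)$selected), 0)
})
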