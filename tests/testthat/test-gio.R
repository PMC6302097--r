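test_that("PLINK bed/bim/fam round-trips including missing genotypes", {
  set.seed(3)
  d <- matrix(sample(c(0:2, NA), 35, replace = TRUE), 5, 7)
  sex <- c("male", "female", "male", "female", "male")
  d[sex == "male", 6:7][!is.na(d[sex == "male", 6:7]) &
                          d[sex == "male", 6:7] == 1] <- 2  # male X is {0,2}
  g <- genotype_matrix(d,
    snps = data.frame(id = sprintf("s%d", 1:7), chr = c(1L, 1L, 1L, 2L, 2L, 23L, 23L),
                      bp = 1:7 * 100L, a1 = "A", a2 = "G"),
    samples = data.frame(id = sprintf("i%d", 1:5), sex = sex))
  td <- withr::local_tempdir()
  write_plink(g, file.path(td, "t"))
  back <- read_plink(file.path(td, "t"))
  expect_equal(unname(back$dosages), unname(g$dosages))
  expect_equal(back$snps$id, g$snps$id)
  expect_equal(back$snps$a1, g$snps$a1)
  expect_equal(back$samples$sex, g$samples$sex)   # fam 1/2 -> male/female

  # sample-major flag rejected
  raw <- readBin(file.path(td, "t.bed"), "raw", n = 1e4)
  raw[3] <- as.raw(0x00)
  writeBin(raw, file.path(td, "t.bed"))
  expect_error(read_plink(file.path(td, "t")), "sample-major")
  raw[1] <- as.raw(0xff)
  writeBin(raw, file.path(td, "t.bed"))
  expect_error(read_plink(file.path(td, "t")), "magic")
})

test_that("hard-calling keeps only confident genotypes", {
  p <- array(0, c(2, 3, 3))
  p[1, 1, ] <- c(0.95, 0.04, 0.01)   # confident dosage 0
  p[1, 2, ] <- c(0.5, 0.4, 0.1)      # max 0.5 <= 0.9: missing
  p[1, 3, ] <- c(0, 0, 1)            # certain dosage 2
  p[2, 1, ] <- c(0.9, 0.1, 0)        # exactly at threshold: missing
  p[2, 2, ] <- c(0.05, 0.91, 0.04)
  p[2, 3, ] <- c(1, 0, 0)
  g <- hard_call(p)
  expect_equal(unname(g$dosages[1, ]), c(0L, NA, 2L))
  expect_equal(unname(g$dosages[2, ]), c(NA, 1L, 0L))
  expect_error(hard_call(array(-1, c(1, 1, 3))), "negative")
})

test_that("exact HWE test matches enumeration and is allele-symmetric", {
  expect_equal(hwe_exact(25, 50, 25), 1)
  expect_equal(hwe_exact(1, 0, 1), 1 / 3)   # het in {0,2}: P(0)=1/3
  for (cc in list(c(10, 5, 3), c(2, 10, 40), c(0, 3, 7))) {
    expect_equal(hwe_exact(cc[1], cc[2], cc[3]), hwe_exact(cc[3], cc[2], cc[1]))
  }
  expect_error(hwe_exact(0, 0, 0), "all-zero")
  # agreement with an independent full-enumeration oracle
  oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa; nA <- 2 * nAA + nAa
    hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), 2)
    pr <- vapply(hets, function(h) {
      aa <- (min(nA, 2 * n - nA) - h) / 2; AA <- n - h - aa
      exp(h * log(2) + lfactorial(n) - lfactorial(AA) - lfactorial(h) -
            lfactorial(aa) + lfactorial(nA) + lfactorial(2 * n - nA) -
            lfactorial(2 * n))
    }, numeric(1))
    sum(pr[pr <= pr[match(nAa, hets)] + 1e-12])
  }
  for (cc in list(c(5, 2, 5), c(8, 9, 1), c(3, 14, 3)))
    expect_equal(hwe_exact(cc[1], cc[2], cc[3]), oracle(cc[1], cc[2], cc[3]),
                 tolerance = 1e-10)
})

test_that("QC filtering applies MAF, missingness and sex-aware HWE rules", {
  set.seed(8)
  n <- 120
  base <- function() sample(0:2, n, TRUE, prob = c(0.49, 0.42, 0.09))
  d <- cbind(
    base(),                      # passes everything
    rep(0L, n),                  # monomorphic: fails MAF
    {x <- base(); x[1:10] <- NA; x},   # 8.3% missing: fails missingness
    {x <- rep(1L, n); x},        # all-het: fails HWE
    base(), base())              # pass
  # three SNPs each fail exactly one filter, three survive
  g <- toy_geno(d, sex = rep(c("male", "female"), n / 2))
  kept <- qc_filter(g, maf_min = 1e-4, miss_max = 0.05, hwe_min = 1e-6)
  expect_equal(ncol(kept$dosages), 3)
  expect_false(any(c("s2", "s3", "s4") %in% kept$snps$id))
  # idempotent
  again <- qc_filter(kept, maf_min = 1e-4, miss_max = 0.05, hwe_min = 1e-6)
  expect_identical(again$snps$id, kept$snps$id)
  # identity thresholds change nothing
  idty <- qc_filter(g, maf_min = 0, miss_max = 1, hwe_min = 0)
  expect_identical(idty$snps$id, g$snps$id)
  # X HWE evaluated in females only: males all-het would be impossible anyway,
  # so construct an X SNP in HWE among females but skewed among males
  dx <- cbind(ifelse(rep(c(TRUE, FALSE), n / 2), 2L, base()))
  gx <- genotype_matrix(dx, data.frame(id = "x1", chr = 23L, bp = 100L,
                                       a1 = "A", a2 = "G"),
                        data.frame(id = sprintf("i%d", 1:n),
                                   sex = rep(c("male", "female"), n / 2)))
  expect_equal(ncol(qc_filter(gx, hwe_min = 1e-6)$dosages), 1)
})

test_that("LD r2 matches hand-computed Pearson correlations", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1)   # perfect negative LD
  # hand Pearson: Sxy = 2, Sxx = 2.75, Syy = 2 -> r2 = 4 / 5.5 = 8/11
  expect_equal(ld_r2(c(0, 0, 1, 2), c(0, 1, 1, 2)), 8 / 11)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "zero-variance")
  expect_error(ld_r2(c(NA, NA, 1), c(0, 1, 2)), "fewer than 2")
  # adjusted estimator subtracts the small-sample bias
  x <- c(0, 0, 1, 2); y <- c(0, 1, 1, 2)
  expect_equal(ld_r2(x, y, adjusted = TRUE), 8 / 11 - (1 - 8 / 11) / 2)
})

test_that("LD scores honour the window and count self-correlation", {
  # duplicated SNP pair plus an orthogonal SNP in the no-noise limit
  x <- rep(c(0, 1, 2, 0, 2, 1), 10)
  z <- rep(c(0, 2, 0, 2, 1, 1), 10)
  g <- toy_geno(cbind(x, x, z))
  l <- ld_scores(g)
  expect_equal(l[1], 2 + ld_r2(x, z))
  expect_equal(l[2], 2 + ld_r2(x, z))
  # SNPs farther apart than the window are excluded
  g2 <- genotype_matrix(cbind(x, x),
    snps = data.frame(id = c("a", "b"), chr = 1L, bp = c(1L, 25000001L),
                      a1 = "A", a2 = "G"),
    samples = data.frame(id = sprintf("i%d", seq_along(x)), sex = "male"))
  expect_equal(ld_scores(g2), c(1, 1))
  expect_error(ld_scores(genotype_matrix(cbind(x, z),
    snps = data.frame(id = c("a", "b"), chr = 1L, bp = c(200L, 100L),
                      a1 = "A", a2 = "G"),
    samples = data.frame(id = sprintf("i%d", seq_along(x)), sex = "male"))),
    "sorted")
  # independent SNPs: scores near 1 + spurious noise floor
  set.seed(2)
  gi <- toy_geno(matrix(sample(0:2, 500 * 40, TRUE), 500, 40))
  li <- ld_scores(gi)
  expect_lt(abs(mean(li) - (1 + 39 / 499)), 0.05)
  # permuting individuals leaves LD scores unchanged
  gp <- toy_geno(gi$dosages[sample(500), ])
  expect_equal(ld_scores(gp), li, tolerance = 1e-12)
})

test_that("MAF/LD component assignment partitions SNPs as printed", {
  ann <- assign_ldms_bins(c(0.0005, 0.01, 0.2, 0.011), c(1, 2, 3, 4))
  expect_equal(ann$maf_bin, c(1L, 2L, 3L, 3L))   # MAF = 0.01 in middle bin
  a2 <- assign_ldms_bins(rep(0.2, 8), 1:8)
  expect_equal(a2$ld_quartile, rep(1:4, each = 2))
  # uniform scores: rank ties broken by order, sizes differ by <= 1
  a3 <- assign_ldms_bins(rep(0.3, 10), rep(5, 10))
  expect_lte(diff(range(tabulate(a3$ld_quartile, 4))), 1)
  expect_error(assign_ldms_bins(c(0.6), 1), "MAF")
  # partition property: each SNP in exactly one of 12 components
  set.seed(4)
  maf <- exp(runif(300, log(2e-5), log(0.5))); maf <- pmin(maf, 0.5)
  ann4 <- assign_ldms_bins(maf, runif(300, 1, 50))
  expect_true(all(ann4$component %in% 1:12))
  expect_equal(sum(tabulate(ann4$component, 12)), 300)
  expect_equal(ann4$component, (ann4$maf_bin - 1L) * 4L + ann4$ld_quartile)
})

test_that("LD pruning removes later members of correlated pairs", {
  x <- rep(c(0, 1, 2, 0, 2, 1), 20)
  set.seed(9)
  z <- sample(0:2, 120, TRUE)
  g <- toy_geno(cbind(x, x, x, z))    # chain a=b, b=c
  kept <- ld_prune(g, r2_max = 0.9)
  expect_equal(kept, c("s1", "s4"))   # earliest of the chain retained
  gi <- toy_geno(matrix(sample(0:2, 200 * 10, TRUE), 200, 10))
  expect_equal(ld_prune(gi), gi$snps$id)   # independent SNPs all retained
  # no retained pair exceeds the threshold
  cfg <- sim_config(n_individuals = 300, n_snps_auto = 400, n_snps_x = 0,
                    ld_decay = 0.95, n_brother_pairs = 0,
                    n_father_son_pairs = 0, seed = 10)
  gs <- simulate_genotypes(cfg)
  kept2 <- ld_prune(gs, r2_max = 0.5, window_snps = 100, step = 20)
  idx <- match(kept2, gs$snps$id)
  r2 <- cor(gs$dosages[, idx])^2
  diag(r2) <- 0
  expect_lt(max(r2), 0.5 + 1e-9)
})

test_that("summary statistics round-trip through the .ma exchange format", {
  ss <- data.frame(SNP = c("rs1", "rs2", "rs3"), A1 = "A", A2 = "G",
                   freq = c(0.1, 0.25, 0.5), b = c(0.02, -0.015, 1e-4),
                   se = c(0.01, 0.02, 0.005),
                   p = c(0.0455, 2.3e-12, 0.9841), N = c(1000L, 999L, 1000L),
                   stringsAsFactors = FALSE)
  td <- withr::local_tempdir()
  write_ma(ss, file.path(td, "t.ma"))
  back <- read_ma(file.path(td, "t.ma"))
  expect_equal(back$b, ss$b)
  expect_equal(back$p, ss$p)      # scientific notation survives
  expect_equal(back$SNP, ss$SNP)
  ss$se[1] <- 0
  expect_error(write_ma(ss, file.path(td, "bad.ma")), "se")
  writeLines("SNP A1 A2 freq b se", file.path(td, "short.ma"))
  expect_error(read_ma(file.path(td, "short.ma")))
})
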