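test_that("genotype simulation is deterministic and produces valid dosages", {
  cfg <- sim_config(n_samples = 50, n_snps = 200, seed = 3)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_true(all(p1$dosages %in% 0:2))
  expect_equal(dim(p1), c(50, 200))
  expect_equal(length(unique(p1$snp_meta$chrom)), cfg$n_chromosomes)
})

test_that("adjacent-SNP correlation matches the block-LD target", {
  # independence case: mean |corr| near zero
  cfg0 <- sim_config(n_samples = 2000, n_snps = 200, n_chromosomes = 1,
                     within_block_corr = 0, seed = 5)
  p0 <- simulate_genotypes(cfg0)
  ac0 <- sapply(1:199, function(j) cor(p0$dosages[, j], p0$dosages[, j + 1]))
  expect_lt(mean(abs(ac0)), 3 / sqrt(2000))

  # strong-LD case: correlation between adjacent SNPs inside a block
  cfg8 <- sim_config(n_samples = 5000, n_snps = 250, n_chromosomes = 1,
                     within_block_corr = 0.8, seed = 5)
  p8 <- simulate_genotypes(cfg8)
  b <- cfg8$block_size_snps
  within <- setdiff(1:249, seq(b, 249, by = b))  # skip block boundaries
  ac8 <- sapply(within, function(j) cor(p8$dosages[, j], p8$dosages[, j + 1]))
  expect_gt(mean(ac8), 0.7)
  expect_lt(mean(ac8), 0.9)

  # across blocks: no correlation in expectation
  across <- seq(b, 249, by = b)
  acx <- sapply(across, function(j) cor(p8$dosages[, j], p8$dosages[, j + 1]))
  expect_lt(mean(abs(acx)), 3 / sqrt(5000))
})

test_that("empirical MAF stays inside the configured range", {
  cfg <- sim_config(n_samples = 2000, n_snps = 500, maf_range = c(0.1, 0.4),
                    seed = 7)
  p <- simulate_genotypes(cfg)
  f <- allele_freq(p)
  maf <- pmin(f, 1 - f)
  tol <- 3 * sqrt(0.25 / (2 * 2000))
  expect_true(all(maf > 0.1 - tol & maf < 0.4 + tol))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(n_snps = 101, block_size_snps = 25), "divisible")
  expect_error(sim_config(within_block_corr = 1), "within_block_corr")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(h2_coding = 0.5, h2_buffer = 0.4, h2_rest = 0.2),
               "sum")
})

test_that("gene annotation is non-overlapping, flagged, and reproducible", {
  cfg <- sim_config(n_snps = 400, n_chromosomes = 1, n_genes = 2,
                    n_geneset_genes = 2, gene_length_bp = 10000, seed = 11)
  g1 <- simulate_gene_annotation(cfg)
  g2 <- simulate_gene_annotation(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 2)
  expect_equal(sum(g1$in_geneset), 2)
  chrom_len <- 400 * cfg$snp_spacing_bp
  expect_true(all(g1$start_bp >= 1 & g1$stop_bp <= chrom_len))
  o <- order(g1$start_bp)
  expect_true(all(g1$start_bp[o][-1] > g1$stop_bp[o][-nrow(g1)]))
  expect_true(all(g1$stop_bp - g1$start_bp + 1 == cfg$gene_length_bp))

  # genes that cannot fit
  cfg_bad <- sim_config(n_snps = 25, n_chromosomes = 1, n_genes = 10,
                        n_geneset_genes = 1, gene_length_bp = 50000,
                        snp_spacing_bp = 100, seed = 1)
  expect_error(simulate_gene_annotation(cfg_bad), "overlap")
})

test_that("phenotype simulation hits exact in-sample partition variances", {
  co <- quick_cohort(seed = 13, h2_coding = 0.01, h2_buffer = 0.03,
                     h2_rest = 0.05)
  expect_equal(unname(co$truth$realized_var),
               c(0.01, 0.03, 0.05), tolerance = 1e-10)
  expect_equal(length(co$phenotype), 300)
  expect_true(all(unlist(co$truth$causal) %in% co$panel$snp_meta$id))

  co2 <- quick_cohort(seed = 13, h2_coding = 0.01, h2_buffer = 0.03,
                      h2_rest = 0.05)
  expect_identical(co$phenotype, co2$phenotype)
})

test_that("an all-null architecture leaves only covariate and noise variance", {
  co <- quick_cohort(seed = 17, n = 2000, h2_coding = 0, h2_buffer = 0,
                     h2_rest = 0)
  expect_true(all(co$truth$realized_var == 0))
  # residual after removing the covariate part should match sigma2_e = 1
  X <- covar_design(co$covariates)
  res <- residuals(lm(co$phenotype ~ X))
  expect_equal(var(res), 1, tolerance = 0.1)
  # single-SNP regressions behave as a null
  p <- sapply(seq(1, 1000, by = 20), function(j)
    summary(lm(co$phenotype ~ co$panel$dosages[, j]))$coefficients[2, 4])
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("a positive-h2 partition without SNPs is a configuration error", {
  cfg <- sim_config(n_samples = 50, n_snps = 100, n_chromosomes = 1,
                    h2_buffer = 0.1, seed = 1)
  panel <- simulate_genotypes(cfg)
  asg <- snp_assignment(rep("rest", 100), buffer_kb = 10,
                        snp_ids = panel$snp_meta$id)
  expect_error(simulate_phenotype(panel, asg, cfg), "zero SNPs")
})

test_that("shared effects reproduce the same architecture in a second cohort", {
  cfg1 <- sim_config(n_samples = 200, n_snps = 500, seed = 19,
                     h2_coding = 0.05, h2_rest = 0.05)
  co1 <- simulate_cohort(cfg1)
  cfg2 <- sim_config(n_samples = 150, n_snps = 500, seed = 23,
                     h2_coding = 0.05, h2_rest = 0.05)
  p2 <- simulate_genotypes(cfg2)
  asg2 <- build_partition(co1$genes, p2, cfg1$buffer_kb_truth)
  co2 <- simulate_phenotype(p2, asg2, cfg2, effects = co1$truth$effects)
  expect_identical(co2$truth$causal, co1$truth$causal)
  expect_identical(co2$truth$effects, co1$truth$effects)
  # realized variance close to, but not exactly, the target in the new sample
  expect_equal(unname(co2$truth$realized_var["coding"]), 0.05,
               tolerance = 0.5)
})
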