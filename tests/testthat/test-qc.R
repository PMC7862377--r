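# closed-form conditional probability of a heterozygote count given allele
# counts (Levene/Haldane distribution) - independent of the package's
# normalization-based route
hwe_closed_form_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n_aa + n_Aa
  if (nA == 0 || nB == 0) return(1)
  hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  pr <- sapply(hs, function(h)
    exp(lfactorial(n) + lfactorial(nA) + lfactorial(nB) + h * log(2) -
          lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((nB - h) / 2) - lfactorial(2 * n)))
  p_obs <- pr[hs == n_Aa]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# exhaustive random-pairing oracle for tiny n: place the nA "A" alleles on
# 2n slots in every possible way, pair consecutive slots into genotypes,
# and count heterozygote outcomes
hwe_pairing_oracle_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  slots <- 2 * n
  if (nA == 0 || nA == slots) return(1)
  combos <- combn(slots, nA)
  hets <- apply(combos, 2, function(ix) {
    al <- integer(slots); al[ix] <- 1L
    pair <- matrix(al, nrow = 2)
    sum(pair[1, ] != pair[2, ])
  })
  tab <- table(hets) / ncol(combos)
  p_obs <- tab[[as.character(n_Aa)]]
  sum(tab[tab <= p_obs * (1 + 1e-7)])
}

test_that("Hardy-Weinberg exact test handles canonical cases", {
  expect_lt(hwe_exact_test(50, 0, 50), 1e-10)
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_equal(hwe_exact_test(0, 0, 10), 1.0)
  expect_error(hwe_exact_test(0, 0, 0), "all genotype counts are zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("Hardy-Weinberg p matches the exhaustive pairing oracle at tiny n", {
  cases <- list(c(2, 1, 2), c(1, 3, 1), c(0, 2, 3), c(3, 0, 2), c(2, 2, 2))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_pairing_oracle_p(cs[1], cs[2], cs[3]),
                 tolerance = 1e-12)
})

test_that("Hardy-Weinberg p matches closed-form enumeration up to n = 200", {
  set.seed(8)
  for (i in 1:40) {
    n <- sample(3:200, 1)
    nA <- sample(1:(2 * n - 1), 1)
    hs <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
    h <- sample(hs, 1)
    nAA <- (nA - h) / 2
    naa <- n - nAA - h
    expect_equal(hwe_exact_test(nAA, h, naa), hwe_closed_form_p(nAA, h, naa),
                 tolerance = 1e-12)
  }
})

test_that("qc_filter removes markers per criterion in the documented order", {
  set.seed(21)
  n <- 200
  # 100 benign filler SNPs keep per-sample call rates at >= 0.99 so the
  # SNP-level filters, not the sample filter, see the missing calls
  filler <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
  # v101: rare (maf 0.005); v102: gross HWE violation; v103: 20% missing;
  # v104: rare AND out of HWE -> counted once, under MAF
  s2 <- c(rep(0, n - 2), 1, 1)
  s3 <- rep(c(0, 2), n / 2)
  s4 <- rbinom(n, 2, 0.4); s4[1:40] <- NA
  s5 <- c(rep(0, n - 1), 2)
  panel <- genotype_panel(cbind(filler, s2, s3, s4, s5),
                          data.frame(id = paste0("v", 1:104), chrom = 1,
                                     pos_bp = 1:104 * 100, allele1 = "A",
                                     allele2 = "B"),
                          paste0("i", 1:n))
  res <- qc_filter(panel, qc_thresholds())
  expect_equal(res$report$samples_removed, 0)
  expect_equal(res$report$maf_removed, 2)       # v101 and v104
  expect_equal(res$report$hwe_removed, 1)       # v102
  expect_equal(res$report$missing_removed, 1)   # v103
  expect_equal(res$panel$snp_meta$id, paste0("v", 1:100))
})

test_that("qc_filter is an identity on clean data and is idempotent", {
  co <- quick_cohort(seed = 5, n = 150, m = 200, maf_range = c(0.2, 0.5))
  r1 <- qc_filter(co$panel)
  expect_equal(unlist(r1$report[1:4]), c(samples_removed = 0, maf_removed = 0,
                                         hwe_removed = 0, missing_removed = 0))
  expect_equal(r1$panel$dosages, co$panel$dosages)
  r2 <- qc_filter(r1$panel)
  expect_equal(r2$panel$dosages, r1$panel$dosages)
  expect_equal(unlist(r2$report[1:4]), unlist(r1$report[1:4]))
})

test_that("low-callrate samples are removed before SNP filters", {
  set.seed(31)
  n <- 100
  x <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
  x[1, 1:10] <- NA  # sample 1 callrate 0.5
  panel <- genotype_panel(x, data.frame(id = paste0("v", 1:20), chrom = 1,
                                        pos_bp = 1:20 * 100, allele1 = "A",
                                        allele2 = "B"), paste0("i", 1:n))
  res <- qc_filter(panel, qc_thresholds())
  expect_equal(res$report$samples_removed, 1)
  expect_false("i1" %in% res$panel$sample_ids)
  # with sample 1 gone, no SNP has residual missingness
  expect_equal(res$report$missing_removed, 0)
})

test_that("removing every marker is an explicit error", {
  panel <- tiny_panel(dosages = matrix(c(0, 0, 0, 0, 0, 1), 3, 2),
                      pos = c(100, 200))
  expect_error(qc_filter(panel, qc_thresholds(min_maf = 0.4)), "every SNP")
})
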