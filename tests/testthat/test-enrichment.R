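test_that("expected heritability is proportional to component size", {
  expect_equal(expected_h2(4656938, 4656938, 0.0753), 0.0753)
  expect_equal(expected_h2(74436, 4656938, 0.0945),
               74436 / 4656938 * 0.0945)
  expect_equal(expected_h2(1, 1000, 0), 0)
  expect_error(expected_h2(0, 10, 0.5), "m_k")
  expect_error(expected_h2(11, 10, 0.5), "m_k")
  # exact additivity over an exclusive partition
  parts <- c(81453, 21288, 4554197)
  expect_equal(sum(sapply(parts, expected_h2, M = sum(parts),
                          h2_total = 0.0803)), 0.0803, tolerance = 1e-12)
})

test_that("enrichment ratios reproduce published-style worked rows", {
  # 35 kb buffer model, third subset
  e1 <- enrichment(0.0105, 0.0025, 74436, 4656938, 0.0945)
  expect_equal(e1$enrichment, 6.94, tolerance = 0.01)
  # 10 kb buffer model, second and third subsets
  e2 <- enrichment(0.0090, 0.0021, 21288, 4656938, 0.0803)
  expect_equal(e2$enrichment, 24.43, tolerance = 0.01)
  e3 <- enrichment(0.0077, 0.0021, 21288, 4656938, 0.0947)
  expect_equal(e3$enrichment, 17.82, tolerance = 0.01)
  expect_true(e1$significant && e2$significant && e3$significant)
})

test_that("enrichment of the whole genome is identically one", {
  e <- enrichment(0.08, 0.008, 1000, 1000, 0.08)
  expect_identical(e$enrichment, 1)
  expect_false(e$significant)
  expect_error(enrichment(0.1, 0.01, 0, 100, 0.1), "zero SNPs")
  # alternative ratio-threshold significance rule
  er <- enrichment(0.01, 1e-9, 10, 1000, 0.08, rule = "ratio")
  expect_true(er$enrichment > 1.96 && er$significant)
  expect_false(enrichment(0.0015, 1e-9, 10, 1000, 0.08,
                          rule = "ratio")$significant)
})

test_that("fixed-effects meta-analysis pools by inverse variance", {
  # equal SEs reduce to the arithmetic mean
  m <- fixed_effects_meta(c(1, 2, 3), c(0.5, 0.5, 0.5))
  expect_equal(m$pooled, 2)
  expect_equal(m$se, 0.5 / sqrt(3))
  # hand-computed pooled value from protein-coding style inputs
  m2 <- fixed_effects_meta(c(0.38, 0.33, 0.55), c(0.16, 0.16, 0.18))
  expect_equal(m2$pooled, 0.410, tolerance = 0.002)
  expect_equal(m2$se, 0.096, tolerance = 0.005)
  expect_lte(m2$se, min(c(0.16, 0.16, 0.18)))
  # single study is the identity
  m1 <- fixed_effects_meta(0.4, 0.1)
  expect_equal(m1$pooled, 0.4)
  expect_equal(m1$se, 0.1)
  expect_error(fixed_effects_meta(c(1, 2), 0.5), "equal length")
  expect_error(fixed_effects_meta(1, 0), "positive")
})

test_that("meta-analysis agrees with an established implementation", {
  library(metafor)
  set.seed(3)
  est <- rnorm(5)
  se <- runif(5, 0.05, 0.3)
  mine <- fixed_effects_meta(est, se)
  ref <- metafor::rma(yi = est, sei = se, method = "FE")
  expect_equal(mine$pooled, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$se, as.numeric(ref$se), tolerance = 1e-10)
})

test_that("percent of total heritability matches the published-style value", {
  mc <- fixed_effects_meta(c(0.38, 0.33, 0.55), c(0.16, 0.16, 0.18))
  mt <- fixed_effects_meta(c(7.53, 7.92, 9.40), c(0.79, 0.78, 0.81))
  expect_equal(percent_total(mc, mt), 4.96, tolerance = 0.05)
  expect_equal(percent_total(mt, mt), 100)
  expect_equal(percent_total(0, mt), 0)
})

test_that("GREML power calculation follows the noncentral chi-square form", {
  pw <- greml_power(41263, 6.68e-4, 1 / 300, alpha = 0.05)
  expect_equal(pw$se_h2, 1.33e-3, tolerance = 0.005)
  expect_gte(pw$power, 0.70)
  # null heritability gives power equal to the test size
  expect_equal(greml_power(1000, 1e-3, 0)$power, 0.05, tolerance = 1e-10)
  expect_error(greml_power(1, 1e-3, 0.1), "n >= 2")
  expect_error(greml_power(100, 0, 0.1), "positive")
})

test_that("quartile split balances subsets by construction", {
  y <- qnorm((1:12) / 13)
  s <- quartile_split(y, 3, seed = 5)
  expect_equal(unname(table(s)), rep(4L, 3), ignore_attr = TRUE)
  quart <- cut(y, quantile(y, 0:4 / 4), include.lowest = TRUE)
  comp <- table(quart, s)
  expect_true(all(comp == 1))
  expect_identical(s, quartile_split(y, 3, seed = 5))
})

test_that("split subsets are distributionally equivalent to the pool", {
  set.seed(9)
  y <- rnorm(4000)
  ok <- 0
  for (seed in 1:20) {
    s <- quartile_split(y, 3, seed = seed)
    ps <- sapply(1:3, function(k)
      suppressWarnings(ks.test(y[s == k], y)$p.value))
    if (all(ps > 0.05)) ok <- ok + 1
    sizes <- table(s)
    expect_lte(max(sizes) - min(sizes), 3)
  }
  expect_gte(ok, 18)
})

test_that("enrichment_table summarises per-subset fits coherently", {
  fits <- lapply(1:3, function(s) {
    co <- quick_cohort(seed = 70 + s, n = 200, m = 600, h2_coding = 0.02,
                       h2_buffer = 0.1, h2_rest = 0.1)
    lab <- co$assignment$labels
    grms <- lapply(levels(lab), function(k)
      compute_grm(co$panel, snps = lab == k))
    fit_greml(co$phenotype, grms, X = covar_design(co$covariates))
  })
  co <- quick_cohort(seed = 71, n = 200, m = 600)
  m_k <- c(coding = unname(co$assignment$counts[["coding"]]),
           buffer = unname(co$assignment$counts[["buffer"]]),
           rest = unname(co$assignment$counts[["rest"]]))
  tab <- enrichment_table(fits, m_k)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$component, c("coding", "buffer", "rest", "total"))
  expect_equal(tab$meta_enrichment[4], 1)
  expect_equal(tab$pct_total[4], 100)
  # component percentages sum near (not exactly) 100: each component is
  # pooled with its own inverse-variance weights
  expect_gt(sum(tab$pct_total[1:3]), 85)
  expect_lt(sum(tab$pct_total[1:3]), 115)
})
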