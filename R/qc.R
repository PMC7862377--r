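#' Marker QC thresholds
#'
#' Defaults follow common array-QC practice for the pipeline's intended
#' inputs: per-sample call rate >= 0.99, MAF >= 0.01, Hardy-Weinberg exact
#' p >= 1e-4, per-SNP missing rate <= 0.10.
#'
#' @param min_maf,min_hwe_p,max_snp_missing,min_sample_callrate fractions in
#'   \[0, 1\].
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.01, min_hwe_p = 1e-4,
                          max_snp_missing = 0.10,
                          min_sample_callrate = 0.99) {
  v <- c(min_maf, min_hwe_p, max_snp_missing, min_sample_callrate)
  if (any(v < 0 | v > 1)) stop("all thresholds must lie in [0, 1]")
  structure(list(min_maf = min_maf, min_hwe_p = min_hwe_p,
                 max_snp_missing = max_snp_missing,
                 min_sample_callrate = min_sample_callrate),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' probability of every heterozygote count no more probable than the
#' observed one is summed. Monomorphic sites return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative; positive sum).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (min(n_AA, n_Aa, n_aa) < 0) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("undefined input: all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n_aa + n_Aa
  if (nA == 0 || nB == 0) return(1)
  h <- hwe_het_support(nA, nB)
  # log P(n_Aa = h | n, nA) up to a common constant
  lp <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((nB - h) / 2)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# feasible heterozygote counts given allele counts (parity-constrained)
hwe_het_support <- function(nA, nB) {
  h_max <- min(nA, nB)
  h_min <- h_max %% 2
  seq.int(h_min, h_max, by = 2)
}

#' Filter a genotype panel on marker and sample QC criteria
#'
#' Samples with call rate below `min_sample_callrate` are removed first;
#' SNPs are then removed, in order, for low minor allele frequency,
#' Hardy-Weinberg disequilibrium, and missingness, each SNP counted once
#' under the first criterion it fails.
#'
#' @param panel a [genotype_panel()].
#' @param thr a [qc_thresholds()].
#' @return list with the filtered `panel` and a `report` of removal counts
#'   (`samples_removed`, `maf_removed`, `hwe_removed`, `missing_removed`).
#' @export
qc_filter <- function(panel, thr = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(thr, "qc_thresholds"))
  callrate <- rowMeans(!is.na(panel$dosages))
  keep_s <- callrate >= thr$min_sample_callrate
  n_sample_rm <- sum(!keep_s)
  if (!any(keep_s)) stop("QC removed every sample")
  if (n_sample_rm > 0) panel <- subset_panel(panel, samples = keep_s)

  x <- panel$dosages
  maf_raw <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(maf_raw, 1 - maf_raw)
  maf[is.nan(maf)] <- 0
  fail_maf <- maf < thr$min_maf

  hwe_p <- vapply(seq_len(ncol(x)), function(j) {
    d <- x[, j]
    hwe_exact_test(sum(d == 2, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                   sum(d == 0, na.rm = TRUE))
  }, numeric(1))
  fail_hwe <- hwe_p < thr$min_hwe_p & !fail_maf

  miss <- colMeans(is.na(x))
  fail_miss <- miss > thr$max_snp_missing & !fail_maf & !fail_hwe

  keep <- !(fail_maf | fail_hwe | fail_miss)
  if (!any(keep)) stop("QC removed every SNP")
  report <- list(samples_removed = n_sample_rm,
                 maf_removed = sum(fail_maf),
                 hwe_removed = sum(fail_hwe),
                 missing_removed = sum(fail_miss),
                 snps_kept = sum(keep))
  list(panel = subset_panel(panel, snps = keep), report = report)
}
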