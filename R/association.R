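#' Mixed-linear-model association with leave-one-chromosome-out GRMs
#'
#' For each chromosome, a single-GRM GREML fit on the relatedness matrix
#' built from all *other* chromosomes supplies `V = sigma2_g A_loco +
#' sigma2_e I`; each SNP on the chromosome is then tested by generalized
#' least squares with the covariates projected out:
#' `b = (w' P y) / (w' P w)`, `chi2_1 = b^2 (w' P w)`. Excluding the tested
#' SNP's chromosome from the GRM avoids proximal contamination. With a
#' single chromosome the function falls back to a plain mixed model (GRM
#' from all SNPs) with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param y phenotype vector.
#' @param X optional covariate matrix (intercept added). Variance
#'   components are re-estimated once per left-out chromosome.
#' @return data.frame of class `gwas_results`: id, chrom, pos, a1, beta,
#'   se, p, n (beta on the 0..2 dosage scale for allele1).
#' @export
mlma_loco <- function(panel, y, X = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$sample_ids)
  stopifnot(length(y) == n)
  if (is.null(X)) X <- matrix(1, n, 1) else {
    X <- as.matrix(X)
    if (!any(apply(X, 2, function(c) stats::sd(c) == 0 && c[1] != 0)))
      X <- cbind(1, X)
  }
  chroms <- unique(panel$snp_meta$chrom)
  loco <- length(chroms) >= 2
  if (!loco)
    warning("single chromosome: falling back to a plain mixed model ",
            "(no leave-one-chromosome-out)")

  per_chrom <- lapply(chroms, function(ch)
    compute_grm(panel, snps = panel$snp_meta$chrom == ch))
  msum <- sum(vapply(per_chrom, `[[`, 0, "m_snps"))
  Asum <- Reduce(`+`, lapply(per_chrom, function(g) g$matrix * g$m_snps))

  res <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    if (loco) {
      mc <- per_chrom[[i]]$m_snps
      A <- (Asum - per_chrom[[i]]$matrix * mc) / (msum - mc)
    } else {
      A <- Asum / msum
    }
    fit <- fit_greml(y, list(A), X = X)
    V <- fit$sigma2[1] * A + diag(rep(fit$sigma2[2], n))
    Vinv <- chol2inv(chol(V))
    VinvX <- Vinv %*% X
    P <- Vinv - VinvX %*% solve(crossprod(X, VinvX)) %*% t(VinvX)
    Py <- drop(P %*% y)

    on_ch <- which(panel$snp_meta$chrom == ch)
    W <- panel$dosages[, on_ch, drop = FALSE]
    # mean-impute missing calls
    if (anyNA(W)) {
      mu <- colMeans(W, na.rm = TRUE)
      idx <- which(is.na(W), arr.ind = TRUE)
      W[idx] <- mu[idx[, 2]]
    }
    wPw <- colSums(W * (P %*% W))
    wPy <- drop(crossprod(W, Py))
    beta <- wPy / wPw
    se <- 1 / sqrt(wPw)
    chi2 <- beta^2 * wPw
    res[[i]] <- data.frame(id = panel$snp_meta$id[on_ch], chrom = ch,
                           pos = panel$snp_meta$pos_bp[on_ch],
                           a1 = panel$snp_meta$allele1[on_ch],
                           beta = beta, se = se,
                           p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                           n = n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[match(panel$snp_meta$id, out$id), ]
  rownames(out) <- NULL
  attr(out, "loco") <- loco
  class(out) <- c("gwas_results", "data.frame")
  out
}

#' Gene-level association by Bonferroni-adjusted minimum SNP p
#'
#' A deliberately simple gene-based aggregate: each gene's p-value is
#' `min(1, n_snps_in_window * min SNP p)` over SNPs within `window_kb`
#' kilobases of the gene body. Genes containing no SNPs are omitted (and
#' reported via a message). This is a stand-in for full multi-marker gene
#' tests and is labeled as such in the output attributes.
#'
#' @param gwas a `gwas_results` data.frame (see [mlma_loco()]).
#' @param genes gene annotation data.frame (symbol, chrom, start_bp,
#'   stop_bp).
#' @param window_kb symmetric window around the gene body (default 10).
#' @return data.frame of class `gene_stats`: symbol, n_snps, p, p_adj
#'   (BH-FDR across the tested genes).
#' @export
gene_minp <- function(gwas, genes, window_kb = 10) {
  w <- window_kb * 1000
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    hit <- gwas$chrom == g$chrom & gwas$pos >= g$start_bp - w &
      gwas$pos <= g$stop_bp + w
    k <- sum(hit)
    if (k == 0) return(NULL)
    data.frame(symbol = g$symbol, n_snps = k,
               p = min(1, k * min(gwas$p[hit])), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    message(dropped, " gene(s) with no SNPs in window omitted")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene contains any SNP within the window")
  out$p_adj <- bh_fdr(out$p)
  rownames(out) <- NULL
  attr(out, "method") <- "bonferroni-min-p (multi-marker gene test stand-in)"
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, preserving
#' input order.
#'
#' @param pvals numeric p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}
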