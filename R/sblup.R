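#' SBLUP shrinkage configuration
#'
#' The summary-based BLUP shrinkage parameter is
#' `lambda = m_total * (1 / h2_snp - 1)`: the implied per-SNP
#' noise-to-signal ratio of an infinitesimal model with total
#' SNP-heritability `h2_snp` spread over `m_total` markers.
#'
#' @param h2_snp total SNP-heritability of the training GWAS trait, in
#'   (0, 1).
#' @param m_total total number of SNPs.
#' @param ld_window_kb LD window (kb) beyond which reference correlations
#'   are zeroed (default 1000).
#' @param ld_ridge small ridge added to the reference correlation diagonal
#'   (default 0.01).
#' @return object of class `sblup_config` with the derived `lambda`.
#' @export
sblup_config <- function(h2_snp, m_total, ld_window_kb = 1000,
                         ld_ridge = 0.01) {
  if (h2_snp <= 0 || h2_snp >= 1) stop("h2_snp must lie in (0, 1)")
  if (m_total <= 0) stop("m_total must be positive")
  structure(list(h2_snp = h2_snp, m_total = m_total,
                 lambda = m_total * (1 / h2_snp - 1),
                 ld_window_kb = ld_window_kb, ld_ridge = ld_ridge),
            class = "sblup_config")
}

#' Windowed LD correlation blocks from a reference panel
#'
#' Per chromosome, the Pearson correlation matrix of the (mean-imputed)
#' reference dosages with entries beyond `window_kb` kilobases set to
#' zero, unit diagonal, and `ridge` added to the diagonal.
#'
#' @param reference a [genotype_panel()] of reference samples.
#' @param window_kb window width in kb.
#' @param ridge diagonal ridge.
#' @return object of class `ld_blocks`: list of per-chromosome blocks,
#'   each with `chrom`, `ids`, `R`.
#' @export
ld_blocks <- function(reference, window_kb = 1000, ridge = 0.01) {
  stopifnot(inherits(reference, "genotype_panel"))
  x <- reference$dosages
  if (anyNA(x)) {  # mean-impute missing reference calls
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  blocks <- lapply(unique(reference$snp_meta$chrom), function(ch) {
    on_ch <- reference$snp_meta$chrom == ch
    R <- suppressWarnings(stats::cor(x[, on_ch, drop = FALSE]))
    R[is.na(R)] <- 0  # monomorphic reference SNPs carry no LD information
    pos <- reference$snp_meta$pos_bp[on_ch]
    far <- abs(outer(pos, pos, `-`)) > window_kb * 1000
    R[far] <- 0
    diag(R) <- 1 + ridge
    list(chrom = ch, ids = reference$snp_meta$id[on_ch], R = R)
  })
  structure(blocks, class = "ld_blocks")
}

#' Summary-based BLUP adjustment of marginal GWAS effects
#'
#' Solves, per LD block, `(n R + lambda I) u = n beta_hat` where
#' `beta_hat` are marginal effects on the standardized-genotype scale, `R`
#' the (ridged) reference LD, `n` the GWAS sample size and `lambda` the
#' shrinkage from [sblup_config()]. The solutions `u` are jointly shrunken
#' effects suitable for polygenic scoring.
#'
#' @param betas named numeric vector of standardized marginal effects
#'   (names = SNP ids covering every LD-block SNP).
#' @param ld an [ld_blocks()] object.
#' @param n_gwas GWAS sample size.
#' @param cfg an [sblup_config()].
#' @return named numeric vector of adjusted effects (LD-block SNP order).
#' @export
sblup_adjust <- function(betas, ld, n_gwas, cfg) {
  stopifnot(inherits(ld, "ld_blocks"), inherits(cfg, "sblup_config"))
  out <- lapply(ld, function(blk) {
    idx <- match(blk$ids, names(betas))
    if (anyNA(idx))
      stop("betas missing for SNPs of LD block on chromosome ", blk$chrom)
    M <- n_gwas * blk$R + diag(cfg$lambda, length(idx))
    u <- tryCatch(solve(M, n_gwas * betas[idx]),
                  error = function(e)
                    stop("SBLUP solve failed for LD block on chromosome ",
                         blk$chrom, ": ", conditionMessage(e)))
    stats::setNames(drop(u), blk$ids)
  })
  unlist(out)
}

#' Standardize GWAS effects
#'
#' Converts allele-dosage-scale effects to the standardized-genotype scale:
#' `beta_std = beta * sqrt(2 p (1 - p))`.
#'
#' @param beta effects on the 0..2 dosage scale.
#' @param freq effect-allele frequencies.
#' @return standardized effects.
#' @export
standardize_effects <- function(beta, freq) {
  beta * sqrt(2 * freq * (1 - freq))
}

#' Polygenic score on standardized dosages
#'
#' `score_j = sum_i u_i z_ij` over the requested SNP subset, with missing
#' dosages mean-imputed by the standardization.
#'
#' @param panel target [genotype_panel()].
#' @param effects named numeric vector of (adjusted) standardized effects.
#' @param snps optional SNP subset (indices, logical, or ids); default all
#'   SNPs with an effect.
#' @return named numeric vector of per-sample scores.
#' @export
pgs_score <- function(panel, effects, snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  ids <- if (is.null(snps)) intersect(panel$snp_meta$id, names(effects))
         else panel$snp_meta$id[resolve_index(snps, panel$snp_meta$id, "SNP")]
  u <- effects[ids]
  if (anyNA(u)) stop("effects missing for requested SNPs")
  Z <- standardize_dosages(subset_panel(panel, snps = ids))
  stats::setNames(drop(Z %*% u), panel$sample_ids)
}

#' Association of polygenic scores with a phenotype
#'
#' Ordinary least squares of the phenotype on each score plus covariates
#' (canonically the leading principal components); reports the score
#' coefficient, its SE and p-value, and the incremental R-squared over the
#' covariate-only model.
#'
#' @param scores numeric vector or matrix (one column per partition score).
#' @param phenotype numeric vector.
#' @param covariates covariate matrix/data.frame (intercept added); must be
#'   full rank.
#' @return data.frame of class `pgs_result`: partition, beta, se, p,
#'   r2_incremental.
#' @export
pgs_association <- function(scores, phenotype, covariates = NULL) {
  S <- as.matrix(scores)
  if (is.null(colnames(S)))
    colnames(S) <- if (ncol(S) == 1) "score" else paste0("score", seq_len(ncol(S)))
  n <- length(phenotype)
  C <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, as.matrix(covariates))
  if (qr(C)$rank < ncol(C))
    stop("covariate matrix is rank deficient (duplicated columns?)")
  fit0 <- stats::lm.fit(C, phenotype)
  rss0 <- sum(fit0$residuals^2)
  tss <- sum((phenotype - mean(phenotype))^2)
  rows <- lapply(colnames(S), function(nm) {
    D <- cbind(S[, nm], C)
    fit <- stats::lm.fit(D, phenotype)
    rss <- sum(fit$residuals^2)
    df <- n - ncol(D)
    sigma2 <- rss / df
    xtx_inv <- chol2inv(chol(crossprod(D)))
    se <- sqrt(sigma2 * xtx_inv[1, 1])
    tval <- fit$coefficients[1] / se
    data.frame(partition = nm, beta = unname(fit$coefficients[1]), se = se,
               p = 2 * stats::pt(-abs(tval), df),
               r2_incremental = (rss0 - rss) / tss,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pgs_result", "data.frame")
  out
}
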