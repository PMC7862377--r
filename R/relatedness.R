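#' Compute a genomic relatedness matrix
#'
#' GCTA-style GRM on standardized dosages:
#' `A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the sample allele frequency and missing calls mean-imputed.
#' Monomorphic SNPs are dropped before averaging.
#'
#' @param panel a [genotype_panel()].
#' @param snps optional SNP subset (indices, logical mask, or ids).
#' @return object of class `grm`: list(matrix, sample_ids, m_snps).
#' @export
compute_grm <- function(panel, snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  vi <- resolve_index(snps, panel$snp_meta$id, "SNP")
  if (length(vi) == 0) stop("SNP subset is empty")
  x <- panel$dosages[, vi, drop = FALSE]
  p <- colMeans(x, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.nan(p)
  if (!any(poly)) stop("SNP subset contains only monomorphic SNPs")
  Z <- standardize_dosages(x[, poly, drop = FALSE], freq = p[poly])
  m <- sum(poly)
  structure(list(matrix = tcrossprod(Z) / m, sample_ids = panel$sample_ids,
                 m_snps = m),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$matrix), "samples,", x$m_snps, "SNPs; mean diagonal",
      sprintf("%.4f", mean(diag(x$matrix))), "\n")
  invisible(x)
}

#' Variance of the off-diagonal GRM elements
#'
#' Unbiased sample variance over the n(n-1)/2 distinct off-diagonal
#' entries — the quantity that drives GREML power.
#'
#' @param grm a `grm` object or a square symmetric matrix.
#' @return scalar variance.
#' @export
offdiag_variance <- function(grm) {
  A <- if (inherits(grm, "grm")) grm$matrix else grm
  if (nrow(A) < 2) stop("need at least 2 samples")
  stats::var(A[lower.tri(A)])
}

#' Greedy relatedness pruning
#'
#' Repeatedly considers the most related remaining pair above `cutoff` and
#' drops its member involved in more above-cutoff pairs (ties: the
#' later-ordered sample), until no pair exceeds the cutoff. A cutoff of
#' 0.05 approximately excludes relationships closer than second cousins.
#'
#' @param grm a `grm` object.
#' @param cutoff positive relatedness threshold (default 0.05).
#' @return character vector of retained sample ids.
#' @export
relatedness_prune <- function(grm, cutoff = 0.05) {
  stopifnot(inherits(grm, "grm"), cutoff > 0)
  A <- grm$matrix
  diag(A) <- 0
  alive <- rep(TRUE, nrow(A))
  repeat {
    B <- abs(A[alive, alive, drop = FALSE])
    over <- B > cutoff
    if (!any(over)) break
    if (sum(alive) == 1) break
    deg <- rowSums(over)
    worst <- which(B == max(B), arr.ind = TRUE)[1, ]
    cand <- c(worst[["row"]], worst[["col"]])
    # most over-cutoff pairs wins; ties broken toward the later id
    drop_local <- if (deg[cand[1]] > deg[cand[2]]) cand[1]
                  else if (deg[cand[2]] > deg[cand[1]]) cand[2]
                  else max(cand)
    alive[which(alive)[drop_local]] <- FALSE
  }
  if (sum(alive) == 1)
    warning("relatedness pruning left a single sample")
  grm$sample_ids[alive]
}

#' Leading principal components of the genotype matrix
#'
#' Left singular directions of the standardized dosage matrix, scaled by
#' their singular values (i.e. PC scores). Sign convention: within each
#' component the SNP loading of largest magnitude is positive.
#'
#' @param panel a [genotype_panel()].
#' @param k number of components (k = 0 returns an n x 0 matrix).
#' @return n x k matrix of scores.
#' @export
top_pcs <- function(panel, k) {
  stopifnot(inherits(panel, "genotype_panel"), k >= 0)
  n <- length(panel$sample_ids)
  if (k == 0) return(matrix(0, n, 0))
  Z <- standardize_dosages(panel)
  sv <- svd(Z, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(k)] * flip, k, k)
  rownames(scores) <- panel$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' m-weighted combination of GRMs over disjoint SNP sets
#'
#' For GRMs built from disjoint SNP subsets with the same samples, the GRM
#' of the union equals the SNP-count-weighted average — used to assemble
#' leave-one-chromosome-out matrices cheaply.
#'
#' @param grms list of `grm` objects sharing sample ids.
#' @return a `grm` over the union of the SNP sets.
#' @export
combine_grms <- function(grms) {
  stopifnot(length(grms) >= 1)
  m <- vapply(grms, `[[`, numeric(1), "m_snps")
  A <- Reduce(`+`, lapply(grms, function(g) g$matrix * g$m_snps)) / sum(m)
  structure(list(matrix = A, sample_ids = grms[[1]]$sample_ids,
                 m_snps = as.integer(sum(m))),
            class = "grm")
}
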