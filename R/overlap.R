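#' Jaccard similarity of two gene sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 0 by convention.
#'
#' @param set_a,set_b character vectors of gene symbols.
#' @return fraction in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Fisher exact test of gene-set overlap against a background
#'
#' Builds the 2x2 table (both / geneset-only / associated-only / neither)
#' over a homolog background and reports the sample odds ratio
#' `(a d)/(b c)` as the headline statistic, the two-sided exact p-value
#' (summing hypergeometric probabilities of tables no more probable than
#' the observed one), and the exact conditional confidence interval and
#' conditional-MLE odds ratio.
#'
#' @param geneset,assoc_genes character vectors of symbols, both subsets of
#'   `background`.
#' @param background character vector: the universe of genes.
#' @param conf_level confidence level for the exact CI (default 0.95).
#' @return object of class `overlap_result`: table (a, b, c, d),
#'   or_sample, or_cmle, p, conf_int.
#' @export
fisher_overlap <- function(geneset, assoc_genes, background,
                           conf_level = 0.95) {
  bg <- unique(background)
  g <- unique(geneset); s <- unique(assoc_genes)
  if (!all(g %in% bg) || !all(s %in% bg))
    stop("geneset and assoc_genes must be subsets of the background")
  a <- length(intersect(g, s))
  b <- length(setdiff(g, s))
  cc <- length(setdiff(s, g))
  d <- length(bg) - a - b - cc
  res <- fisher_overlap_counts(a, b, cc, d, conf_level = conf_level)
  res
}

#' @rdname fisher_overlap
#' @param a,b,c,d the 2x2 table counts directly (both, geneset-only,
#'   associated-only, neither).
#' @export
fisher_overlap_counts <- function(a, b, c, d, conf_level = 0.95) {
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (min(tab) < 0) stop("table counts must be non-negative")
  or_sample <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)

  # two-sided exact p: hypergeometric over tables with the observed margins
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  dens <- stats::dhyper(lo:hi, m1, m2, k)
  p <- min(1, sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-7)]))

  ft <- stats::fisher.test(tab, conf.level = conf_level)
  structure(list(table = c(a = a, b = b, c = c, d = d),
                 background = a + b + c + d,
                 or_sample = or_sample,
                 or_cmle = unname(ft$estimate),
                 p = p, conf_int = as.numeric(ft$conf.int)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: OR = %.2f (sample), %.2f (conditional MLE), p = %.4g, %s%% CI [%.2f, %.2f]\n",
    x$or_sample, x$or_cmle, x$p, "95", x$conf_int[1], x$conf_int[2]))
  cat("  table (both / set-only / assoc-only / neither):",
      paste(x$table, collapse = " / "), "\n")
  invisible(x)
}

#' Permutation test of gene-set association signal
#'
#' Tests whether a gene set carries more gene-level association signal
#' (mean -log10 p over its genes present in `gene_stats`) than random gene
#' sets of the same size drawn from the tested genes.
#'
#' @param geneset character vector of symbols.
#' @param gene_stats a `gene_stats` data.frame (see [gene_minp()]).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list(statistic, p, n_genes_used, null) with
#'   `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#' @export
permutation_signal_test <- function(geneset, gene_stats, n_perm = 1000,
                                    seed = 1L) {
  set.seed(seed)
  present <- gene_stats$symbol %in% geneset
  k <- sum(present)
  if (k == 0) stop("no gene-set gene present in gene_stats")
  score <- -log10(gene_stats$p)
  obs <- mean(score[present])
  null <- vapply(seq_len(n_perm), function(i)
    mean(score[sample.int(length(score), k)]), numeric(1))
  list(statistic = obs, p = (1 + sum(null >= obs)) / (n_perm + 1),
       n_genes_used = k, null = null)
}

#' Rank-sum comparison of association signal between two gene groups
#'
#' Two-sided Wilcoxon rank-sum test on -log10 gene p-values of two disjoint
#' gene groups (e.g. genes from two source species).
#'
#' @param set_a,set_b character vectors of symbols.
#' @param gene_stats a `gene_stats` data.frame.
#' @return list(statistic, p).
#' @export
signal_ranksum <- function(set_a, set_b, gene_stats) {
  sa <- -log10(gene_stats$p[gene_stats$symbol %in% set_a])
  sb <- -log10(gene_stats$p[gene_stats$symbol %in% set_b])
  if (!length(sa) || !length(sb)) stop("both groups need tested genes")
  wt <- stats::wilcox.test(sa, sb, exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
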