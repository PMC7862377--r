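#' Genotype panel
#'
#' The central container of the package: a sample-by-SNP matrix of allele
#' dosages (counts of `allele1`, so values 0/1/2 with `NA` for missing calls)
#' together with per-SNP metadata and sample identifiers. This mirrors the
#' information content of a PLINK BED/BIM/FAM fileset.
#'
#' @param dosages integer/numeric matrix, samples in rows, SNPs in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param snp_meta data.frame with columns `id`, `chrom`, `pos_bp` (1-based),
#'   `allele1`, `allele2`. Positions must be strictly increasing within each
#'   chromosome and SNP ids unique.
#' @param sample_ids character vector, one id per row of `dosages`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, snp_meta, sample_ids) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(sample_ids))
    stop("dosages has ", nrow(dosages), " rows but ", length(sample_ids),
         " sample ids")
  if (ncol(dosages) != nrow(snp_meta))
    stop("dosages has ", ncol(dosages), " columns but snp_meta has ",
         nrow(snp_meta), " rows")
  req <- c("id", "chrom", "pos_bp", "allele1", "allele2")
  if (!all(req %in% names(snp_meta)))
    stop("snp_meta must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(snp_meta$id))
    stop("SNP ids are not unique")
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos_bp[snp_meta$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("dosages must lie in {0, 1, 2} or be NA")
  dimnames(dosages) <- list(sample_ids, snp_meta$id)
  structure(list(dosages = dosages,
                 snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "samples x",
      nrow(x$snp_meta), "SNPs on",
      length(unique(x$snp_meta$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param samples sample indices, logical mask, or ids (default: keep all).
#' @param snps SNP indices, logical mask, or ids (default: keep all).
#' @return a `genotype_panel` restricted to the requested rows/columns.
#' @export
subset_panel <- function(panel, samples = NULL, snps = NULL) {
  si <- resolve_index(samples, panel$sample_ids, "sample")
  vi <- resolve_index(snps, panel$snp_meta$id, "SNP")
  genotype_panel(panel$dosages[si, vi, drop = FALSE],
                 panel$snp_meta[vi, , drop = FALSE],
                 panel$sample_ids[si])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.logical(idx)) {
    if (length(idx) != length(ids))
      stop("logical ", what, " index has wrong length")
    return(which(idx))
  }
  if (is.character(idx)) {
    m <- match(idx, ids)
    if (anyNA(m)) stop("unknown ", what, " id(s): ",
                       paste(utils::head(idx[is.na(m)], 3), collapse = ", "))
    return(m)
  }
  as.integer(idx)
}

#' Per-SNP allele frequency of allele1
#'
#' Computed on non-missing calls; `NaN` for SNPs with no calls.
#' @param panel a [genotype_panel()] or dosage matrix.
#' @return numeric vector of length n_snps.
#' @export
allele_freq <- function(panel) {
  x <- if (inherits(panel, "genotype_panel")) panel$dosages else panel
  colMeans(x, na.rm = TRUE) / 2
}

#' Standardize dosages
#'
#' Centers each SNP at twice its allele frequency and scales by
#' `sqrt(2 p (1 - p))`; missing calls are mean-imputed (zero after
#' centering), the single convention used by the GRM, association and
#' scoring stages.
#'
#' @param panel a [genotype_panel()] or dosage matrix.
#' @param freq optional externally supplied allele frequencies.
#' @return numeric matrix of standardized dosages.
#' @export
standardize_dosages <- function(panel, freq = NULL) {
  x <- if (inherits(panel, "genotype_panel")) panel$dosages else panel
  p <- if (is.null(freq)) colMeans(x, na.rm = TRUE) / 2 else freq
  s <- sqrt(2 * p * (1 - p))
  z <- sweep(x, 2L, 2 * p, `-`)
  z <- sweep(z, 2L, s, `/`)
  z[is.na(z) | is.infinite(z)] <- 0
  z
}
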