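#' SNP partition assignment
#'
#' Exclusive assignment of every SNP of a panel to one of the three
#' variance-partitioning categories: `coding` (inside a gene-set gene body),
#' `buffer` (within the flanking window of a gene-set gene but not coding),
#' `rest` (everything else).
#'
#' @param labels factor/character vector over SNPs with levels
#'   coding/buffer/rest.
#' @param buffer_kb the buffer width the labels were built with.
#' @param snp_ids SNP identifiers, parallel to `labels`.
#' @return object of class `snp_assignment` with a `counts` element.
#' @export
snp_assignment <- function(labels, buffer_kb, snp_ids) {
  labels <- factor(labels, levels = c("coding", "buffer", "rest"))
  if (anyNA(labels)) stop("labels must be coding/buffer/rest")
  structure(list(labels = labels, buffer_kb = buffer_kb,
                 snp_ids = snp_ids,
                 counts = table(labels)),
            class = "snp_assignment")
}

#' @export
print.snp_assignment <- function(x, ...) {
  cat("snp_assignment (buffer ", x$buffer_kb, " kb): ", sep = "")
  cat(paste(names(x$counts), as.integer(x$counts), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Partition SNPs by a gene set and flanking buffer
#'
#' A SNP inside any gene-set gene body (`start_bp`..`stop_bp`, inclusive) is
#' `coding`; otherwise, a SNP within `buffer_kb` kilobases of a gene-set
#' gene's start or stop is `buffer`; all remaining SNPs are `rest`.
#' Genes not flagged `in_geneset` do not define regions. Overlapping
#' gene-set intervals are merged before labeling, buffers are clipped at
#' position 1 and never extend across chromosomes, and coding status takes
#' precedence when regions of different genes overlap.
#'
#' @param genes data.frame with columns symbol, chrom, start_bp, stop_bp,
#'   in_geneset (see [simulate_gene_annotation()] / [read_genes()]).
#' @param panel a [genotype_panel()].
#' @param buffer_kb non-negative buffer width in kilobases.
#' @return a [snp_assignment()].
#' @export
build_partition <- function(genes, panel, buffer_kb) {
  stopifnot(inherits(panel, "genotype_panel"), buffer_kb >= 0)
  gs <- genes[genes$in_geneset, , drop = FALSE]
  if (nrow(gs) == 0) stop("gene set is empty")
  if (any(gs$start_bp > gs$stop_bp)) stop("gene with start_bp > stop_bp")
  unknown <- !gs$chrom %in% unique(panel$snp_meta$chrom)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " gene-set gene(s) on chromosomes ",
            "absent from the panel: ",
            paste(utils::head(gs$symbol[unknown], 5), collapse = ", "))
    gs <- gs[!unknown, , drop = FALSE]
  }
  if (nrow(gs) == 0) stop("gene set is empty after chromosome filtering")

  w <- buffer_kb * 1000
  labels <- rep("rest", nrow(panel$snp_meta))
  for (ch in unique(gs$chrom)) {
    on_ch <- panel$snp_meta$chrom == ch
    if (!any(on_ch)) next
    pos <- panel$snp_meta$pos_bp[on_ch]
    g <- gs[gs$chrom == ch, , drop = FALSE]
    coding <- in_merged_intervals(pos, g$start_bp, g$stop_bp)
    wide <- in_merged_intervals(pos, pmax(1, g$start_bp - w), g$stop_bp + w)
    lab <- ifelse(coding, "coding", ifelse(wide, "buffer", "rest"))
    labels[on_ch] <- lab
  }
  snp_assignment(labels, buffer_kb, panel$snp_meta$id)
}

# membership of positions in the union of [start, stop] intervals,
# via merged sorted intervals and findInterval
in_merged_intervals <- function(pos, starts, stops) {
  o <- order(starts)
  starts <- starts[o]; stops <- stops[o]
  ms <- starts[1]; me <- stops[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(starts) > 1) for (i in 2:length(starts)) {
    if (starts[i] <= me + 1) me <- max(me, stops[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- starts[i]; me <- stops[i] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  k <- findInterval(pos, out_s)
  k > 0 & pos <= out_e[pmax(k, 1)]
}

#' Read a gene annotation table / a gene list
#'
#' `read_genes` reads a tab- or whitespace-delimited table with columns
#' symbol, chrom, start, stop (header optional, detected); `read_geneset`
#' reads a plain list, one gene symbol per line, and flags the annotation.
#'
#' @param path file path.
#' @param geneset optional character vector of symbols to flag
#'   `in_geneset`.
#' @return data.frame with columns symbol, chrom, start_bp, stop_bp,
#'   in_geneset.
#' @export
read_genes <- function(path, geneset = NULL) {
  first <- readLines(path, n = 1)
  has_header <- grepl("symbol", first, ignore.case = TRUE)
  d <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  names(d)[1:4] <- c("symbol", "chrom", "start_bp", "stop_bp")
  d$in_geneset <- if (is.null(geneset)) FALSE else d$symbol %in% geneset
  d[, c("symbol", "chrom", "start_bp", "stop_bp", "in_geneset")]
}

#' @rdname read_genes
#' @export
read_geneset <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
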