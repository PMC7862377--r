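#' Simulation configuration
#'
#' Parameters for the synthetic cohort generator. Defaults emulate the study
#' conditions the pipeline was designed for: a quantitative consumption-like
#' trait with total additive SNP-heritability around 8-10%, part of it
#' concentrated in and around a designated gene set, block-structured LD,
#' and sex/age/age-squared/site covariates.
#'
#' @param n_samples,n_snps,n_chromosomes cohort dimensions. `n_snps` must be
#'   divisible by `block_size_snps`.
#' @param block_size_snps SNPs per LD block; blocks never span chromosomes.
#' @param within_block_corr target correlation between adjacent SNPs inside
#'   a block, in \[0, 1). Achieved by a copy-or-refresh haplotype mosaic:
#'   each haplotype allele copies its left neighbour with this probability,
#'   otherwise is drawn fresh at the block allele frequency, so the
#'   adjacent-SNP genotype correlation equals the parameter in expectation
#'   and decays geometrically with distance inside the block.
#' @param maf_range block minor-allele frequencies are drawn uniformly from
#'   this interval; lower bound must be > 0.
#' @param n_genes,gene_length_bp,snp_spacing_bp annotation geometry.
#' @param n_geneset_genes how many genes are flagged as the a-priori
#'   ("model organism") gene set.
#' @param h2_coding,h2_buffer,h2_rest target per-partition heritability
#'   fractions; their sum must be < 1.
#' @param buffer_kb_truth buffer width (kb) used to define the true causal
#'   partition.
#' @param causal_fraction fraction of each partition's SNPs that are causal
#'   when its target h2 is positive.
#' @param covariate_effects named coefficients applied to standardized
#'   covariate columns (names among sex, age, age2, site).
#' @param exact_rescale rescale each partition's genetic values so realized
#'   in-sample variances hit the targets exactly (default); `FALSE` gives
#'   pure expectation mode.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000, n_snps = 5000, n_chromosomes = 5,
                       block_size_snps = 25, within_block_corr = 0.6,
                       maf_range = c(0.05, 0.5),
                       n_genes = 100, gene_length_bp = 10000,
                       snp_spacing_bp = 2500, n_geneset_genes = 20,
                       h2_coding = 0.005, h2_buffer = 0.03, h2_rest = 0.05,
                       buffer_kb_truth = 10, causal_fraction = 0.1,
                       covariate_effects = c(sex = 0.10, age = 0.05,
                                             age2 = -0.02, site = 0.10),
                       exact_rescale = TRUE, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              block_size_snps = as.integer(block_size_snps),
              within_block_corr = within_block_corr,
              maf_range = maf_range, n_genes = as.integer(n_genes),
              gene_length_bp = as.integer(gene_length_bp),
              snp_spacing_bp = as.integer(snp_spacing_bp),
              n_geneset_genes = as.integer(n_geneset_genes),
              h2_coding = h2_coding, h2_buffer = h2_buffer, h2_rest = h2_rest,
              buffer_kb_truth = buffer_kb_truth,
              causal_fraction = causal_fraction,
              covariate_effects = covariate_effects,
              exact_rescale = isTRUE(exact_rescale), seed = as.integer(seed))
  with(cfg, {
    if (n_samples <= 0 || n_snps <= 0 || n_chromosomes <= 0 ||
        block_size_snps <= 0)
      stop("configuration error: dimensions must be positive")
    if (n_snps %% block_size_snps != 0)
      stop("configuration error: n_snps must be divisible by block_size_snps")
    if (n_snps / block_size_snps < n_chromosomes)
      stop("configuration error: fewer LD blocks than chromosomes")
    if (within_block_corr < 0 || within_block_corr >= 1)
      stop("configuration error: within_block_corr must be in [0, 1)")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stop("configuration error: maf_range must lie in (0, 0.5]")
    if (h2_coding + h2_buffer + h2_rest >= 1)
      stop("configuration error: h2 fractions must sum to < 1")
    if (min(h2_coding, h2_buffer, h2_rest) < 0)
      stop("configuration error: h2 fractions must be non-negative")
    if (n_geneset_genes > n_genes)
      stop("configuration error: n_geneset_genes exceeds n_genes")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate LD-structured diploid genotypes
#'
#' Haplotype mosaic model: SNPs are laid out in blocks of
#' `block_size_snps`; each block gets a constant allele frequency drawn from
#' `maf_range` and, along each of the 2n haplotypes, an allele copies its
#' left neighbour with probability `within_block_corr` or is redrawn at the
#' block frequency. Blocks are independent; dosage = sum of two haplotypes,
#' so genotypes satisfy Hardy-Weinberg proportions marginally.
#'
#' @param config a [sim_config()].
#' @return a [genotype_panel()]; SNPs are placed every `snp_spacing_bp` bp
#'   on `n_chromosomes` chromosomes.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_snps
  b <- config$block_size_snps
  n_blocks <- m %/% b
  rho <- config$within_block_corr

  # contiguous blocks assigned to chromosomes as evenly as possible
  blocks_per_chrom <- diff(round(seq(0, n_blocks, length.out =
                                       config$n_chromosomes + 1)))
  chrom_of_block <- rep(seq_len(config$n_chromosomes), blocks_per_chrom)

  dos <- matrix(0L, n, m)
  H <- matrix(0L, 2L * n, b)
  for (blk in seq_len(n_blocks)) {
    maf <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    H[, 1L] <- stats::rbinom(2L * n, 1L, maf)
    if (b > 1L) for (j in 2:b) {
      copy <- stats::runif(2L * n) < rho
      fresh <- stats::rbinom(2L * n, 1L, maf)
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    }
    cols <- ((blk - 1L) * b + 1L):(blk * b)
    dos[, cols] <- H[1:n, ] + H[(n + 1L):(2L * n), ]
  }

  chrom <- rep(chrom_of_block, each = b)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    seq_along(ix) * config$snp_spacing_bp), use.names = FALSE)
  meta <- data.frame(id = sprintf("snp%d_%d", chrom, pos),
                     chrom = chrom, pos_bp = pos,
                     allele1 = "A", allele2 = "B",
                     stringsAsFactors = FALSE)
  genotype_panel(dos, meta, sprintf("id%04d", seq_len(n)))
}

#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` intervals of `gene_length_bp` uniformly at random
#' without overlap, spread across the simulated chromosomes, and flags the
#' first `n_geneset_genes` placed genes as the a-priori gene set.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns symbol, chrom, start_bp, stop_bp
#'   (1-based inclusive), in_geneset.
#' @export
simulate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_blocks <- config$n_snps %/% config$block_size_snps
  blocks_per_chrom <- diff(round(seq(0, n_blocks, length.out =
                                       config$n_chromosomes + 1)))
  chrom_len <- blocks_per_chrom * config$block_size_snps *
    config$snp_spacing_bp
  genes_per_chrom <- diff(round(seq(0, config$n_genes, length.out =
                                      config$n_chromosomes + 1)))
  out <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    g <- genes_per_chrom[ch]
    if (g == 0L) next
    L <- chrom_len[ch]
    free <- L - g * config$gene_length_bp
    if (free < 0)
      stop("configuration error: genes cannot be placed without overlap on ",
           "chromosome ", ch)
    gaps <- sort(sample.int(free + 1L, g, replace = TRUE) - 1L)
    starts <- gaps + (seq_len(g) - 1L) * config$gene_length_bp + 1L
    out[[ch]] <- data.frame(chrom = ch, start_bp = starts,
                            stop_bp = starts + config$gene_length_bp - 1L)
  }
  genes <- do.call(rbind, out)
  genes$symbol <- sprintf("GENE%03d", seq_len(nrow(genes)))
  flagged <- sample.int(nrow(genes), config$n_geneset_genes)
  genes$in_geneset <- seq_len(nrow(genes)) %in% flagged
  genes[, c("symbol", "chrom", "start_bp", "stop_bp", "in_geneset")]
}

#' Simulate a phenotype with partition-specific genetic architecture
#'
#' Draws causal SNPs within each partition (a `causal_fraction` of the
#' partition, at least one when its target h2 is positive), Gaussian effects
#' on standardized dosages, covariate effects, and Gaussian noise with
#' variance `1 - h2_coding - h2_buffer - h2_rest`. With `exact_rescale`
#' (default) each partition's genetic values are rescaled so their in-sample
#' variance equals the target exactly, giving parameter-recovery tests a
#' known truth.
#'
#' @param panel a [genotype_panel()].
#' @param assignment a [snp_assignment()] covering all SNPs of `panel`.
#' @param config a [sim_config()].
#' @param effects optional `truth$effects` from a previously simulated
#'   cohort: the same causal SNPs and (scaled) effect sizes are applied to
#'   this panel, producing a second cohort that shares the genetic
#'   architecture (for discovery/validation designs). Exact rescaling is
#'   skipped in that case.
#' @return list of class `simulated_cohort` with elements `panel`,
#'   `phenotype`, `covariates` (data.frame: sex, age, age2, site) and
#'   `truth` (targets, realized variances, causal SNP ids and scaled
#'   effects per partition).
#' @export
simulate_phenotype <- function(panel, assignment, config, effects = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(assignment, "snp_assignment"))
  if (length(assignment$labels) != nrow(panel$snp_meta))
    stop("assignment does not cover the panel")
  set.seed(config$seed + 2L)
  n <- length(panel$sample_ids)
  h2 <- c(coding = config$h2_coding, buffer = config$h2_buffer,
          rest = config$h2_rest)

  covariates <- data.frame(
    sex = stats::rbinom(n, 1L, 0.5),
    age = round(stats::runif(n, 40, 70)),
    site = sample.int(3L, n, replace = TRUE))
  covariates$age2 <- covariates$age^2
  covariates <- covariates[, c("sex", "age", "age2", "site")]

  fixed <- numeric(n)
  ce <- config$covariate_effects
  for (nm in names(ce)) {
    if (!nm %in% names(covariates)) next
    col <- covariates[[nm]]
    fixed <- fixed + ce[[nm]] * as.numeric(scale(col))
  }

  Z <- standardize_dosages(panel)
  g <- matrix(0, n, 3, dimnames = list(NULL, names(h2)))
  causal <- list(coding = character(0), buffer = character(0),
                 rest = character(0))
  scaled_effects <- list(coding = numeric(0), buffer = numeric(0),
                         rest = numeric(0))
  realized <- c(coding = 0, buffer = 0, rest = 0)
  for (k in names(h2)) {
    if (is.null(effects)) {
      if (h2[[k]] <= 0) next
      idx <- which(assignment$labels == k)
      if (length(idx) == 0L)
        stop("configuration error: partition '", k,
             "' has target h2 > 0 but zero SNPs")
      nc <- max(1L, round(config$causal_fraction * length(idx)))
      ci <- sample(idx, nc)
      beta <- stats::rnorm(nc)
      gk <- drop(Z[, ci, drop = FALSE] %*% beta)
      v <- stats::var(gk)
      if (v <= 0) stop("degenerate genetic values in partition '", k, "'")
      if (config$exact_rescale) beta <- beta * sqrt(h2[[k]] / v)
      else beta <- beta * sqrt(h2[[k]] / sum(beta^2))  # expectation mode
      beta <- stats::setNames(beta, panel$snp_meta$id[ci])
    } else {
      beta <- effects[[k]]
      if (length(beta) == 0) next
      ci <- match(names(beta), panel$snp_meta$id)
      if (anyNA(ci))
        stop("shared effects refer to SNPs absent from this panel")
    }
    gk <- drop(Z[, ci, drop = FALSE] %*% beta)
    g[, k] <- gk
    causal[[k]] <- panel$snp_meta$id[ci]
    scaled_effects[[k]] <- beta
    realized[k] <- stats::var(gk)
  }

  sigma2_e <- 1 - sum(h2)
  e <- stats::rnorm(n, 0, sqrt(sigma2_e))
  y <- rowSums(g) + fixed + e

  structure(list(panel = panel, phenotype = y, covariates = covariates,
                 truth = list(h2_targets = h2, realized_var = realized,
                              causal = causal, effects = scaled_effects,
                              sigma2_e = sigma2_e, genetic_values = g)),
            class = "simulated_cohort")
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: genotypes, gene annotation, the true-buffer SNP
#' partition, and the phenotype, in one call.
#'
#' @param config a [sim_config()].
#' @return a `simulated_cohort` with additional elements `genes` and
#'   `assignment`.
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_genotypes(config)
  genes <- simulate_gene_annotation(config)
  assignment <- build_partition(genes, panel,
                                buffer_kb = config$buffer_kb_truth)
  cohort <- simulate_phenotype(panel, assignment, config)
  cohort$genes <- genes
  cohort$assignment <- assignment
  cohort
}
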