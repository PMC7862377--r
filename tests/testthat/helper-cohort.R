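# shared fixture builders; everything is generated in code at test time

# a hand-specified panel for interval/GRM arithmetic tests
tiny_panel <- function(pos = c(800, 1500, 2500, 20000), chrom = 1,
                       dosages = NULL, n = 3) {
  m <- length(pos)
  if (is.null(dosages)) {
    set.seed(42)
    dosages <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  }
  genotype_panel(dosages,
                 data.frame(id = paste0("s", seq_len(m)),
                            chrom = rep(chrom, length.out = m), pos_bp = pos,
                            allele1 = "A", allele2 = "B"),
                 paste0("ind", seq_len(nrow(dosages))))
}

one_gene <- function(start = 1000, stop = 2000, chrom = 1, flag = TRUE,
                     symbol = "G1") {
  data.frame(symbol = symbol, chrom = chrom, start_bp = start,
             stop_bp = stop, in_geneset = flag)
}

# small simulated cohort for pipeline tests; gene counts scale with panel
# size so annotations always fit on the simulated chromosomes
quick_cohort <- function(seed = 1, n = 300, m = 1000, ...) {
  args <- list(...)
  if (is.null(args$block_size_snps))
    args$block_size_snps <- max(Filter(function(b) m %% b == 0,
                                       c(1L, 2L, 4L, 5L, 10L, 20L, 25L)))
  if (is.null(args$n_genes)) args$n_genes <- max(4L, m %/% 50L)
  if (is.null(args$n_geneset_genes))
    args$n_geneset_genes <- max(2L, args$n_genes %/% 5L)
  base <- list(n_samples = n, n_snps = m, n_chromosomes = 2, seed = seed)
  base[names(args)] <- args
  simulate_cohort(do.call(sim_config, base))
}

# covariate design matrix in the convention used throughout: standardized
# sex/age/age2 plus site dummies
covar_design <- function(covariates) {
  cbind(sex = covariates$sex,
        age = as.numeric(scale(covariates$age)),
        age2 = as.numeric(scale(covariates$age2)),
        stats::model.matrix(~ factor(covariates$site))[, -1, drop = FALSE])
}

# marginal GWAS effects on the standardized-genotype scale (training stage
# of the polygenic-score tests)
marginal_std_effects <- function(panel, y) {
  Z <- standardize_dosages(panel)
  b <- drop(crossprod(Z, scale(y))) / (length(y) - 1)
  stats::setNames(b, panel$snp_meta$id)
}
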