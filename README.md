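# parth2

Partitioned SNP-heritability, gene-set enrichment, and polygenic scoring
for quantitative traits, in one tested R package.

## The problem

A recurring question in complex-trait genetics is whether an *a-priori*
gene set — for example, genes implicated by model-organism experiments —
carries more of a trait's heritability than its share of the genome would
predict, and whether effect sizes estimated around those genes transfer to
an independent cohort. Answering it end-to-end requires a chain of standard
but fiddly components: marker QC, genomic relatedness matrices, restricted
maximum likelihood variance components, enrichment statistics with
meta-analysis across sample subsets, mixed-model association, gene-set
overlap tests, and summary-statistic polygenic scores. `parth2` implements
that chain for quantitative traits, together with a block-LD genotype and
phenotype simulator so every stage is testable without access-controlled
cohort data.

## The model

SNPs are partitioned exclusively into three categories relative to the
flagged gene set: **coding** (inside a gene body), **buffer** (within *w*
kb of a gene's start or stop; *w* ∈ {0, 5, 10, 25, 35, 50} by convention),
and **rest**. For each category *k* a genomic relatedness matrix (GRM) is
built on standardized dosages,

    A_k[i,j] = (1/m_k) Σ_s (x_is − 2p_s)(x_js − 2p_s) / (2 p_s (1 − p_s)),

and the phenotype is modelled as

    y ~ N(Xβ, σ²_coding A_coding + σ²_buffer A_buffer + σ²_rest A_rest + σ²_e I),

fitted by average-information REML (`fit_greml`). Component shares
h²_k = σ²_k / Σ σ² are compared with their expectation under a uniform
per-SNP architecture,

    expected h²_k = (m_k / M) · h²_total,

and the **enrichment** ratio h²_k(observed) / h²_k(expected) is flagged
significant when the expectation falls outside the 95% confidence interval
of the observed estimate. Estimates from power-calibrated sample subsets
(`greml_power`, `quartile_split`) are pooled by fixed-effects
inverse-variance meta-analysis. Downstream, `mlma_loco` produces
mixed-model association statistics with leave-one-chromosome-out GRMs,
`fisher_overlap`/`jaccard`/`permutation_signal_test` compare gene sets
against a homolog background, and `sblup_adjust`/`pgs_score` build
summary-based BLUP polygenic scores (shrinkage λ = m(1/h² − 1) against a
reference LD panel) that are validated with `pgs_association`.

## Worked example

```r
library(parth2)
# simulate a cohort with heritability concentrated around the gene set
cfg <- sim_config(n_samples = 1500, n_snps = 5000, n_chromosomes = 5,
                  n_genes = 60, n_geneset_genes = 12,
                  h2_coding = 0.01, h2_buffer = 0.03, h2_rest = 0.05,
                  buffer_kb_truth = 10, seed = 42)
cohort <- simulate_cohort(cfg)
cohort$assignment
#> snp_assignment (buffer 10 kb): coding=48, buffer=96, rest=4856

lab <- cohort$assignment$labels
grms <- lapply(c("coding", "buffer", "rest"),
               function(k) compute_grm(cohort$panel, snps = lab == k))
X <- cbind(cohort$covariates$sex, scale(cohort$covariates$age),
           scale(cohort$covariates$age2),
           model.matrix(~ factor(cohort$covariates$site))[, -1])
fit <- fit_greml(cohort$phenotype, grms, X = X)
fit
#> greml_fit: 1500 samples, 3 genetic component(s); converged in 7 iterations
#>   sigma2_g1 = 0.00660 (SE 0.00753)  h2 share = 0.0065 (0.0074)
#>   sigma2_g2 = 0.04495 (SE 0.01665)  h2 share = 0.0444 (0.0160)
#>   sigma2_g3 = 0.04803 (SE 0.04835)  h2 share = 0.0474 (0.0477)
#>   sigma2_e = 0.91292 (SE 0.05825)  h2 share = 0.9016 (0.0503)
#>   REML loglik = -761.0341

h2_tot <- sum(fit$h2$h2[1:3])
enrichment(h2_obs = fit$h2$h2[2], se_obs = fit$h2$se[2],
           m_k = cohort$assignment$counts[["buffer"]],
           M = sum(cohort$assignment$counts), h2_total = h2_tot)
#> enrichment: 23.510 (obs 0.0444 +/- 0.0160 vs exp 0.0019; m_k = 96 / 5000) *

reduced <- fit_greml(cohort$phenotype, grms[c(1, 3)], X = X)
unlist(lrt_component(fit, reduced))
#>          lrt            p
#> 1.940369e+01 5.290133e-06
```

The buffer component was simulated to carry 3% heritability on ~2% of the
SNPs; the fitted share (4.4% ± 1.6%) is ~24 times its uniform-architecture
expectation, the expectation lies outside the 95% CI of the estimate
(starred), and dropping the component costs 19.4 log-likelihood units
(boundary-mixture p ≈ 5×10⁻⁶). The true simulated enrichment is
0.03/(96/5000 × 0.09) ≈ 17; the estimate is within one standard error.

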