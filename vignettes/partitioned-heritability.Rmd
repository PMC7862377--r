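---
title: "Partitioned heritability with an a-priori gene set: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned heritability with an a-priori gene set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parth2)
```

This vignette is the package's own account of the statistics it
implements: the variance-component model and its assumptions, what the
synthetic-data generator does and does not emulate, every numerical
constant that matters, and the design decisions that were genuinely open.
It states no empirical result that the test suite does not itself compute.

## 1. The variance-component model

Given an exclusive SNP partition into *coding* (inside a flagged gene
body), *buffer* (within a configurable number of kilobases of a flagged
gene's start or stop, clipped at position 1 and never crossing a
chromosome boundary), and *rest*, the phenotype model is

$$ y \sim N\!\left(X\beta,\; \sum_k \sigma^2_k A_k + \sigma^2_e I\right), $$

with one GCTA-style GRM $A_k$ per category, built on
sample-allele-frequency-standardized dosages with missing calls
mean-imputed and the average taken over the category's polymorphic SNPs.
Key consequences of this construction that the tests rely on:

* the GRM of a union of disjoint SNP sets is exactly the SNP-count-weighted
  average of the per-set GRMs (`combine_grms`), which is how
  leave-one-chromosome-out matrices are assembled;
* sample-frequency centering forces every GRM row to sum to zero, so the
  mean off-diagonal element is $-1/(n-1)$, not 0 — relevant when judging
  "unrelatedness" empirically;
* `offdiag_variance`, the variance of the distinct off-diagonal entries,
  is the quantity that drives detection power
  ($\mathrm{var}(\hat h^2) \approx 2/(n^2 v)$, `greml_power`, noncentral
  $\chi^2_1$ convention).

Assumptions: additive effects only, exchangeable samples (relatedness
handled by pruning, `relatedness_prune`, default cutoff 0.05 ≈ second
cousins), quantitative trait on the observed scale (no liability
transform), covariates modelled as fixed effects inside the REML rather
than pre-residualized.

## 2. AI-REML: the estimation engine

`fit_greml` maximizes the restricted likelihood with

* a single EM step first (robust far from the optimum), then
  average-information Newton steps;
* step-halving whenever a proposal would decrease the restricted
  log-likelihood or make $V$ indefinite, so the accepted trajectory is
  monotone (a property test asserts this);
* a variance floor of $10^{-6}\,\mathrm{var}(y)$ per component
  (constrained REML, GCTA-like). When a component pins to the floor, the
  Newton step is re-solved in the free coordinates only — without this the
  clamped coordinate contaminates the joint step and the fit stalls short
  of the optimum;
* convergence when the log-likelihood changes by less than $10^{-4}$,
  with at most 100 iterations; non-convergence is reported, never silent;
* sampling covariance = inverse AI matrix at convergence; heritability
  shares $\sigma^2_k/\sum\sigma^2$ carry delta-method standard errors;
* a singular AI matrix (e.g. a GRM equal to the identity, confounded with
  the residual) raises a non-identifiability error.

The likelihood-ratio test for one component (`lrt_component`) uses the
boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, i.e.
$p = \tfrac12 P(\chi^2_1 > \mathrm{LRT})$. A caveat the test suite makes
explicit: at the $h^2 = 0$ boundary the *estimate* is positive whenever
the profile score is positive, which under the null happens with
probability about one half at any sample size — a null fit "at the floor
every time" is not a property any correct implementation can have.

## 3. Enrichment, significance, meta-analysis

Expected component heritability under a uniform per-SNP architecture is
$(m_k/M)\,h^2_{\mathrm{total}}$; enrichment is observed/expected; the
whole genome has enrichment 1 identically. Two significance readings of
"1.96" circulate for this statistic: a confidence-interval exclusion rule
($|h^2_{\mathrm{obs}} - h^2_{\mathrm{exp}}| > 1.96\,\mathrm{SE}$) and a
threshold on the ratio itself ($\mathrm{enrichment} > 1.96$). They
disagree — a ratio of 1.6 with a tiny SE is significant under the first
and not the second. The CI-exclusion rule is the default because it is
the statistically coherent one; the ratio rule is available as
`rule = "ratio"` and no further intent is guessed.

Subsets are built by `quartile_split` (round-robin within phenotype
quartiles, so subset compositions differ by at most one sample per
quartile) and pooled by fixed-effects inverse-variance meta-analysis
(`fixed_effects_meta`; cross-checked in the tests against
`metafor::rma(method = "FE")`). `enrichment_table` assembles the standard
summary: per-component meta-estimates, enrichment, significance, and
percent of the meta-analyzed total. Note that component percentages need
not sum exactly to 100: each component is pooled with its own weights.

## 4. Association and gene-level aggregation

`mlma_loco` re-estimates variance components once per left-out chromosome
(standard mixed-model association practice), then tests each SNP by GLS
with covariates projected out: $\hat b = w^\top P y / w^\top P w$,
$\chi^2_1 = \hat b^2\, w^\top P w$. Excluding the tested chromosome's SNPs
from the GRM avoids proximal contamination — absorbing the tested SNP into
the random effect shrinks its own signal, a property the tests verify
directly. With a single chromosome the function degrades to a plain mixed
model with a warning.

`gene_minp` is deliberately the simplest defensible gene-level aggregate:
$p_{\mathrm{gene}} = \min(1, n_{\mathrm{SNPs}} \times \min p)$ over SNPs
within ±10 kb of the gene body, BH-FDR adjusted across genes. It stands in
for full multi-marker gene tests (which couple SNPs through LD and
regulatory annotations) and is labelled as such in its output; conclusions
that depend on the fine structure of gene-level signal should not rest on
it.

## 5. Overlap statistics

`fisher_overlap` reports the *sample* odds ratio $ad/bc$ as the headline
number (it is the quantity reproducible from printed 2×2 counts), computes
the two-sided exact p itself by hypergeometric enumeration, and stores the
conditional-MLE odds ratio and exact conditional CI from `fisher.test`
secondarily. `permutation_signal_test` compares a gene set's mean
$-\log_{10} p$ against same-size random draws with the add-one estimator
$p = (1 + \#\{null \ge obs\})/(n_{\mathrm{perm}} + 1)$. Between-group
signal comparisons use a two-sided rank-sum on $-\log_{10} p$
(`signal_ranksum`) — a package choice, exposed but not claimed to match
any particular published pipeline.

## 6. Summary-based BLUP scores

Marginal GWAS effects are standardized
($\beta_{\mathrm{std}} = \hat\beta\sqrt{2p(1-p)}$), then jointly shrunken
per LD block by solving $(n R + \lambda I) u = n \hat\beta$ with
$\lambda = m_{\mathrm{total}}(1/h^2_{\mathrm{SNP}} - 1)$. Choices:

* $\lambda$ uses the total SNP count and total GWAS heritability and is
  applied identically to all partitions (per-partition shrinkage would
  presuppose the enrichment being tested);
* the LD reference is a windowed per-chromosome Pearson correlation
  matrix of reference dosages (default window 1000 kb, ridge 0.01 on the
  diagonal); a reference panel of ≥ 500 samples stands in for a public
  reference cohort;
* scores are computed on standardized target dosages, so partition scores
  add exactly to the all-SNP score;
* `pgs_association` reports the score coefficient and the incremental
  $R^2$ over a covariate-only model (canonically the first 6 PCs from
  `top_pcs`, which uses a deterministic sign convention: the
  largest-magnitude SNP loading of each component is positive).

## 7. The synthetic-data generator

`simulate_genotypes` uses a **copy-or-refresh haplotype mosaic**: SNPs are
laid out in blocks with a constant block allele frequency drawn from
`maf_range`; along each of the $2n$ haplotypes, an allele copies its left
neighbour with probability `within_block_corr` or is redrawn at the block
frequency. Dosage = sum of two independent haplotypes. This gives exactly
the target adjacent-SNP genotype correlation in expectation, geometric
decay with distance inside a block, independence across blocks, and
Hardy–Weinberg marginals. A latent-Gaussian threshold model was considered
and rejected: thresholding attenuates a latent correlation of 0.8 to a
genotype correlation of roughly 0.5–0.6 (tetrachoric attenuation), so the
LD "knob" would not mean what it says.

`simulate_phenotype` draws causal SNPs within each partition (default 10%
of the partition), Gaussian effects on standardized dosages, covariate
effects (sex, age, age², site, applied to standardized columns so the
coefficient is in phenotype-SD units), and Gaussian noise with variance
$1 - \sum_k h^2_k$. With `exact_rescale` (default) each partition's
genetic values are rescaled so the realized in-sample variance equals the
target *exactly*, giving recovery tests a known truth; `exact_rescale =
FALSE` is pure expectation mode. A `truth$effects` record lets a second
cohort reuse the same causal SNPs and effect sizes
(`simulate_phenotype(..., effects = )`), which is what makes
discovery/validation transfer experiments meaningful.

Default study conditions (`sim_config`) emulate the intended application:
total additive heritability 0.085 (0.005 coding + 0.03 buffer + 0.05
rest — in the 8–10% range typical of consumption phenotypes), a flagged
gene set of 20 of 100 genes, 10 kb true buffer, block LD of 0.6.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: realistic human allele-frequency and LD
spectra (blocks are exchangeable and unrealistically regular), imputation
dosages, the X chromosome, relatedness and population structure beyond
exchangeable samples, assortative mating, and any non-additive
architecture. Results on real cohorts additionally depend on QC and
ancestry handling outside the simulator's scope.

## 8. Marker QC conventions

`qc_filter` removes low-call-rate samples first (call rate ≥ 0.99), then
SNPs in a fixed order — minor allele frequency (remove MAF < 0.01, the
PLINK `--maf` semantics), Hardy–Weinberg exact p (< 10⁻⁴), missingness
(> 0.10) — each SNP counted once under the first criterion it fails, so
reports are unambiguous and the filter is idempotent. "Genotyping rate"
thresholds are ambiguous between per-sample and per-SNP readings in common
usage; the per-sample reading is implemented, mirroring PLINK's
`--mind`/`--geno` split. The Hardy–Weinberg test is the two-sided exact
conditional test (no mid-p), checked against closed-form enumeration and,
at tiny n, against exhaustive allele-pairing enumeration.

## 9. Problem sizes used by the simulation studies

The heavy properties in the test suite run at "desk scale", sized by power
arithmetic before the tests were frozen:

* **REML recovery**: n = 800, m = 20,000, truth (0.01, 0.03, 0.05), 100
  phenotype replicates over one genotype panel (phenotype and estimation
  noise dominate genotype resampling for this check); coverage of ±2 SE
  intervals ≥ 90% per component.
* **Enrichment detection**: 3 subsets of n = 1500 from one cohort of
  4500, m = 5000 with the buffer ≈ 2% of SNPs carrying h² = 0.03 against
  h² = 0.05 elsewhere. The idealized $\mathrm{var}(\hat h^2) = 2/(n^2 v)$
  underestimates multi-component SEs (components are correlated); the
  empirical AI-REML SE at n = 1500 gives a meta-analysis SE ≈ 0.0074 and
  ~96% per-run detection, hence ≥ 18/20 runs.
* **LRT calibration**: 200 null fits at n = 500, m = 1000.
* **Association type-I error**: 2000 SNPs × 4 null phenotypes at n = 400.
* **Polygenic transfer**: train n = 2000, validate n = 800, m = 3000,
  h²_coding = 0.06 vs h²_rest = 0.02, fixed LD reference of n = 500
  reused across 20 replicates (as a fixed external reference panel would
  be); expected coding-score incremental R² of 1.5–3% against the ~0.5%
  needed for p < 0.05 at n = 800.

## 10. Known limitations

* GRMs mean-impute missing calls and divide by the SNP count, not by
  per-pair non-missing counts; identical when post-QC missingness is
  zero, slightly different otherwise.
* PCs are computed on an LD-unaware standardized matrix; for real data an
  LD-pruned marker set should feed `top_pcs`.
* `gene_minp` is a stand-in (Section 4); the Fisher-overlap CI is
  conditional and can disagree slightly with the sample OR near boundary
  tables; `mlma_loco` refits variance components per chromosome, not per
  SNP.
* The boundary behaviour of null variance components (Section 2) means
  "significance" of tiny components should lean on the LRT, not on
  Wald-type intervals.
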