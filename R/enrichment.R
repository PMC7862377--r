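#' Expected component heritability under uniform per-SNP contribution
#'
#' `(m_k / M) * h2_total`: the heritability a component of `m_k` SNPs would
#' capture if total SNP-heritability were spread evenly over all `M` SNPs.
#'
#' @param m_k SNPs in the component (0 < m_k <= M).
#' @param M total SNPs used to estimate `h2_total`.
#' @param h2_total total SNP-heritability in \[0, 1\].
#' @return expected heritability fraction.
#' @export
expected_h2 <- function(m_k, M, h2_total) {
  if (m_k <= 0 || m_k > M) stop("need 0 < m_k <= M")
  if (h2_total < 0 || h2_total > 1) stop("h2_total must lie in [0, 1]")
  (m_k / M) * h2_total
}

#' Heritability enrichment of a SNP category
#'
#' Ratio of the observed component heritability to its expectation under a
#' uniform per-SNP architecture. Significance (default rule `"ci"`) flags
#' components whose expectation falls outside the 95% confidence interval
#' of the observed estimate, i.e. `|h2_obs - h2_exp| > z * se_obs`. The
#' alternative rule `"ratio"` flags `enrichment > z` instead; it is exposed
#' because both readings circulate, but the CI-exclusion rule is the
#' default.
#'
#' @param h2_obs observed component heritability.
#' @param se_obs its standard error (> 0).
#' @param m_k,M,h2_total see [expected_h2()].
#' @param z critical value (default 1.96).
#' @param rule `"ci"` (default) or `"ratio"`.
#' @return object of class `enrichment_result`: m_k, M, h2_obs, se_obs,
#'   h2_exp, enrichment, significant.
#' @export
enrichment <- function(h2_obs, se_obs, m_k, M, h2_total, z = 1.96,
                       rule = c("ci", "ratio")) {
  rule <- match.arg(rule)
  if (se_obs <= 0) stop("se_obs must be positive")
  if (m_k == 0) stop("undefined enrichment: component has zero SNPs")
  h2_exp <- expected_h2(m_k, M, h2_total)
  enr <- h2_obs / h2_exp
  sig <- if (rule == "ci") abs(h2_obs - h2_exp) > z * se_obs else enr > z
  structure(list(m_k = m_k, M = M, h2_obs = h2_obs, se_obs = se_obs,
                 h2_exp = h2_exp, enrichment = enr, significant = sig,
                 rule = rule),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %.3f (obs %.4f +/- %.4f vs exp %.4f; m_k = %d / %d)%s\n",
    x$enrichment, x$h2_obs, x$se_obs, x$h2_exp, as.integer(x$m_k),
    as.integer(x$M), if (x$significant) " *" else ""))
  invisible(x)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools estimates with weights `1/se^2`; the pooled standard error is
#' `1/sqrt(sum of weights)`.
#'
#' @param estimates numeric vector of per-subset estimates.
#' @param ses their standard errors (positive, same length).
#' @return object of class `meta_estimate`: pooled, se, z, p, and the
#'   inputs.
#' @export
fixed_effects_meta <- function(estimates, ses) {
  if (length(estimates) != length(ses) || length(estimates) == 0)
    stop("estimates and ses must be non-empty and of equal length")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- pooled / se
  structure(list(pooled = pooled, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 estimates = estimates, ses = ses),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("meta_estimate: %.4f (SE %.4f) from %d subset(s)\n",
              x$pooled, x$se, length(x$estimates)))
  invisible(x)
}

#' Component share of total heritability, in percent
#'
#' @param meta_component,meta_total `meta_estimate` objects (or scalars) for
#'   the component and the model total.
#' @return percentage `100 * component / total`.
#' @export
percent_total <- function(meta_component, meta_total) {
  num <- if (inherits(meta_component, "meta_estimate"))
    meta_component$pooled else meta_component
  den <- if (inherits(meta_total, "meta_estimate"))
    meta_total$pooled else meta_total
  if (den == 0) stop("total heritability is zero")
  100 * num / den
}

#' GREML power calculation
#'
#' The GCTA-GREML power calculator convention for a quantitative trait:
#' `var(h2_hat) = 2 / (n^2 v)` with `v` the variance of the off-diagonal
#' GRM elements; the test statistic is noncentral chi-squared with 1 df and
#' `NCP = h2^2 / var(h2_hat)`.
#'
#' @param n sample size (>= 2).
#' @param v_offdiag off-diagonal GRM variance (> 0); see
#'   [offdiag_variance()].
#' @param h2 the heritability to detect.
#' @param alpha type-I error rate (default 0.05).
#' @return list(power, se_h2, ncp).
#' @export
greml_power <- function(n, v_offdiag, h2, alpha = 0.05) {
  if (n < 2) stop("need n >= 2")
  if (v_offdiag <= 0) stop("v_offdiag must be positive")
  var_h2 <- 2 / (n^2 * v_offdiag)
  ncp <- h2^2 / var_h2
  crit <- stats::qchisq(1 - alpha, df = 1)
  list(power = stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE),
       se_h2 = sqrt(var_h2), ncp = ncp)
}

#' Quartile-balanced random subset assignment
#'
#' Splits samples into `k_subsets` groups of near-equal size whose
#' phenotype distributions are constitutionally equivalent: within each
#' phenotype quartile, samples are shuffled and dealt round-robin, so
#' per-subset quartile composition differs by at most one sample.
#'
#' @param phenotype numeric vector.
#' @param k_subsets number of subsets (>= 2).
#' @param seed integer seed.
#' @return integer vector of subset labels in 1..k_subsets.
#' @export
quartile_split <- function(phenotype, k_subsets, seed = 1L) {
  stopifnot(k_subsets >= 2)
  set.seed(seed)
  qs <- stats::quantile(phenotype, c(0.25, 0.5, 0.75), type = 7)
  quart <- findInterval(phenotype, qs, rightmost.closed = FALSE) + 1L
  out <- integer(length(phenotype))
  offset <- 0L
  for (q in sort(unique(quart))) {
    idx <- sample(which(quart == q))
    out[idx] <- ((seq_along(idx) - 1L + offset) %% k_subsets) + 1L
    offset <- offset + length(idx)  # carry remainder across quartiles
  }
  out
}

#' Partitioned-heritability enrichment table across subsets
#'
#' Combines per-subset multi-component GREML fits into the standard
#' partitioned-heritability summary: per-subset observed h2 (SE) and
#' enrichment per component, fixed-effects meta-analysis across subsets,
#' and each component's percent of the meta-analyzed total.
#'
#' @param fits list of `greml_fit` objects, one per subset, sharing the
#'   same ordered genetic components.
#' @param m_k named SNP counts per genetic component (order matching the
#'   GRMs passed to [fit_greml()]).
#' @param z,rule passed to [enrichment()].
#' @return data.frame, one row per component plus a `total` row, with
#'   per-subset estimates, meta-analysis, enrichment and percent of total.
#' @export
enrichment_table <- function(fits, m_k, z = 1.96, rule = "ci") {
  K <- length(m_k)
  M <- sum(m_k)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, function(f) length(f$sigma2), 0L) == K + 1))
  comp_names <- names(m_k)
  rows <- list()
  get_h2 <- function(f, k) c(f$h2$h2[k], f$h2$se[k])
  # per-subset totals: genetic share = 1 - residual share
  totals <- lapply(fits, function(f) {
    h2g <- sum(f$h2$h2[seq_len(K)])
    grad_mask <- c(rep(1, K), 0)
    tot <- sum(f$sigma2)
    grad <- (grad_mask * tot - sum(f$sigma2[seq_len(K)])) / tot^2
    se <- sqrt(max(0, drop(t(grad) %*% f$cov_sigma2 %*% grad)))
    c(h2g, se)
  })
  meta_tot <- fixed_effects_meta(vapply(totals, `[`, 0, 1),
                                 vapply(totals, `[`, 0, 2))
  for (k in seq_len(K)) {
    est <- vapply(fits, function(f) f$h2$h2[k], 0)
    se <- vapply(fits, function(f) f$h2$se[k], 0)
    meta_k <- fixed_effects_meta(est, se)
    enr <- lapply(seq_along(fits), function(s)
      enrichment(est[s], se[s], m_k[k], M, totals[[s]][1], z = z,
                 rule = rule))
    meta_enr <- enrichment(meta_k$pooled, meta_k$se, m_k[k], M,
                           meta_tot$pooled, z = z, rule = rule)
    rows[[k]] <- data.frame(
      component = comp_names[k], m_k = m_k[k],
      meta_h2 = meta_k$pooled, meta_se = meta_k$se,
      meta_enrichment = meta_enr$enrichment,
      meta_significant = meta_enr$significant,
      pct_total = percent_total(meta_k, meta_tot),
      n_subsets_significant = sum(vapply(enr, `[[`, TRUE, "significant")))
  }
  rows[[K + 1]] <- data.frame(
    component = "total", m_k = M,
    meta_h2 = meta_tot$pooled, meta_se = meta_tot$se,
    meta_enrichment = 1, meta_significant = FALSE,
    pct_total = 100, n_subsets_significant = NA_integer_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
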