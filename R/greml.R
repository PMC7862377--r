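#' Average-information REML variance-component estimation
#'
#' Fits `y ~ N(X beta, V)` with `V = sum_k sigma2_k A_k + sigma2_e I` by
#' restricted maximum likelihood. The first update is an EM step; later
#' iterations are average-information (AI) Newton steps with step-halving
#' whenever a proposal would decrease the restricted log-likelihood or make
#' V indefinite. Components are constrained at a small positive floor by
#' default (set `constrain = FALSE` for unconstrained estimates).
#'
#' Per iteration, with `P = Vinv - Vinv X (X' Vinv X)^-1 X' Vinv`:
#' score_k = -1/2 (tr(P A_k) - y' P A_k P y), AI_kl = 1/2 y' P A_k P A_l P y.
#' The sampling covariance of the estimates is the inverse AI matrix at
#' convergence, and per-component heritability shares carry delta-method
#' standard errors.
#'
#' @param y numeric phenotype vector.
#' @param grms list of `grm` objects (or plain matrices) sharing sample
#'   order with `y`; may be empty for a covariates-only model.
#' @param X fixed-effect design matrix (default: intercept only). An
#'   intercept column is added if absent.
#' @param constrain keep components at or above the floor
#'   (`floor_frac * var(y)`).
#' @param tol convergence tolerance on the change in log-likelihood.
#' @param max_iter maximum number of iterations.
#' @param floor_frac floor, as a fraction of `var(y)`.
#' @return object of class `greml_fit`: `sigma2` (named, residual last),
#'   `cov_sigma2` (inverse AI), `loglik`, `h2` (data.frame of shares and
#'   delta-method SEs), `converged`, `n_iter`, `ll_trace` (accepted
#'   log-likelihood after each iteration).
#' @export
fit_greml <- function(y, grms, X = NULL, constrain = TRUE, tol = 1e-4,
                      max_iter = 100L, floor_frac = 1e-6) {
  n <- length(y)
  if (n < 30) stop("need at least 30 samples")
  A <- lapply(grms, function(g) {
    M <- if (inherits(g, "grm")) g$matrix else as.matrix(g)
    if (nrow(M) != n) stop("GRM dimension does not match phenotype length")
    (M + t(M)) / 2
  })
  K <- length(A)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(c) stats::sd(c) == 0 && c[1] != 0)))
    X <- cbind(1, X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  p <- ncol(X)
  if (p >= n) stop("more covariates than samples")

  vy <- stats::var(y)
  floor_v <- floor_frac * vy
  sigma2 <- c(rep(vy / (2 * max(K, 1)), K), vy / 2)
  names(sigma2) <- c(if (K) paste0("g", seq_len(K)), "e")

  eval_model <- function(s2) {
    V <- diag(rep(s2[K + 1], n))
    for (k in seq_len(K)) V <- V + s2[k] * A[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVX <- crossprod(X, VinvX)
    chx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vinv - VinvX %*% chol2inv(chx) %*% t(VinvX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll)
  }

  st <- eval_model(sigma2)
  if (is.null(st)) stop("initial variance matrix is not positive definite")
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- st$P; Py <- st$Py
    # derivative pieces; residual component uses A = I
    APy <- c(lapply(A, function(Ak) drop(Ak %*% Py)), list(Py))
    trPA <- c(vapply(A, function(Ak) sum(P * Ak), numeric(1)),
              sum(diag(P)))
    ytPAPy <- vapply(APy, function(v) sum(Py * v), numeric(1))
    score <- -0.5 * (trPA - ytPAPy)
    PAPy <- lapply(APy, function(v) drop(P %*% v))
    AI <- matrix(0, K + 1, K + 1)
    for (i in seq_len(K + 1)) for (j in i:(K + 1))
      AI[i, j] <- AI[j, i] <- 0.5 * sum(APy[[i]] * PAPy[[j]])
    if (rcond(AI) < 1e-12)
      stop("model is not identifiable: singular average-information matrix")

    delta <- if (iter == 1L) sigma2^2 * (ytPAPy - trPA) / n  # EM step
             else drop(solve(AI, score))
    if (constrain && iter > 1L) {
      # components pinned at the floor: hold them and take the Newton step
      # in the free coordinates only
      viol <- which(sigma2 + delta < floor_v)
      if (length(viol) > 0 && length(viol) <= K) {
        free <- setdiff(seq_len(K + 1), viol)
        delta[viol] <- floor_v - sigma2[viol]
        delta[free] <- drop(solve(AI[free, free, drop = FALSE],
                                  score[free] - AI[free, viol, drop = FALSE] %*%
                                    delta[viol]))
      }
    }
    step <- 1
    repeat {
      prop <- sigma2 + step * delta
      if (constrain) prop <- pmax(prop, floor_v)
      st_new <- eval_model(prop)
      if (!is.null(st_new) && st_new$ll >= st$ll - 1e-8) break
      step <- step / 2
      if (step < 1e-8) { st_new <- st; prop <- sigma2; break }
    }
    sigma2 <- prop
    st <- st_new
    ll_trace <- c(ll_trace, st$ll)
    if (abs(st$ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- st$ll
  }

  cov_s2 <- tryCatch(solve(AI), error = function(e) MASS::ginv(AI))
  dimnames(cov_s2) <- list(names(sigma2), names(sigma2))

  tot <- sum(sigma2)
  h2 <- sigma2 / tot
  se_h2 <- vapply(seq_along(sigma2), function(k) {
    grad <- -sigma2[k] / tot^2
    grad <- rep(grad, length(sigma2))
    grad[k] <- grad[k] + 1 / tot
    sqrt(max(0, drop(t(grad) %*% cov_s2 %*% grad)))
  }, numeric(1))

  structure(list(sigma2 = sigma2, cov_sigma2 = cov_s2, loglik = st$ll,
                 h2 = data.frame(component = names(sigma2), h2 = unname(h2),
                                 se = unname(se_h2)),
                 converged = converged, n_iter = iter, n = n,
                 floor = floor_v, constrain = constrain,
                 ll_trace = ll_trace),
            class = "greml_fit")
}

#' @export
print.greml_fit <- function(x, ...) {
  cat("greml_fit:", x$n, "samples,", length(x$sigma2) - 1,
      "genetic component(s);",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations\n")
  se <- sqrt(pmax(0, diag(x$cov_sigma2)))
  for (i in seq_along(x$sigma2))
    cat(sprintf("  sigma2_%s = %.5f (SE %.5f)  h2 share = %.4f (%.4f)\n",
                names(x$sigma2)[i], x$sigma2[i], se[i], x$h2$h2[i],
                x$h2$se[i]))
  cat(sprintf("  REML loglik = %.4f\n", x$loglik))
  invisible(x)
}

#' Likelihood-ratio test for one variance component
#'
#' Compares a full fit with a nested fit in which one GRM was dropped. The
#' statistic `2 (ll_full - ll_reduced)` is clipped at zero and referred to
#' the boundary mixture `0.5 chi2_0 + 0.5 chi2_1`, i.e.
#' `p = 0.5 P(chi2_1 > LRT)`.
#'
#' @param fit_full,fit_reduced `greml_fit` objects; the reduced model must
#'   nest the full one.
#' @return list(lrt, p).
#' @export
lrt_component <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "greml_fit"), inherits(fit_reduced, "greml_fit"))
  if (length(fit_reduced$sigma2) >= length(fit_full$sigma2))
    stop("reduced model must have fewer components than the full model")
  d <- fit_full$loglik - fit_reduced$loglik
  if (d < -1e-3)
    warning("full model log-likelihood below the reduced model's; ",
            "the full fit may not have converged - consider refitting")
  lrt <- max(0, 2 * d)
  p <- if (lrt == 0) 0.5 else 0.5 * stats::pchisq(lrt, df = 1,
                                                  lower.tail = FALSE)
  list(lrt = lrt, p = p)
}
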