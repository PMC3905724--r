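#' Centered genetic relationship (kinship) matrix
#'
#' `K = W W' / p` where `W` has one column per polymorphic variant holding
#' `x - 2f` (genotype centered at twice the effect-allele frequency) and `p`
#' is the number of polymorphic variants — the centered convention used by
#' mixed-model association software. Missing genotypes are mean-imputed per
#' variant for this computation only.
#'
#' @param g a [geno_matrix] with at least 2 polymorphic variants (a single
#'   sample is allowed and yields a 1x1 matrix).
#' @return symmetric n x n kinship matrix with sample IDs as dimnames.
#' @export
kinship_centered <- function(g) {
  f <- alt_freqs(g)
  poly <- which(!is.na(f) & f > 0 & f < 1)
  if (length(poly) == 0) stop("no polymorphic variants; kinship undefined")
  W <- g$geno[, poly, drop = FALSE]
  for (j in seq_along(poly)) {
    col <- W[, j]
    col[is.na(col)] <- 2 * f[poly[j]]
    W[, j] <- col - 2 * f[poly[j]]
  }
  storage.mode(W) <- "double"
  K <- tcrossprod(W) / length(poly)
  dimnames(K) <- list(sample_ids(g), sample_ids(g))
  K
}

#' Precompute the spectral decomposition used by the mixed model
#'
#' The mixed model profiles the variance ratio on the eigendecomposition of
#' the kinship matrix; decomposing once per (kinship, cohort) and reusing it
#' across variants is the standard speed-up.
#'
#' @param K symmetric positive-semidefinite kinship matrix.
#' @return object of class `lmm_ready` holding eigenvalues/vectors.
#' @export
lmm_prepare <- function(K) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8) stop("kinship matrix must be symmetric")
  ee <- eigen(K, symmetric = TRUE)
  if (min(ee$values) < -1e-6 * max(abs(ee$values), 1)) {
    stop("kinship matrix is not positive semidefinite")
  }
  structure(list(values = pmax(ee$values, 0), vectors = ee$vectors, n = nrow(K)),
            class = "lmm_ready")
}

## Profiled ML log-likelihood of y = X b + u + e, cov(u) = sg^2 K,
## cov(e) = se^2 I, at variance ratio lambda = sg^2 / se^2, on the rotated
## data (yr = U'y, Xr = U'X, d = eigenvalues of K).
.lmm_profile_ll <- function(log10_lambda, yr, Xr, d) {
  lambda <- 10^log10_lambda
  w <- 1 / (lambda * d + 1)
  ## weighted least squares via pivoted QR; aliased columns (e.g. a variant
  ## conditioned on itself) get coefficient 0 rather than an error
  Xw <- Xr * sqrt(w)
  yw <- yr * sqrt(w)
  qrX <- qr(Xw)
  b <- qr.coef(qrX, yw)
  b[is.na(b)] <- 0
  rss <- sum((yw - Xw %*% b)^2)
  XtWX <- crossprod(Xw)
  n <- length(yr)
  s2 <- rss / n
  ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s2) - 0.5 * sum(log(lambda * d + 1)) - 0.5 * n
  list(ll = ll, beta = b, s2 = s2, XtWX = XtWX, lambda = lambda)
}

.lmm_ml <- function(y, X, prep, lower = -5, upper = 5, grid = NULL) {
  if (is.null(prep$vectors)) {        # identity kinship: no rotation needed
    yr <- y
    Xr <- X
  } else {
    yr <- crossprod(prep$vectors, y)
    Xr <- crossprod(prep$vectors, X)
  }
  f <- function(l10) .lmm_profile_ll(l10, yr, Xr, prep$values)$ll
  if (is.null(grid)) {
    opt <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = 1e-8)
    ## a bounded 1-D search can miss a boundary optimum; check the ends
    cand <- c(opt$maximum, lower, upper)
    best <- cand[which.max(vapply(cand, f, 0))]
  } else {
    pts <- seq(lower, upper, length.out = grid)
    best <- pts[which.max(vapply(pts, f, 0))]
  }
  fit <- .lmm_profile_ll(best, yr, Xr, prep$values)
  fit$se <- tryCatch(sqrt(diag(solve(fit$XtWX)) * fit$s2),
                     error = function(e) rep(NA_real_, ncol(Xr)))
  fit$log10_lambda <- best
  fit
}

#' Single-variant linear mixed-model association
#'
#' Fits `y = covariates*a + x*b + u + e` with `cov(u) = sg^2 K` and
#' `cov(e) = se^2 I` by maximum likelihood, profiling the variance ratio
#' `sg^2/se^2` on the eigendecomposition of K and optimizing it by bounded
#' one-dimensional search on log10 scale in [-5, 5]. The p-value is a
#' likelihood-ratio test on chi-square(1) against the null model without `x`.
#' Rows with missing `y`, `x` or covariates are dropped (complete cases).
#'
#' @param y numeric trait values.
#' @param x variant dosages (0/1/2 or imputed).
#' @param covariates optional numeric matrix/data.frame of covariates (an
#'   intercept is always included).
#' @param K kinship matrix, a prepared [lmm_prepare] object (only valid when
#'   no rows are dropped), or `NULL` for unrelated samples (identity kinship,
#'   under which the fit reduces to ordinary ML regression).
#' @return an `assoc_result` list: `beta`, `se`, `p_lrt`, `lrt`,
#'   `effect_allele_freq`, `variance_explained`, `n`, `n_dropped`,
#'   `log10_lambda`, and the alternative/null log-likelihoods.
#' @export
lmm_fit <- function(y, x, covariates = NULL, K) {
  X0 <- cbind(intercept = rep(1, length(y)))
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  ok <- stats::complete.cases(y, x, X0)
  n_dropped <- sum(!ok)
  if (is.null(K)) {
    ## identity kinship (unrelated samples): the model is plain ML regression
    prep <- structure(list(values = rep(0, sum(ok)), vectors = NULL,
                           n = sum(ok)), class = "lmm_ready")
  } else if (inherits(K, "lmm_ready")) {
    if (n_dropped > 0) {
      stop("prepared decomposition cannot be used when rows are dropped; pass K")
    }
    prep <- K
  } else {
    prep <- lmm_prepare(K[ok, ok, drop = FALSE])
  }
  y <- y[ok]; x <- x[ok]; X0 <- X0[ok, , drop = FALSE]
  if (stats::var(x) == 0) {
    warning("variant dosage is constant; no association test possible")
    return(structure(list(beta = 0, se = NA_real_, p_lrt = 1, lrt = 0,
                          effect_allele_freq = mean(x) / 2,
                          variance_explained = 0, n = length(y),
                          n_dropped = n_dropped, log10_lambda = NA_real_,
                          ll_alt = NA_real_, ll_null = NA_real_),
                     class = "assoc_result"))
  }
  fit1 <- .lmm_ml(y, cbind(X0, x = x), prep)
  fit0 <- .lmm_ml(y, X0, prep)
  lrt <- max(0, 2 * (fit1$ll - fit0$ll))
  k <- ncol(X0) + 1
  beta <- fit1$beta[k]
  structure(
    list(
      beta = unname(beta), se = unname(fit1$se[k]),
      p_lrt = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
      lrt = lrt,
      effect_allele_freq = mean(x) / 2,
      variance_explained = variance_explained(beta, mean(x) / 2, stats::var(y)),
      n = length(y), n_dropped = n_dropped,
      log10_lambda = fit1$log10_lambda,
      ll_alt = fit1$ll, ll_null = fit0$ll
    ),
    class = "assoc_result"
  )
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf(
    "assoc_result: beta = %.4g (se %.4g), LRT p = %.3g, EAF = %.4g, VE = %.3g, n = %d\n",
    x$beta, x$se, x$p_lrt, x$effect_allele_freq, x$variance_explained, x$n))
  invisible(x)
}

#' Fraction of trait variance explained by an additive variant
#'
#' `VE = 2 f (1 - f) beta^2 / var_y`, clamped to [0, 1).
#'
#' @param beta per-allele effect in trait units.
#' @param f effect-allele frequency.
#' @param var_y trait variance (> 0).
#' @export
variance_explained <- function(beta, f, var_y) {
  stopifnot(var_y > 0, f >= 0, f <= 1)
  min(2 * f * (1 - f) * beta^2 / var_y, 1 - 1e-12)
}

#' Conditional single-variant association
#'
#' Re-tests `x_test` with `x_condition` added to the covariates; a signal that
#' survives conditioning is statistically independent of the conditioning
#' variant.
#'
#' @param y,x_test,covariates,K as in [lmm_fit].
#' @param x_condition dosage vector of the conditioning variant.
#' @return the conditional `assoc_result`, with elements `p_unconditional`
#'   and `p_change` added.
#' @export
conditional_fit <- function(y, x_test, x_condition, covariates = NULL, K) {
  ok <- stats::complete.cases(x_test, x_condition)
  r2 <- suppressWarnings(stats::cor(x_test[ok], x_condition[ok])^2)
  if (!is.na(r2) && r2 > 0.999) {
    warning("test and conditioning variants are nearly collinear (r2 > 0.999)")
  }
  covs <- cbind(condition = x_condition)
  if (!is.null(covariates)) covs <- cbind(as.matrix(covariates), covs)
  uncond <- lmm_fit(y, x_test, covariates, K)
  res <- lmm_fit(y, x_test, covs, K)
  res$p_unconditional <- uncond$p_lrt
  res$p_change <- res$p_lrt - uncond$p_lrt
  res
}

#' Mixed-model association for a binary trait
#'
#' Fits the linear mixed model to the 0/1 outcome (the linear-on-the-binary-
#' scale treatment common in mixed-model association pipelines); the effect
#' is reported both
#' as a risk-difference beta and on an exponentiated scale with a 95% CI.
#' A logistic mixed model is out of scope.
#'
#' @param y01 binary outcome in {0, 1}; both classes must be present.
#' @inheritParams lmm_fit
#' @return `assoc_result` with `exp_beta`, `exp_ci_lower`, `exp_ci_upper`.
#' @export
binary_trait_fit <- function(y01, x, covariates = NULL, K) {
  ok <- !is.na(y01)
  if (!all(y01[ok] %in% 0:1)) stop("binary outcome must be coded 0/1")
  if (length(unique(y01[ok])) < 2) stop("binary outcome has a single class")
  res <- lmm_fit(as.numeric(y01), x, covariates, K)
  res$exp_beta <- exp(res$beta)
  res$exp_ci_lower <- exp(res$beta - 1.96 * res$se)
  res$exp_ci_upper <- exp(res$beta + 1.96 * res$se)
  res
}

#' Association results as a table
#'
#' Collects `assoc_result` objects into a data.frame with the conventional
#' columns (variant, effect allele, frequency, beta, se, p).
#'
#' @param results named list of `assoc_result` objects.
#' @export
assoc_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(variant = nm, effect_allele_freq = r$effect_allele_freq,
               beta = r$beta, se = r$se, p_lrt = r$p_lrt,
               variance_explained = r$variance_explained, n = r$n)
  }))
}
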