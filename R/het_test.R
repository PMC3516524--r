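#' Maximum-likelihood GLM fit with BIC
#'
#' Fits a generalised linear model by iteratively re-weighted least
#' squares (`stats::glm.fit`), returning the coefficient vector, log
#' likelihood, parameter count and BIC used by the heterogeneity
#' statistics. Convergence uses a relative deviance change below 1e-8 or
#' 100 iterations. Rows with any missing value are dropped. Complete
#' separation under the logit link is handled by capping coefficients at
#' +/-15 on the log-odds scale and flagging the fit as non-converged
#' rather than erroring, so genome scans run to completion.
#'
#' For the identity link the residual variance counts as one extra BIC
#' parameter (its MLE `rss/n` enters the log likelihood); this term is
#' shared by the heterogeneous and null models and cancels in T.
#'
#' @param y response vector (binary 0/1 for `"logit"`).
#' @param X design matrix, full column rank after row dropping.
#' @param link `"logit"` or `"identity"`.
#' @return An object of class `glm_fit` with elements `coefficients`,
#'   `se`, `log_likelihood`, `n_params`, `n_used`, `link`, `converged`,
#'   `separation`, `bic`.
#' @export
fit_glm <- function(y, X, link = c("logit", "identity")) {
  link <- match.arg(link)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X)
  p_cols <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p_cols) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p_cols)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (link == "logit" && !all(y %in% c(0, 1))) {
    stop("logit link requires a binary 0/1 phenotype")
  }
  fam <- if (link == "logit") stats::binomial() else stats::gaussian()
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  beta <- fit$coefficients
  converged <- isTRUE(fit$converged)
  separation <- FALSE
  if (link == "logit" && any(abs(beta) > 15)) {
    beta <- pmin(pmax(beta, -15), 15)
    separation <- TRUE
    converged <- FALSE
  }
  eta <- drop(X %*% beta)
  if (link == "logit") {
    mu <- pmin(pmax(expit(eta), 1e-12), 1 - 1e-12)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    n_params <- p_cols
    w <- mu * (1 - mu)
    vc <- tryCatch(solve(crossprod(X * sqrt(w))),
                   error = function(e) matrix(NA_real_, p_cols, p_cols))
  } else {
    rss <- sum((y - eta)^2)
    sigma2 <- rss / n
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
    n_params <- p_cols + 1  # residual variance
    vc <- tryCatch(rss / (n - p_cols) * solve(crossprod(X)),
                   error = function(e) matrix(NA_real_, p_cols, p_cols))
  }
  se <- sqrt(diag(vc))
  names(beta) <- names(se) <- colnames(X)
  structure(list(
    coefficients = beta,
    se = se,
    vcov = vc,
    log_likelihood = ll,
    n_params = n_params,
    n_used = n,
    link = link,
    converged = converged,
    separation = separation,
    bic = -2 * ll + n_params * log(n)
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit (%s): n=%d, params=%d, logLik=%.3f, BIC=%.3f%s\n",
              x$link, x$n_used, x$n_params, x$log_likelihood, x$bic,
              if (!x$converged) " [not converged]" else ""))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Build heterogeneous and null design matrices for one marker
#'
#' The heterogeneous model carries K cluster-indicator intercepts
#' (`alpha_1..alpha_K`), K cluster-specific genotype columns
#' (`beta_1..beta_K`, the indicator times the dosage) and the shared
#' adjustment covariates; the null model replaces the K genotype columns
#' with a single shared dosage column (`beta`), retaining the cluster
#' intercepts so that cluster-specific background prevalence never
#' masquerades as interaction. Samples with a missing dosage (or missing
#' covariate) are dropped from both designs identically, so the two BICs
#' are computed on the same n.
#'
#' @param x dosage vector for the tested marker.
#' @param clustering an `exposure_clustering`.
#' @param W optional covariate matrix aligned with `x`.
#' @return List with `X_het`, `X_null`, logical `keep`, and `n`.
#'   A cluster left with fewer than 2 genotyped samples raises a
#'   condition of class `marker_skip`.
#' @export
build_designs <- function(x, clustering, W = NULL) {
  Z <- clustering$Z
  K <- clustering$K
  keep <- !is.na(x)
  if (!is.null(W)) keep <- keep & stats::complete.cases(W)
  Zk <- Z[keep, , drop = FALSE]
  cnt <- colSums(Zk)
  if (any(cnt < 2)) {
    stop(errorCondition(
      paste0("cluster(s) ", paste(which(cnt < 2), collapse = ", "),
             " have fewer than 2 samples with observed genotype"),
      class = c("marker_skip", "error", "condition")))
  }
  xk <- x[keep]
  Wk <- if (is.null(W)) NULL else W[keep, , drop = FALSE]
  gnames <- if (is.null(Wk)) NULL else paste0("gamma_", colnames(Wk))
  X_het <- cbind(Zk, Zk * xk, Wk)
  colnames(X_het) <- c(paste0("alpha_", seq_len(K)),
                       paste0("beta_", seq_len(K)), gnames)
  X_null <- cbind(Zk, xk, Wk)
  colnames(X_null) <- c(paste0("alpha_", seq_len(K)), "beta", gnames)
  list(X_het = X_het, X_null = X_null, keep = keep, n = sum(keep))
}

#' T statistic: BIC evidence for heterogeneous association
#'
#' Fits the heterogeneous and null models for one marker under a given
#' clustering and returns `T = BIC_null - BIC_het`: positive values mean
#' the cluster-specific-effect model is preferred even after paying the
#' complexity penalty, i.e. evidence of interaction heterogeneity.
#' Equivalently `T = 2*(logLik_het - logLik_null) - (K-1)*log(n)`.
#'
#' @param ds a [genotype_dataset].
#' @param marker marker id or column index.
#' @param clustering an `exposure_clustering`.
#' @param W optional covariate matrix (defaults to none; pass `ds$W` to
#'   adjust).
#' @param link `"logit"` or `"identity"`.
#' @return List with `T`, `het_fit`, `null_fit`, and `flagged` (TRUE when
#'   either fit failed to converge).
#' @export
t_statistic <- function(ds, marker, clustering, W = NULL,
                        link = c("logit", "identity")) {
  link <- match.arg(link)
  x <- if (is.character(marker)) ds$dosages[, match(marker, ds$marker_ids)]
       else ds$dosages[, marker]
  dz <- build_designs(x, clustering, W)
  yk <- ds$y[dz$keep]
  het <- fit_glm(yk, dz$X_het, link)
  null <- fit_glm(yk, dz$X_null, link)
  list(T = null$bic - het$bic,
       het_fit = het,
       null_fit = null,
       flagged = !(het$converged && null$converged))
}

#' D statistic: difference of heterogeneity evidence between exposures
#'
#' `D = T_A - T_B` for two T statistics computed on the same marker and
#' sample set. Positive D says exposure A (ancestry, in the canonical
#' analysis) explains the heterogeneity better; negative D points at
#' exposure B (the collection label), i.e. a collection artefact.
#'
#' @param T_A,T_B T statistics from [t_statistic].
#' @return `T_A - T_B`.
#' @export
d_statistic <- function(T_A, T_B) T_A - T_B

# Full per-marker test against two clusterings: T_anc, T_coll, D and the
# per-cluster effect estimates from both heterogeneous fits. Internal
# workhorse of scan_markers().
marker_het_test <- function(ds, marker, clustering_anc, clustering_coll,
                            W = NULL, link = "logit") {
  ta <- t_statistic(ds, marker, clustering_anc, W, link)
  tb <- t_statistic(ds, marker, clustering_coll, W, link)
  ka <- clustering_anc$K
  kb <- clustering_coll$K
  ba <- ta$het_fit$coefficients[paste0("beta_", seq_len(ka))]
  bb <- tb$het_fit$coefficients[paste0("beta_", seq_len(kb))]
  list(T_anc = ta$T, T_coll = tb$T, D = d_statistic(ta$T, tb$T),
       n_used = ta$het_fit$n_used,
       beta_anc = unname(ba),
       se_anc = unname(ta$het_fit$se[paste0("beta_", seq_len(ka))]),
       beta_coll = unname(bb),
       se_coll = unname(tb$het_fit$se[paste0("beta_", seq_len(kb))]),
       flagged = ta$flagged || tb$flagged)
}

# Lean fitting path used by the null-calibration and scan loops: returns
# the log likelihood (from the deviance for the Bernoulli family), the
# rank, and a convergence flag, skipping the construction of a full
# glm_fit object. Returns NULL on rank deficiency.
.ll_fast <- function(X, y, fam, identity = FALSE) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (fit$rank < ncol(X)) return(NULL)
  if (identity) {
    n <- length(y)
    sigma2 <- fit$deviance / n
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  } else {
    ll <- -fit$deviance / 2
  }
  list(ll = ll, converged = isTRUE(fit$converged))
}

# T statistics for a raw dosage vector against prebuilt clustering
# components; returns c(T, converged) or NULL when the design degenerates
# (monomorphic-in-cluster markers and the like).
.t_fast <- function(x, y, Z, W, fam, identity, ln_n, K) {
  Xh <- cbind(Z, Z * x, W)
  Xn <- cbind(Z, x, W)
  fh <- .ll_fast(Xh, y, fam, identity)
  if (is.null(fh)) return(NULL)
  fn <- .ll_fast(Xn, y, fam, identity)
  if (is.null(fn)) return(NULL)
  c(T = 2 * (fh$ll - fn$ll) - (K - 1) * ln_n,
    converged = as.numeric(fh$converged && fn$converged))
}
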