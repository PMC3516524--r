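#' Expected chance count above an upper-centile threshold
#'
#' The number of markers expected to pass a `centile`% null threshold by
#' chance alone in a scan of `n_markers` markers: for integer centiles the
#' exact integer `n_markers * (100 - centile) / 100` (floored), e.g.
#' 485,757 markers at the 99th centile give 4,857.
#'
#' @param n_markers number of markers tested.
#' @param centile threshold centile (default 99).
#' @return Integer expected count.
#' @export
expected_chance_count <- function(n_markers, centile = 99) {
  if (centile == round(centile)) {
    as.integer((as.double(n_markers) * (100 - centile)) %/% 100)
  } else {
    as.integer(floor(n_markers * (100 - centile) / 100))
  }
}

#' Genome-wide heterogeneity scan
#'
#' Computes T_anc, T_coll and D for every marker of a dataset, filters to
#' markers whose D exceeds the calibrated threshold (strictly greater)
#' and ranks the candidates by T_anc, descending. Markers whose designs
#' degenerate (e.g. monomorphic within a cluster) are skipped with a
#' logged reason rather than aborting the scan.
#'
#' @param ds a [genotype_dataset].
#' @param clustering_anc,clustering_coll the two exposure clusterings
#'   (must cover the same samples as `ds`).
#' @param W optional adjustment covariates.
#' @param thresholds a `threshold_table` from [estimate_thresholds], or a
#'   single numeric D threshold.
#' @param link `"logit"` or `"identity"`.
#' @return A `scan_report`: `results` (per-marker statistics), and
#'   `candidates` (the D-filtered markers ordered by decreasing T_anc),
#'   `expected_by_chance`, `skipped`.
#' @export
scan_markers <- function(ds, clustering_anc, clustering_coll, W = NULL,
                         thresholds, link = "logit") {
  n <- length(ds$sample_ids)
  if (nrow(clustering_anc$Z) != n || nrow(clustering_coll$Z) != n) {
    stop("clusterings must cover the same samples as the dataset")
  }
  if (is.numeric(thresholds)) {
    d_thr <- thresholds
    centile <- 99
  } else {
    d_thr <- thresholds$d_threshold
    centile <- thresholds$settings$centile
  }
  m <- ncol(ds$dosages)
  ka <- clustering_anc$K
  kb <- clustering_coll$K
  rows <- vector("list", m)
  skipped <- character(0)
  for (j in seq_len(m)) {
    res <- tryCatch(
      marker_het_test(ds, j, clustering_anc, clustering_coll, W, link),
      marker_skip = function(e) conditionMessage(e),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped <- c(skipped, stats::setNames(res, ds$marker_ids[j]))
      next
    }
    row <- data.frame(marker_id = ds$marker_ids[j], n_used = res$n_used,
                      T_anc = res$T_anc, T_coll = res$T_coll, D = res$D,
                      flagged = res$flagged, stringsAsFactors = FALSE)
    for (c in seq_len(ka)) {
      row[[paste0("beta_anc_", c)]] <- res$beta_anc[c]
      row[[paste0("se_anc_", c)]] <- res$se_anc[c]
      if (link == "logit") row[[paste0("or_anc_", c)]] <- exp(res$beta_anc[c])
    }
    for (c in seq_len(kb)) {
      row[[paste0("beta_coll_", c)]] <- res$beta_coll[c]
      row[[paste0("se_coll_", c)]] <- res$se_coll[c]
      if (link == "logit") row[[paste0("or_coll_", c)]] <- exp(res$beta_coll[c])
    }
    rows[[j]] <- row
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(results) <- NULL
  cand <- results[!is.na(results$D) & results$D > d_thr, , drop = FALSE]
  cand <- cand[order(-cand$T_anc), , drop = FALSE]
  structure(list(
    results = results,
    candidates = cand,
    d_threshold = d_thr,
    centile = centile,
    n_markers = nrow(results),
    expected_by_chance = expected_chance_count(nrow(results), centile),
    skipped = skipped,
    K_anc = ka, K_coll = kb
  ), class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("scan_report: %d markers tested (%d skipped)\n",
              x$n_markers, length(x$skipped)))
  cat(sprintf("  D > %.4f (upper %g%%): %d candidate(s); %d expected by chance\n",
              x$d_threshold, x$centile, nrow(x$candidates), x$expected_by_chance))
  if (nrow(x$candidates)) {
    print(utils::head(x$candidates[, c("marker_id", "T_anc", "T_coll", "D")], 10))
  }
  invisible(x)
}

#' Cross-phase consistency of candidate markers
#'
#' Returns the markers that pass the D filter in both discovery phases
#' *and* whose per-cluster effect directions agree across phases (the
#' sign of each matched cluster's heterogeneous-model effect estimate is
#' the same in both scans). Cluster labels are assumed matched across
#' phases.
#'
#' @param candidates_phase1,results_phase2 `scan_report` objects sharing
#'   marker identifiers.
#' @return Character vector of retained marker ids (possibly empty; a
#'   warning is raised when the phases share no candidate markers).
#' @export
cross_phase_consistency <- function(candidates_phase1, results_phase2) {
  stopifnot(inherits(candidates_phase1, "scan_report"),
            inherits(results_phase2, "scan_report"))
  if (candidates_phase1$K_anc != results_phase2$K_anc) {
    stop("phases were scanned with different ancestry cluster counts")
  }
  c1 <- candidates_phase1$candidates
  c2 <- results_phase2$candidates
  shared <- intersect(c1$marker_id, c2$marker_id)
  if (!length(shared)) {
    warning("no shared markers pass the D filter in both phases")
    return(character(0))
  }
  ka <- candidates_phase1$K_anc
  keep <- vapply(shared, function(id) {
    b1 <- as.numeric(c1[c1$marker_id == id, paste0("beta_anc_", seq_len(ka))])
    b2 <- as.numeric(c2[c2$marker_id == id, paste0("beta_anc_", seq_len(ka))])
    all(sign(b1) == sign(b2))
  }, logical(1))
  shared[keep]
}

#' Targeted replication with proxy group labels
#'
#' Per-group association test for one marker in an independent
#' replication cohort where ancestry cannot be recomputed and a proxy
#' label (typically collection of origin) stands in for it. Fits a GLM of
#' phenotype on dosage (plus covariates) within each label group and
#' reports the Wald estimate, 95% CI, and one-sided p in the direction
#' pre-registered at discovery (no multiple-testing adjustment: targeted
#' replication tests a single pre-specified marker).
#'
#' @param ds_rep replication [genotype_dataset].
#' @param marker marker id or index.
#' @param proxy_labels factor of proxy group labels; defaults to the
#'   dataset's collection factor.
#' @param W optional covariates.
#' @param direction `"protective"` or `"risk"` - the discovery-phase
#'   direction; either a single value for all groups or a vector named by
#'   group level.
#' @return A `replication_result` data frame with one row per group:
#'   `group`, `n`, `beta`, `se`, `or`, `lo`, `hi`, `p_one`, `p_two`,
#'   `skipped`.
#' @export
replication_test <- function(ds_rep, marker, proxy_labels = ds_rep$collection,
                             W = NULL, direction = "protective") {
  x <- if (is.character(marker)) ds_rep$dosages[, match(marker, ds_rep$marker_ids)]
       else ds_rep$dosages[, marker]
  f <- droplevels(as.factor(proxy_labels))
  lev <- levels(f)
  dir_vec <- if (length(direction) == 1) stats::setNames(rep(direction, length(lev)), lev)
             else direction
  if (!all(lev %in% names(dir_vec))) stop("direction must be named for every group")
  if (!all(dir_vec %in% c("protective", "risk"))) {
    stop('direction values must be "protective" or "risk"')
  }
  rows <- lapply(lev, function(g) {
    sel <- f == g
    xg <- x[sel]
    yg <- ds_rep$y[sel]
    Wg <- if (is.null(W)) NULL else W[sel, , drop = FALSE]
    if (stats::var(xg, na.rm = TRUE) == 0 || all(is.na(xg))) {
      return(data.frame(group = g, n = sum(sel), beta = NA_real_, se = NA_real_,
                        or = NA_real_, lo = NA_real_, hi = NA_real_,
                        p_one = NA_real_, p_two = NA_real_,
                        skipped = "no dosage variation", stringsAsFactors = FALSE))
    }
    X <- cbind(intercept = 1, x = xg, Wg)
    fit <- fit_glm(yg, X, "logit")
    b <- fit$coefficients[["x"]]
    se <- fit$se[["x"]]
    z <- b / se
    p1 <- if (dir_vec[[g]] == "protective") stats::pnorm(z) else stats::pnorm(-z)
    data.frame(group = g, n = fit$n_used, beta = b, se = se,
               or = exp(b), lo = exp(b - 1.96 * se), hi = exp(b + 1.96 * se),
               p_one = p1, p_two = 2 * stats::pnorm(-abs(z)),
               skipped = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("replication_result", "data.frame")
  out
}

#' Normal-approximation p-value from a printed OR and 95% CI
#'
#' Back-computes the Wald p-value implied by a reported odds ratio and
#' its 95% confidence interval: `SE = (ln hi - ln lo) / (2 * 1.96)`,
#' `z = ln(OR) / SE`, then the one- or two-sided normal tail. Useful as a
#' consistency check of published association tables.
#'
#' @param or_ point estimate of the odds ratio.
#' @param lo,hi 95% confidence bounds, `0 < lo < or_ < hi`.
#' @param sided 1 or 2.
#' @return The p-value.
#' @export
pvalue_from_or_ci <- function(or_, lo, hi, sided = 2) {
  if (!(lo > 0 && lo < or_ && or_ < hi)) {
    stop("confidence bounds must bracket the odds ratio: need 0 < lo < OR < hi")
  }
  if (!sided %in% c(1, 2)) stop("sided must be 1 or 2")
  se <- (log(hi) - log(lo)) / (2 * 1.96)
  z <- log(or_) / se
  sided * stats::pnorm(-abs(z))
}

#' Pooled fit of one marker across datasets
#'
#' Meta-analytic logistic fit on the concatenated samples with a free
#' intercept per source dataset (source as fixed factor, echoing the
#' cluster-intercept philosophy of the null model) and a single shared
#' genetic effect. Sample ids must be disjoint and the phenotype coding
#' identical across datasets.
#'
#' @param datasets list of [genotype_dataset]s, each containing `marker`.
#' @param marker marker id (character) shared by all datasets.
#' @param covars optional character vector of covariate column names to
#'   adjust for; each named column must exist in every dataset's `W`.
#' @param direction optional `"protective"`/`"risk"` for the one-sided p.
#' @return List with `beta`, `se`, `or`, `lo`, `hi`, `p_two`, `p_one`,
#'   `n`, `n_sources`.
#' @export
pooled_fit <- function(datasets, marker, covars = NULL, direction = "protective") {
  ids <- unlist(lapply(datasets, `[[`, "sample_ids"))
  if (anyDuplicated(ids)) stop("sample ids must be disjoint across pooled datasets")
  biny <- vapply(datasets, function(d) all(d$y[!is.na(d$y)] %in% c(0, 1)), logical(1))
  if (!all(biny == biny[1])) stop("phenotype coding differs across datasets")
  pieces <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    j <- if (is.character(marker)) match(marker, d$marker_ids) else marker
    if (is.na(j)) stop("marker not present in dataset ", i)
    Wc <- NULL
    if (!is.null(covars)) {
      if (!all(covars %in% colnames(d$W))) {
        stop("dataset ", i, " lacks covariate(s): ",
             paste(setdiff(covars, colnames(d$W)), collapse = ", "))
      }
      Wc <- d$W[, covars, drop = FALSE]
    }
    list(y = d$y, x = d$dosages[, j], W = Wc, src = rep(i, length(d$y)))
  })
  y <- unlist(lapply(pieces, `[[`, "y"))
  x <- unlist(lapply(pieces, `[[`, "x"))
  src <- factor(unlist(lapply(pieces, `[[`, "src")))
  W <- if (is.null(covars)) NULL else do.call(rbind, lapply(pieces, `[[`, "W"))
  S <- stats::model.matrix(~ 0 + src)
  colnames(S) <- paste0("alpha_src", levels(src))
  X <- cbind(S, x = x, W)
  fit <- fit_glm(y, X, "logit")
  b <- fit$coefficients[["x"]]
  se <- fit$se[["x"]]
  z <- b / se
  list(beta = b, se = se, or = exp(b),
       lo = exp(b - 1.96 * se), hi = exp(b + 1.96 * se),
       p_two = 2 * stats::pnorm(-abs(z)),
       p_one = if (direction == "protective") stats::pnorm(z) else stats::pnorm(-z),
       n = fit$n_used, n_sources = length(datasets))
}

# Retrospective genotype class distributions for cases and controls given
# a population MAF, a per-genotype log-odds slope, and a baseline (g = 0)
# disease probability: P(g | case) ~ r(g) f(g), P(g | control) ~ (1 -
# r(g)) f(g) with r(g) = expit(logit(prev) + log(or) g) and f the HWE
# genotype frequencies.
.retro_geno_dist <- function(maf, or_, prevalence) {
  f <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  r <- expit(logit(prevalence) + log(or_) * (0:2))
  case <- r * f
  ctrl <- (1 - r) * f
  list(case = case / sum(case), control = ctrl / sum(ctrl))
}

# Aggregated logistic fit of case status on genotype class (3 rows with
# binomial weights) - identical MLE/SE to the individual-level fit.
.fit_geno_counts <- function(n_case_g, n_ctrl_g) {
  tot <- n_case_g + n_ctrl_g
  use <- tot > 0
  if (sum(use) < 2) return(NULL)
  g <- (0:2)[use]
  X <- cbind(1, g)
  fit <- suppressWarnings(
    stats::glm.fit(X, n_case_g[use] / tot[use], weights = tot[use],
                   family = stats::binomial()))
  if (fit$rank < 2) return(NULL)
  b <- fit$coefficients[2]
  w <- fit$weights
  vc <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
  if (is.null(vc)) return(NULL)
  c(beta = unname(b), se = sqrt(vc[2, 2]))
}

#' Closed-form Wald power for a replication association test
#'
#' Analytic counterpart of [power_switch] at switch rate 0: under
#' retrospective case-control sampling the limiting logistic model keeps
#' the genotype slope `log(or_)` with an intercept shifted by the
#' sampling fractions; the Fisher information is evaluated under the
#' sampled genotype mixture, and power follows from the normal
#' approximation to the Wald test.
#'
#' @param or_ true per-allele odds ratio.
#' @param maf minor-allele frequency.
#' @param n_cases,n_controls sample sizes.
#' @param alpha significance level.
#' @param sided 1 (in the direction of `or_`) or 2.
#' @param prevalence baseline (genotype 0) disease probability in the
#'   source population.
#' @return Power in `[0, 1]`.
#' @export
power_wald <- function(or_, maf, n_cases, n_controls, alpha = 0.05,
                       sided = 1, prevalence = 0.05) {
  b <- log(or_)
  dist <- .retro_geno_dist(maf, or_, prevalence)
  phi <- n_cases / (n_cases + n_controls)
  n <- n_cases + n_controls
  g <- 0:2
  fmix <- phi * dist$case + (1 - phi) * dist$control
  # limiting intercept: odds(case | g) in the sampled data
  odds0 <- phi * dist$case[1] / ((1 - phi) * dist$control[1])
  a_star <- log(odds0)
  mu <- expit(a_star + b * g)
  w <- fmix * mu * (1 - mu)
  info <- matrix(c(sum(w), sum(w * g), sum(w * g), sum(w * g^2)), 2, 2)
  var_b <- solve(info)[2, 2] / n
  se <- sqrt(var_b)
  if (sided == 1) {
    stats::pnorm(stats::qnorm(alpha) + abs(b) / se)
  } else {
    stats::pnorm(stats::qnorm(alpha / 2) + abs(b) / se) +
      stats::pnorm(stats::qnorm(alpha / 2) - abs(b) / se)
  }
}

#' Power of proxy-label replication as the switch rate varies
#'
#' Monte-Carlo power analysis for replicating a group-specific
#' association when only a noisy proxy of the ancestry label is
#' available. At each switch rate s, a "group-1-labelled" individual is
#' truly from group 1 with probability 1-s and from group 2 otherwise;
#' case and control genotypes are drawn retrospectively from the genotype
#' distributions implied by each true group's odds ratio and the MAF
#' under a logistic disease model with baseline prevalence `prevalence`.
#' Power is the fraction of simulations whose one-sided p (in the
#' direction of `or_group1`) falls below `alpha`. Misclassification
#' attenuates the labelled-group effect, so power is monotone
#' non-increasing in s (up to Monte-Carlo error).
#'
#' @param or_group1 true odds ratio in the labelled target group.
#' @param or_group2 true odds ratio in the other group (default 1).
#' @param maf minor-allele frequency (shared; the proxy-error model
#'   isolates label noise from frequency differences).
#' @param n_cases,n_controls labelled-group sample sizes.
#' @param switch_rate_grid switch rates in `[0, 0.5]`.
#' @param alpha significance level.
#' @param sided 1 or 2.
#' @param sims Monte-Carlo replicates per grid point.
#' @param seed integer master seed.
#' @param prevalence baseline disease probability.
#' @return A `power_result` data frame: `switch_rate`, `power`, `mc_se`
#'   (`sqrt(power (1-power) / sims)`), `n_valid`; settings attached as
#'   attributes.
#' @export
power_switch <- function(or_group1, or_group2 = 1, maf, n_cases, n_controls,
                         switch_rate_grid = c(0, 0.1, 0.2, 0.3, 0.5),
                         alpha = 0.05, sided = 1, sims = 1000, seed = 1,
                         prevalence = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(switch_rate_grid < 0 | switch_rate_grid > 0.5)) {
    stop("switch rates must lie in [0, 0.5]")
  }
  d1 <- .retro_geno_dist(maf, or_group1, prevalence)
  d2 <- .retro_geno_dist(maf, or_group2, prevalence)
  protective <- or_group1 <= 1
  draw_counts <- function(n, s, dist1, dist2) {
    n2 <- stats::rbinom(1, n, s)
    c1 <- stats::rmultinom(1, n - n2, dist1)[, 1]
    c2 <- if (n2 > 0) stats::rmultinom(1, n2, dist2)[, 1] else c(0, 0, 0)
    c1 + c2
  }
  rows <- lapply(switch_rate_grid, function(s) {
    reject <- logical(sims)
    valid <- logical(sims)
    for (i in seq_len(sims)) {
      set.seed(mix_seed(seed, round(s * 1000), i))
      nc <- draw_counts(n_cases, s, d1$case, d2$case)
      n0 <- draw_counts(n_controls, s, d1$control, d2$control)
      fit <- .fit_geno_counts(nc, n0)
      if (is.null(fit)) next
      valid[i] <- TRUE
      z <- fit[["beta"]] / fit[["se"]]
      p <- if (sided == 2) 2 * stats::pnorm(-abs(z))
           else if (protective) stats::pnorm(z) else stats::pnorm(-z)
      reject[i] <- p < alpha
    }
    nv <- sum(valid)
    pw <- if (nv) sum(reject[valid]) / nv else NA_real_
    data.frame(switch_rate = s, power = pw,
               mc_se = sqrt(pw * (1 - pw) / nv), n_valid = nv)
  })
  out <- do.call(rbind, rows)
  attr(out, "settings") <- list(or_group1 = or_group1, or_group2 = or_group2,
                                maf = maf, n_cases = n_cases,
                                n_controls = n_controls, alpha = alpha,
                                sided = sided, sims = sims, seed = seed,
                                prevalence = prevalence)
  class(out) <- c("power_result", "data.frame")
  out
}
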