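#' Simulate null genotypes under Hardy-Weinberg equilibrium
#'
#' Retrospective null draw: genotypes are simulated independently of the
#' (fixed) phenotype, covariates and clusterings, with class probabilities
#' `(1-p)^2, 2p(1-p), p^2` at minor-allele frequency `p`.
#'
#' @param n number of samples.
#' @param maf minor-allele frequency in `(0, 0.5]`.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (callers that manage their own substreams pass `NULL`).
#' @return Integer dosage vector of length `n`.
#' @export
simulate_null_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
    stop("maf must lie in (0, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  sample.int(3L, n, replace = TRUE,
             prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)) - 1L
}

#' Draw a null sample of T and D statistics
#'
#' Simulates `length(mafs)` null markers (genotypes independent of the
#' fixed phenotype, under HWE at each given MAF) and computes the T
#' statistic under clustering A, and - when a second clustering is
#' supplied - under clustering B plus the difference statistic D.
#' Each draw uses its own substream seed derived from (`seed`, MAF,
#' occurrence index), so results are invariant to reordering of `mafs`.
#'
#' @param y fixed phenotype vector.
#' @param clustering_a primary (ancestry) `exposure_clustering`.
#' @param clustering_b optional secondary (collection) clustering; `NULL`
#'   for single-clustering designs.
#' @param W optional fixed covariate matrix.
#' @param link `"logit"` or `"identity"`.
#' @param mafs vector of minor-allele frequencies, one per simulated
#'   marker.
#' @param seed integer master seed.
#' @return Data frame with columns `maf`, `T_a`, (`T_b`, `D`,) `converged`.
#' @export
simulate_null_stats <- function(y, clustering_a, clustering_b = NULL,
                                W = NULL, link = "logit", mafs, seed = 1) {
  identity <- link == "identity"
  fam <- if (identity) stats::gaussian() else stats::binomial()
  n <- length(y)
  Za <- clustering_a$Z
  Ka <- clustering_a$K
  Zb <- if (!is.null(clustering_b)) clustering_b$Z else NULL
  Kb <- if (!is.null(clustering_b)) clustering_b$K else NA_integer_
  ln_n <- log(n)
  nm <- length(mafs)
  T_a <- rep(NA_real_, nm)
  T_b <- rep(NA_real_, nm)
  conv <- rep(NA, nm)
  maf_key <- round(mafs * 1000)
  occ <- stats::ave(seq_len(nm), maf_key, FUN = seq_along)
  for (i in seq_len(nm)) {
    set.seed(mix_seed(seed, maf_key[i], occ[i]))
    x <- simulate_null_genotypes(n, mafs[i])
    ra <- .t_fast(x, y, Za, W, fam, identity, ln_n, Ka)
    if (is.null(ra)) next
    ok <- ra[["converged"]] > 0
    T_a[i] <- ra[["T"]]
    if (!is.null(Zb)) {
      rb <- .t_fast(x, y, Zb, W, fam, identity, ln_n, Kb)
      if (is.null(rb)) { T_a[i] <- NA_real_; next }
      T_b[i] <- rb[["T"]]
      ok <- ok && rb[["converged"]] > 0
    }
    conv[i] <- ok
  }
  out <- data.frame(maf = mafs, T_a = T_a)
  if (!is.null(Zb)) {
    out$T_b <- T_b
    out$D <- T_a - T_b
  }
  out$converged <- conv
  out
}

#' Calibrate significance thresholds for D (and T) by null simulation
#'
#' Estimates the null distribution of the difference statistic by
#' retrospective simulation: the observed phenotype, covariates and both
#' clusterings stay fixed while genotypes are redrawn under HWE at each
#' MAF on the grid (default 0.05 to 0.50 in steps of 0.05, 10,000
#' simulations per MAF). D values are pooled across the grid and the
#' upper threshold is the empirical `centile` quantile (inverse-ECDF,
#' so `centile = 100` gives the sample maximum); exceedance downstream is
#' strictly greater-than. The mirror `100 - centile` quantile is also
#' reported for collection-enrichment screens, and per-MAF strata are
#' retained so the MAF-invariance of the null can be checked. With a
#' single clustering (`clustering_b = NULL`) the thresholds are computed
#' on T instead.
#'
#' @inheritParams simulate_null_stats
#' @param maf_grid MAF grid, each value in `(0, 0.5]`.
#' @param sims_per_maf simulations per grid point; values below 100 give
#'   an unstable quantile and trigger a warning.
#' @param centile upper percentile defining the threshold (default 99).
#' @return A `threshold_table`: `d_threshold`, `d_lower`, `t_threshold`,
#'   the pooled per-stratum `null` draws, failure counts, and all
#'   settings.
#' @export
estimate_thresholds <- function(y, clustering_a, clustering_b = NULL,
                                W = NULL, link = "logit",
                                maf_grid = seq(0.05, 0.5, by = 0.05),
                                sims_per_maf = 10000, centile = 99,
                                seed = 1) {
  if (any(maf_grid <= 0 | maf_grid > 0.5)) stop("maf_grid values must lie in (0, 0.5]")
  if (sims_per_maf < 100) {
    warning("sims_per_maf < 100: quantile estimates will be unstable")
  }
  if (centile <= 0 || centile > 100) stop("centile must lie in (0, 100]")
  strata <- vector("list", length(maf_grid))
  n_failed <- integer(length(maf_grid))
  for (i in seq_along(maf_grid)) {
    res <- simulate_null_stats(y, clustering_a, clustering_b, W, link,
                               mafs = rep(maf_grid[i], sims_per_maf),
                               seed = seed)
    stat <- if (!is.null(clustering_b)) res$D else res$T_a
    bad <- is.na(stat) | !res$converged
    n_failed[i] <- sum(bad)
    if (n_failed[i] > 0.01 * sims_per_maf) {
      warning(sprintf("MAF %.2f stratum: %d of %d simulated fits failed",
                      maf_grid[i], n_failed[i], sims_per_maf))
    }
    res$stat <- stat
    strata[[i]] <- res
  }
  pooled_d <- unlist(lapply(strata, function(s) s$stat[!is.na(s$stat)]))
  pooled_t <- unlist(lapply(strata, function(s) s$T_a[!is.na(s$T_a)]))
  q <- function(v, p) unname(stats::quantile(v, p, type = 1))
  tab <- structure(list(
    d_threshold = if (!is.null(clustering_b)) q(pooled_d, centile / 100) else NA_real_,
    d_lower = if (!is.null(clustering_b)) q(pooled_d, 1 - centile / 100) else NA_real_,
    t_threshold = q(pooled_t, centile / 100),
    null = strata,
    n_failed = n_failed,
    settings = list(maf_grid = maf_grid, sims_per_maf = sims_per_maf,
                    centile = centile, seed = seed, link = link,
                    n = length(y),
                    K_a = clustering_a$K,
                    K_b = if (!is.null(clustering_b)) clustering_b$K else NA_integer_,
                    single_clustering = is.null(clustering_b))
  ), class = "threshold_table")
  tab
}

#' @export
print.threshold_table <- function(x, ...) {
  s <- x$settings
  cat(sprintf("threshold_table: %d MAFs x %d sims (n=%d, centile=%g, seed=%d)\n",
              length(s$maf_grid), s$sims_per_maf, s$n, s$centile, s$seed))
  if (!s$single_clustering) {
    cat(sprintf("  D threshold (upper %g%%): %.4f   lower: %.4f\n",
                s$centile, x$d_threshold, x$d_lower))
  }
  cat(sprintf("  T threshold (upper %g%%): %.4f\n", s$centile, x$t_threshold))
  if (sum(x$n_failed)) {
    cat(sprintf("  failed fits: %d\n", sum(x$n_failed)))
  }
  invisible(x)
}

#' Write a threshold table to JSON
#'
#' Serialises thresholds, settings and per-stratum quantile summaries
#' (not the raw draws) for downstream runs.
#'
#' @param tab a `threshold_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_thresholds <- function(tab, path) {
  strata <- lapply(seq_along(tab$settings$maf_grid), function(i) {
    s <- tab$null[[i]]$stat
    s <- s[!is.na(s)]
    list(maf = tab$settings$maf_grid[i],
         quantiles = as.list(stats::quantile(s, c(0.01, 0.25, 0.5, 0.75, 0.99))))
  })
  out <- list(d_threshold = tab$d_threshold,
              d_lower = tab$d_lower,
              t_threshold = tab$t_threshold,
              n_failed = tab$n_failed,
              settings = tab$settings,
              strata = strata)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
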