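#' LD-prune markers with a sliding-window pairwise-r2 filter
#'
#' Reproduces the classic `--indep-pairwise` behaviour: markers inside the
#' supplied long-range-LD exclusion regions are removed first, then a
#' window of `window` (default 50) surviving markers slides along each
#' chromosome in steps of `step` (default 5); within each window, while
#' any kept pair has squared Pearson correlation of dosages above
#' `r2_threshold` (default 0.2), one member of the worst pair is removed.
#' The removed member is the one with the lower minor-allele frequency;
#' on a tie, the later-positioned marker goes. r2 is computed on the
#' 0/1/2 dosage scale over pairwise-complete samples.
#'
#' @param ds a [genotype_dataset] with markers ordered by chromosome and
#'   position.
#' @param regions optional `region_list` of exclusion regions.
#' @param r2_threshold,window,step pruning parameters.
#' @return Integer vector of surviving marker indices (into `ds`).
#' @export
prune_markers <- function(ds, regions = NULL, r2_threshold = 0.2,
                          window = 50, step = 5) {
  if (window < 2) stop("window must be at least 2 markers")
  if (step < 1) stop("step must be at least 1")
  m <- ncol(ds$dosages)
  ord <- order(ds$chrom, ds$pos, na.last = TRUE)
  if (any(ord != seq_len(m))) {
    stop("markers must be ordered by chromosome and position")
  }
  excluded <- markers_in_regions(ds$chrom, ds$pos, regions)
  kept <- which(!excluded)
  if (!length(kept)) return(integer(0))
  maf <- apply(ds$dosages[, kept, drop = FALSE], 2, function(g) {
    p <- mean(g, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  alive <- rep(TRUE, length(kept))
  start <- 1L
  repeat {
    idx_alive <- which(alive)
    if (start > length(idx_alive)) break
    win <- idx_alive[seq(start, min(start + window - 1L, length(idx_alive)))]
    if (length(win) >= 2) {
      r <- suppressWarnings(
        stats::cor(ds$dosages[, kept[win], drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- r^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      in_win <- rep(TRUE, length(win))
      repeat {
        r2w <- r2
        r2w[!in_win, ] <- 0
        r2w[, !in_win] <- 0
        mx <- max(r2w)
        if (mx <= r2_threshold) break
        pair <- which(r2w == mx, arr.ind = TRUE)[1, ]
        a <- pair[1]; b <- pair[2]
        # drop the lower-MAF member; tie -> the later-positioned one
        drop_local <- if (maf[win[a]] < maf[win[b]]) a
                      else if (maf[win[b]] < maf[win[a]]) b
                      else max(a, b)
        in_win[drop_local] <- FALSE
        alive[win[drop_local]] <- FALSE
      }
    }
    if (start + window - 1L >= length(idx_alive)) break
    start <- start + step
  }
  kept[alive]
}

#' Fit a PCA basis on genotype dosages
#'
#' EIGENSTRAT-style principal component analysis of the genotype matrix:
#' each marker column is centred by its observed mean and scaled by
#' `sqrt(p(1-p))` where `p = (1 + sum(g)) / (2 + 2 n_called)` is the
#' shrunk allele-frequency estimate; missing entries are replaced by the
#' column mean (zero after centring) before the decomposition. Monomorphic
#' markers are dropped with a warning. Loading signs are fixed
#' deterministically (largest-magnitude loading positive).
#'
#' @param ds a [genotype_dataset].
#' @param markers indices (or ids) of markers to use; typically the output
#'   of [prune_markers]. Defaults to all markers.
#' @param n_components number of components to retain (default 2, the
#'   number of leading components used to define the ancestry space).
#' @return A list with components `basis` (class `pca_basis`: marker ids,
#'   centring/scaling, loadings, eigenvalues) and `scores`
#'   (N x n_components matrix).
#' @export
fit_pca <- function(ds, markers = seq_len(ncol(ds$dosages)), n_components = 2) {
  if (is.character(markers)) markers <- match(markers, ds$marker_ids)
  X <- ds$dosages[, markers, drop = FALSE]
  n <- nrow(X)
  mono <- apply(X, 2, function(g) stats::var(g, na.rm = TRUE) == 0 ||
                  all(is.na(g)))
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s) dropped from PCA")
    X <- X[, !mono, drop = FALSE]
    markers <- markers[!mono]
  }
  if (n_components > min(n, ncol(X))) {
    stop("n_components exceeds min(samples, markers)")
  }
  center <- colMeans(X, na.rm = TRUE)
  n_called <- colSums(!is.na(X))
  p_shrunk <- (1 + colSums(X, na.rm = TRUE)) / (2 + 2 * n_called)
  scale <- sqrt(p_shrunk * (1 - p_shrunk))
  Xn <- sweep(X, 2, center, "-")
  Xn[is.na(Xn)] <- 0
  Xn <- sweep(Xn, 2, scale, "/")
  d <- n_components
  if (ncol(Xn) > n) {
    # wide matrices: eigendecompose the N x N Gram matrix
    G <- tcrossprod(Xn)
    eg <- eigen(G, symmetric = TRUE)
    sv <- sqrt(pmax(eg$values[seq_len(d)], 0))
    U <- eg$vectors[, seq_len(d), drop = FALSE]
    V <- crossprod(Xn, U) %*% diag(1 / sv, d)
    scores <- U %*% diag(sv, d)
    evals <- eg$values[seq_len(d)]
  } else {
    sv <- svd(Xn, nu = d, nv = d)
    V <- sv$v
    scores <- sv$u %*% diag(sv$d[seq_len(d)], d)
    evals <- sv$d[seq_len(d)]^2
  }
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(d)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(d))
  rownames(scores) <- ds$sample_ids
  basis <- structure(list(
    marker_ids = ds$marker_ids[markers],
    center = unname(center),
    scale = unname(scale),
    loadings = unname(V),
    eigenvalues = evals
  ), class = "pca_basis")
  list(basis = basis, scores = scores)
}

#' Project samples onto a fitted PCA basis
#'
#' Applies the basis's stored centring and scaling and multiplies by the
#' stored loadings; the basis is never refitted, so projections of an
#' independent dataset share the fitting data's sign convention. Missing
#' dosages are mean-imputed (to the *fitting* means). Used to check that
#' components computed in one phase represent ancestry rather than a
#' collection artefact in another.
#'
#' @param ds a [genotype_dataset] containing every basis marker.
#' @param basis a `pca_basis` from [fit_pca].
#' @return N x n_components score matrix.
#' @export
project_pca <- function(ds, basis) {
  idx <- match(basis$marker_ids, ds$marker_ids)
  if (anyNA(idx)) {
    stop("dataset is missing basis marker(s): ",
         paste(utils::head(basis$marker_ids[is.na(idx)], 10), collapse = ", "))
  }
  X <- ds$dosages[, idx, drop = FALSE]
  Xn <- sweep(X, 2, basis$center, "-")
  Xn[is.na(Xn)] <- 0
  Xn <- sweep(Xn, 2, basis$scale, "/")
  scores <- Xn %*% basis$loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- ds$sample_ids
  scores
}

# Exposure clustering container: exposure matrix E, hard assignment and its
# one-hot indicator Z. Every downstream model consumes Z.
new_exposure_clustering <- function(E, assignment, source = "custom") {
  assignment <- as.integer(assignment)
  K <- max(assignment)
  n <- length(assignment)
  if (any(tabulate(assignment, K) == 0)) stop("every cluster must be non-empty")
  Z <- matrix(0, n, K)
  Z[cbind(seq_len(n), assignment)] <- 1
  colnames(Z) <- paste0("c", seq_len(K))
  structure(list(E = E, K = K, Z = Z, assignment = assignment,
                 source = source), class = "exposure_clustering")
}

#' @export
print.exposure_clustering <- function(x, ...) {
  cat(sprintf("exposure_clustering (%s): %d samples in %d cluster(s): %s\n",
              x$source, length(x$assignment), x$K,
              paste(tabulate(x$assignment, x$K), collapse = ", ")))
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, later
# centres with probability proportional to squared distance to the
# nearest chosen centre.
.kmpp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ], "-")^2))
  }
  centers
}

# BIC of a hard clustering scored as an axis-aligned Gaussian mixture
# with per-dimension variances shared across clusters: classification
# log-likelihood (including the multinomial mixing-weight term) penalised
# with k*d + d parameters. Sharing a per-dimension (rather than a single
# spherical) variance stops the criterion from slicing clusters that are
# tight on the structured component but wide on a noise component - the
# generic shape of PC scores, where trailing components are pure noise
# with larger spread than the within-cluster spread of the leading one.
.kmeans_bic <- function(km, X, n, d) {
  k <- nrow(km$centers)
  resid <- X - km$centers[km$cluster, , drop = FALSE]
  sigma2 <- pmax(colSums(resid^2) / n, .Machine$double.eps)
  ll <- -n / 2 * sum(log(2 * pi * sigma2)) - n * d / 2 +
    sum(km$size * log(km$size / n))
  -2 * ll + (k * d + d) * log(n)
}

#' Cluster samples into ancestry groups
#'
#' Runs k-means (k-means++ initialization, `n_restarts` seeded restarts,
#' best within-cluster SSE kept, ties broken by the earliest restart) for
#' each k in `k_min:k_max` on the PC-score matrix, scores each clustering
#' with a Gaussian-mixture BIC (axis-aligned, per-dimension variances
#' shared across clusters), and returns the clustering with minimal BIC.
#' Restart seeds are derived deterministically from `seed`, so the BIC
#' curve is reproducible.
#'
#' @param scores N x d matrix of exposure coordinates (usually leading PC
#'   scores from [fit_pca]).
#' @param k_min,k_max cluster-count range searched; `k_min` defaults to 2
#'   because heterogeneity testing needs at least two groups.
#' @param seed integer master seed.
#' @param n_restarts k-means restarts per k (default 25).
#' @return An `exposure_clustering` with source `"ancestry"`; the per-k
#'   BIC table is attached as `$bic_table`.
#' @export
cluster_ancestry <- function(scores, k_min = 2, k_max = 6, seed = 1,
                             n_restarts = 25) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  d <- ncol(scores)
  if (k_min < 1 || k_max < k_min) stop("need 1 <= k_min <= k_max")
  if (n < k_max) stop("fewer samples than k_max clusters")
  ks <- k_min:k_max
  fits <- vector("list", length(ks))
  bics <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(mix_seed(seed, k, r))
      km <- tryCatch({
        init <- .kmpp_init(scores, k)
        stats::kmeans(scores, centers = init, iter.max = 100)
      }, error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) {
      stop("k-means failed to produce ", k,
           " non-empty clusters after ", n_restarts, " restarts")
    }
    fits[[i]] <- best
    bics[i] <- .kmeans_bic(best, scores, n, d)
  }
  sel <- which.min(bics)  # ties resolve to the smaller k
  cl <- new_exposure_clustering(scores, fits[[sel]]$cluster, source = "ancestry")
  cl$bic_table <- data.frame(k = ks, bic = bics)
  cl$centers <- fits[[sel]]$centers
  cl
}

#' Clustering defined by an existing label
#'
#' Wraps a factor of hard labels as an `exposure_clustering` (one-hot
#' indicator, K = number of levels). No algorithm is involved.
#'
#' @param labels factor (or coercible) of group labels.
#' @param source one of `"collection"`, `"ancestry"`, `"custom"`.
#' @return An `exposure_clustering`.
#' @export
label_clustering <- function(labels, source = "custom") {
  f <- as.factor(labels)
  f <- droplevels(f)
  E <- matrix(as.numeric(f), ncol = 1)
  cl <- new_exposure_clustering(E, as.integer(f), source = source)
  cl$levels <- levels(f)
  colnames(cl$Z) <- levels(f)
  cl
}

#' Collection clustering of a dataset
#'
#' The design-fixed grouping: the one-hot encoding of the dataset's
#' collection factor, with K equal to the number of collection labels.
#'
#' @param ds a [genotype_dataset].
#' @return An `exposure_clustering` with source `"collection"`.
#' @export
collection_clustering <- function(ds) {
  label_clustering(ds$collection, source = "collection")
}

#' Switch rate between two clusterings
#'
#' The proportion of samples whose labels disagree between two clusterings
#' of the same samples, minimised over all matchings of cluster labels
#' (so the measure is invariant to label permutation). Requires equal K.
#'
#' @param a,b `exposure_clustering` objects over the same samples.
#' @return A proportion in `[0, 1]`.
#' @export
switch_rate <- function(a, b) {
  if (a$K != b$K) {
    stop("switch rate requires clusterings with the same number of clusters (",
         a$K, " vs ", b$K, ")")
  }
  n <- length(a$assignment)
  if (n != length(b$assignment)) stop("clusterings cover different samples")
  K <- a$K
  if (K > 8) stop("switch rate only supported for K <= 8")
  tab <- table(factor(a$assignment, levels = seq_len(K)),
               factor(b$assignment, levels = seq_len(K)))
  perms <- all_permutations(K)
  agree <- apply(perms, 1, function(p) sum(tab[cbind(seq_len(K), p)]))
  1 - max(agree) / n
}
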