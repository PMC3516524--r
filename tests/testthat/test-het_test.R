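test_that("logistic MLE matches the 2x2 cross-product oracle", {
  # cases 30/70 exposed/unexposed, controls 10/90
  y <- c(rep(1, 100), rep(0, 100))
  x <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  fit <- fit_glm(y, cbind(intercept = 1, x = x), "logit")
  expect_equal(unname(fit$coefficients["x"]), log((30 * 90) / (70 * 10)),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$bic, -2 * fit$log_likelihood + 2 * log(200))
})

test_that("a null marker at large n gives a small estimate and z", {
  set.seed(12)
  n <- 5000
  y <- rbinom(n, 1, 0.5)
  x <- rbinom(n, 2, 0.3)
  fit <- fit_glm(y, cbind(1, x = x), "logit")
  z <- fit$coefficients["x"] / fit$se["x"]
  expect_lt(abs(fit$coefficients["x"]), 0.1)
  expect_lt(abs(z), 3.5)
})

test_that("identity-link fit reproduces ordinary least squares", {
  set.seed(13)
  n <- 120
  X <- cbind(1, a = rnorm(n), b = rbinom(n, 2, 0.4))
  y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(n)
  fit <- fit_glm(y, X, "identity")
  ols <- qr.solve(X, y)  # normal-equations oracle
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-8)
  # residual variance counts as a BIC parameter for the identity link
  expect_equal(fit$n_params, ncol(X) + 1)
  expect_equal(fit$bic, -2 * fit$log_likelihood + fit$n_params * log(n))
})

test_that("rank deficiency errors with the collinear column named", {
  y <- rep(c(0, 1), 20)
  X <- cbind(one = 1, dup = 1, x = rnorm(40))
  expect_error(fit_glm(y, X, "logit"), "dup")
})

test_that("complete separation is capped and flagged, not fatal", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rep(0, 20), rep(1, 20))
  fit <- fit_glm(y, cbind(1, x = x), "logit")
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_lte(max(abs(fit$coefficients)), 15)
})

test_that("design matrices have the documented shapes and partition identity", {
  set.seed(14)
  n <- 40
  x <- rbinom(n, 2, 0.3)
  cl <- label_clustering(rep(1:2, each = n / 2))
  W <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "age"))
  dz <- build_designs(x, cl, W)
  expect_equal(ncol(dz$X_het), 5)   # K=2, q=1: 2 + 2 + 1
  expect_equal(ncol(dz$X_null), 4)  # K + 1 + q
  expect_equal(ncol(dz$X_het) - ncol(dz$X_null), cl$K - 1)
  # cluster-specific genotype columns sum to the shared column
  expect_equal(rowSums(dz$X_het[, c("beta_1", "beta_2")]),
               unname(dz$X_null[, "beta"]))

  # K = 1 degenerates to identical designs
  cl1 <- label_clustering(rep(1, n))
  dz1 <- build_designs(x, cl1)
  expect_equal(unname(dz1$X_het), unname(dz1$X_null))

  # missing dosage drops the same rows from both designs
  x[3] <- NA
  dzm <- build_designs(x, cl, W)
  expect_equal(nrow(dzm$X_het), n - 1)
  expect_equal(nrow(dzm$X_het), nrow(dzm$X_null))

  # a near-empty cluster skips the marker
  xs <- x; xs[cl$assignment == 2] <- NA
  xs[which(cl$assignment == 2)[1]] <- 1
  expect_error(build_designs(xs, cl), class = "marker_skip")
})

test_that("T vanishes for one cluster and hits -log(n) for duplicated clusters", {
  ds <- tiny_dataset(n = 80, m = 3, seed = 15)
  cl1 <- label_clustering(rep(1, 80))
  expect_equal(t_statistic(ds, 1, cl1)$T, 0)

  # cluster 2 an exact copy of cluster 1's rows: cluster-wise MLEs coincide
  # with the shared MLE, so T = -(K-1) log(n)
  half <- tiny_dataset(n = 40, m = 2, seed = 16)
  dup <- genotype_dataset(rbind(half$dosages, half$dosages),
                          y = rep(half$y, 2),
                          collection = rep(c("A", "B"), each = 40),
                          sample_ids = sprintf("T%03d", 1:80))
  tt <- t_statistic(dup, 1, collection_clustering(dup))
  expect_equal(tt$T, -log(80), tolerance = 1e-6)
})

test_that("likelihood nesting and the T identity hold across random markers", {
  nd <- null_scan_dataset(n = 300, m = 25, seed = 17)
  cl <- nd$scenario$clustering_anc
  for (j in seq(1, 25, by = 3)) {
    tt <- t_statistic(nd$ds, j, cl, W = nd$scenario$W)
    # null is nested in the heterogeneous model
    expect_gte(tt$het_fit$log_likelihood, tt$null_fit$log_likelihood - 1e-8)
    # T == 2 dLL - (K-1) log n
    expect_equal(tt$T,
                 2 * (tt$het_fit$log_likelihood - tt$null_fit$log_likelihood) -
                   (cl$K - 1) * log(tt$het_fit$n_used),
                 tolerance = 1e-9)
    expect_equal(tt$het_fit$n_used, tt$null_fit$n_used)
  }
})

test_that("the difference statistic is zero for equal clusterings and antisymmetric", {
  expect_equal(d_statistic(3.2, 3.2), 0)
  expect_equal(d_statistic(1.5, -2), -d_statistic(-2, 1.5))

  nd <- null_scan_dataset(n = 200, m = 4, seed = 18)
  ta <- t_statistic(nd$ds, 1, nd$scenario$clustering_anc)$T
  expect_equal(d_statistic(ta, ta), 0)
})

test_that("quantitative traits run through the identity link", {
  set.seed(19)
  n <- 300
  cl <- label_clustering(rep(1:2, each = n / 2))
  x <- rbinom(n, 2, 0.3)
  y <- 0.5 * (cl$assignment == 2) + ifelse(cl$assignment == 1, -0.4, 0) * x + rnorm(n)
  ds <- genotype_dataset(cbind(mk = x), y = y,
                         collection = factor(c("A", "B")[cl$assignment]))
  tt <- t_statistic(ds, 1, cl, link = "identity")
  expect_true(is.finite(tt$T))
  expect_gt(tt$T, 0)  # strong simulated heterogeneity is detected
  # identity-link variance parameter cancels in T
  expect_equal(tt$het_fit$n_params - tt$null_fit$n_params, cl$K - 1)
})
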