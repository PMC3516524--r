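test_that("perfect-LD duplicates are pruned and independent markers survive", {
  set.seed(7)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  dos <- cbind(g, g, rbinom(n, 2, 0.4))
  ds <- genotype_dataset(dos, y = rep(c(0, 1), n / 2),
                         collection = rep("A", n),
                         marker_ids = c("a", "b", "c"),
                         chrom = rep("1", 3), pos = c(100, 200, 300))
  kept <- prune_markers(ds, r2_threshold = 0.2, window = 3, step = 1)
  expect_length(intersect(kept, 1:2), 1)  # exactly one of the r2=1 pair
  expect_true(3 %in% kept)

  # independent markers: brute-force all-pairs r2 oracle says all survive
  set.seed(8)
  dos2 <- sapply(runif(30, 0.2, 0.5), function(p) rbinom(500, 2, p))
  r2 <- cor(dos2)^2; diag(r2) <- 0
  expect_lt(max(r2), 0.2)  # oracle: no pair violates
  ds2 <- genotype_dataset(dos2, y = rep(c(0, 1), 250), collection = rep("A", 500),
                          chrom = rep("1", 30), pos = seq_len(30))
  expect_equal(prune_markers(ds2), seq_len(30))

  expect_error(prune_markers(ds2, window = 1), "window")
  expect_error(prune_markers(ds2, step = 0), "step")
})

test_that("markers inside exclusion regions are removed before LD pruning", {
  ds <- tiny_dataset(n = 100, m = 5, seed = 3)  # pos = 1000, 2000, ..., 5000
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("1 1500 2500", bed)
  kept <- prune_markers(ds, read_regions(bed))
  expect_false(2 %in% kept)  # pos 2000 is inside [1500, 2500)
  expect_true(all(c(1, 3, 4, 5) %in% kept))
})

test_that("PCA separates ideal populations and matches a dense decomposition oracle", {
  # rank-1 structure: two ideal populations, no noise, plus 2 noise markers
  pop <- rep(1:2, each = 30)
  m_struct <- 6
  dos <- cbind(matrix(ifelse(pop == 1, 0, 2), 60, m_struct),
               matrix(rbinom(120, 2, 0.5), 60, 2))
  set.seed(2)
  dos[, m_struct + 1] <- rbinom(60, 2, 0.4)
  ds <- genotype_dataset(dos, y = rep(c(0, 1), 30), collection = rep("A", 60))
  fp <- fit_pca(ds, n_components = 2)

  # oracle: same normalization done longhand, then base eigen()
  X <- ds$dosages
  ctr <- colMeans(X)
  p_sh <- (1 + colSums(X)) / (2 + 2 * nrow(X))
  Xn <- sweep(sweep(X, 2, ctr), 2, sqrt(p_sh * (1 - p_sh)), "/")
  eg <- eigen(tcrossprod(Xn), symmetric = TRUE)
  expect_equal(fp$basis$eigenvalues, eg$values[1:2], tolerance = 1e-8)
  expect_gt(eg$values[1] / eg$values[2], 5)  # structure dominates
  expect_equal(abs(cor(fp$scores[, 1], eg$vectors[, 1])), 1, tolerance = 1e-8)
  # score sign separates the populations
  expect_true(all(sign(fp$scores[pop == 1, 1]) != sign(fp$scores[pop == 2, 1])))

  # loadings orthonormal, scores centred on the fitting data
  V <- fp$basis$loadings
  expect_equal(crossprod(V), diag(2), tolerance = 1e-8)
  expect_equal(colMeans(fp$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-8)
})

test_that("row-duplicated data yields row-duplicated scores and monomorphic markers drop", {
  ds <- tiny_dataset(n = 40, m = 12, seed = 5)
  dup <- genotype_dataset(rbind(ds$dosages, ds$dosages),
                          y = rep(ds$y, 2),
                          collection = rep(ds$collection, 2),
                          sample_ids = sprintf("D%03d", 1:80))
  fp <- fit_pca(dup, n_components = 2)
  expect_equal(unname(fp$scores[1:40, ]), unname(fp$scores[41:80, ]),
               tolerance = 1e-8)

  mono <- ds
  dosm <- ds$dosages; dosm[, 1] <- 1
  dsm <- genotype_dataset(dosm, y = ds$y, collection = ds$collection)
  expect_warning(fpm <- fit_pca(dsm, n_components = 2), "monomorphic")
  expect_false("rs001" %in% fpm$basis$marker_ids ||
                 length(fpm$basis$marker_ids) == ncol(dosm))
})

test_that("projection applies the stored basis without refitting", {
  ds <- tiny_dataset(n = 50, m = 20, seed = 6)
  fp <- fit_pca(ds, n_components = 2)
  # self-projection identity
  expect_equal(project_pca(ds, fp$basis), fp$scores, tolerance = 1e-10)
  # single-sample projection equals the matching row of batch projection
  one <- genotype_dataset(rbind(ds$dosages[c(3, 3), ]), y = c(0, 1),
                          collection = c("A", "A"),
                          marker_ids = ds$marker_ids,
                          sample_ids = c("a", "b"))
  expect_equal(unname(project_pca(one, fp$basis)[1, ]),
               unname(fp$scores[3, ]), tolerance = 1e-10)
  # missing basis markers are named
  ds_drop <- tiny_dataset(n = 50, m = 10, seed = 6)
  expect_error(project_pca(ds_drop, fp$basis), "rs011")
})

test_that("projection of an independent draw keeps the fitted sign convention", {
  tp <- make_two_phase(sim_config(n_per_population = 250, n_markers = 1500,
                                  fst = 0.01, seed = 21),
                       sim_config(n_per_population = 250, n_markers = 1500,
                                  fst = 0.01, seed = 22))
  fp <- fit_pca(tp$phase1$dataset, n_components = 2)
  s2 <- project_pca(tp$phase2$dataset, fp$basis)
  m1 <- tapply(fp$scores[, 1], tp$phase1$truth$population, mean)
  m2 <- tapply(s2[, 1], tp$phase2$truth$population, mean)
  # populations separate in both phases, with the same orientation
  expect_gt(abs(m1[1] - m1[2]), 6 * sd(fp$scores[tp$phase1$truth$population == 1, 1]))
  expect_equal(sign(m1[1] - m1[2]), sign(m2[1] - m2[2]))
})

test_that("k-means/BIC selects two clusters for two blobs and the floor for one", {
  X2 <- two_blob_scores(n_per = 200, seed = 31)
  cl <- cluster_ancestry(X2, k_min = 2, k_max = 6, seed = 1)
  expect_equal(cl$K, 2)
  truth <- rep(1:2, each = 200)
  expect_equal(switch_rate(cl, label_clustering(truth)), 0)  # every point correct

  set.seed(32)
  X1 <- cbind(rnorm(300), rnorm(300))
  expect_equal(cluster_ancestry(X1, k_min = 2, k_max = 5, seed = 1)$K, 2)

  # permutation of input rows permutes the assignment consistently
  perm <- sample(nrow(X2))
  clp <- cluster_ancestry(X2[perm, ], k_min = 2, k_max = 6, seed = 1)
  expect_equal(switch_rate(clp, label_clustering(truth[perm])), 0)

  expect_error(cluster_ancestry(X2[1:4, ], k_min = 2, k_max = 6), "fewer samples")
})

test_that("BIC curve is deterministic given the seed", {
  X <- two_blob_scores(n_per = 100, seed = 33)
  a <- cluster_ancestry(X, 2, 4, seed = 9)
  b <- cluster_ancestry(X, 2, 4, seed = 9)
  expect_identical(a$bic_table, b$bic_table)
  expect_identical(a$assignment, b$assignment)
})

test_that("collection clustering is the one-hot of the label factor", {
  ds <- tiny_dataset(n = 20, m = 2)
  cl <- collection_clustering(ds)
  expect_equal(cl$K, 2)
  expect_true(all(rowSums(cl$Z) == 1))
  expect_equal(colnames(cl$Z), c("A", "B"))

  ds1 <- genotype_dataset(matrix(rbinom(20, 2, .4), 10, 2), y = rep(c(0, 1), 5),
                          collection = rep("only", 10))
  expect_equal(collection_clustering(ds1)$K, 1)
})

test_that("switch rate is the permutation-minimal disagreement and is symmetric", {
  a <- label_clustering(rep(1:2, each = 50))
  expect_equal(switch_rate(a, a), 0)
  # label swap is still a perfect match
  b <- label_clustering(rep(2:1, each = 50))
  expect_equal(switch_rate(a, b), 0)

  # 10 of 100 samples moved across: exhaustive-permutation oracle gives 0.10
  moved <- rep(1:2, each = 50); moved[1:10] <- 2
  m <- label_clustering(moved)
  tab <- table(a$assignment, m$assignment)
  oracle <- 1 - max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / 100
  expect_equal(oracle, 0.10)
  expect_equal(switch_rate(a, m), 0.10)
  expect_equal(switch_rate(m, a), switch_rate(a, m))

  expect_error(switch_rate(a, label_clustering(rep(1:4, 25))), "same number")
})

test_that("generator truth labels recover the injected label-switch rate", {
  cfg <- sim_config(n_per_population = 1000, n_markers = 2, seed = 55,
                    label_switch_rate = 0.2)
  sim <- simulate_dataset(cfg)
  anc <- label_clustering(sim$truth$population, "ancestry")
  sr <- switch_rate(anc, collection_clustering(sim$dataset))
  expect_lt(abs(sr - 0.2), 0.03)
})
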