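test_that("configurations validate their fields", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(label_switch_rate = 0.7), "switch_rate")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(n_markers = 5,
                          causal = data.frame(index = 9, or1 = 1, or2 = 1)),
               "indices")
})

test_that("one master seed fixes the dataset byte-for-byte through write_dataset", {
  cfg <- sim_config(n_per_population = 60, n_markers = 12, seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$dosages, s2$dataset$dosages)
  expect_identical(s1$truth$population, s2$truth$population)
  f1 <- withr::local_tempfile(fileext = ".raw")
  f2 <- withr::local_tempfile(fileext = ".raw")
  write_dataset(s1$dataset, f1)
  write_dataset(s2$dataset, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("undifferentiated populations show no PC separation", {
  cfg <- sim_config(n_per_population = 150, n_markers = 800, fst = 0,
                    seed = 101)
  sim <- simulate_dataset(cfg)
  fp <- fit_pca(sim$dataset, n_components = 2)
  pop <- sim$truth$population
  # standardized mean separation on PC1 is noise-level
  sep <- abs(mean(fp$scores[pop == 1, 1]) - mean(fp$scores[pop == 2, 1])) /
    sd(fp$scores[, 1])
  expect_lt(sep, 0.4)
})

test_that("empirical allele frequencies converge to the drawn Beta frequencies", {
  cfg <- sim_config(n_per_population = 2500, n_markers = 25, fst = 0.01,
                    seed = 102)
  sim <- simulate_dataset(cfg)
  pop <- sim$truth$population
  for (p in 1:2) {
    emp <- colMeans(sim$dataset$dosages[pop == p, ]) / 2
    f <- sim$truth$pop_freqs[p, ]
    # binomial band: 4 SEs on 2n draws per marker
    band <- 4 * sqrt(f * (1 - f) / (2 * sum(pop == p)))
    expect_true(all(abs(emp - f) < pmax(band, 0.015)))
  }
})

test_that("ascertainment honours the case:control ratio and prevalence ordering", {
  cfg <- sim_config(n_per_population = 300, n_markers = 4,
                    case_control_ratio = 2, seed = 103)
  sim <- simulate_dataset(cfg)
  expect_equal(sum(sim$dataset$y == 1), 2 * sum(sim$dataset$y == 0))
  expect_equal(nrow(sim$dataset$dosages), 600)

  expect_error(simulate_dataset(sim_config(n_per_population = 200,
                                           n_markers = 2,
                                           prevalence = c(1e-6, 1e-6),
                                           seed = 104)),
               "infeasible ascertainment")
})

test_that("two phases share the marker panel but not samples", {
  cfg1 <- sim_config(n_per_population = 80, n_markers = 20, seed = 105,
                     causal = data.frame(index = 10, or1 = 0.7, or2 = 1))
  cfg2 <- sim_config(n_per_population = 50, n_markers = 20, seed = 106,
                     causal = data.frame(index = 10, or1 = 0.7, or2 = 1))
  tp <- make_two_phase(cfg1, cfg2, marker_subset = 1:15)
  expect_length(intersect(tp$phase1$dataset$sample_ids,
                          tp$phase2$dataset$sample_ids), 0)
  expect_equal(tp$phase2$dataset$marker_ids, tp$phase1$dataset$marker_ids[1:15])
  # same realized population frequencies drive both phases
  expect_equal(tp$phase2$truth$pop_freqs,
               tp$phase1$truth$pop_freqs[, 1:15])
  # causal marker outside the phase 2 panel is an error
  cfg3 <- cfg2; cfg3$causal$index <- 18
  expect_error(make_two_phase(cfg1, cfg3, marker_subset = 1:15),
               "inside the phase 2 panel")
  expect_error(make_two_phase(cfg1, cfg2, marker_subset = c(1, 25)),
               "subset")
})

test_that("collection-scope effects follow the label, not the population", {
  # with a collection-scope effect and truth clustering, the estimated
  # per-collection effects should separate while per-population ones shrink
  cfg <- sim_config(n_per_population = 3000, n_markers = 1, seed = 107,
                    maf_range = c(0.3, 0.3), label_switch_rate = 0.2,
                    causal = data.frame(index = 1, or1 = 0.6, or2 = 1.0),
                    effect_scope = "collection")
  sim <- simulate_dataset(cfg)
  coll <- collection_clustering(sim$dataset)
  tt <- t_statistic(sim$dataset, 1, coll)
  b <- tt$het_fit$coefficients
  expect_lt(b[["beta_1"]], log(0.75))  # coll_A carries the protective effect
  expect_gt(b[["beta_2"]], log(0.9))
})
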