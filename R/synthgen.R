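#' Configuration for the structured-GWAS generator
#'
#' Describes a two-population case-control study with Balding-Nichols
#' allele-frequency differentiation, population-specific baseline disease
#' risk, optional causal markers with group-specific odds ratios, and a
#' collection label that disagrees with the true population for a
#' configured fraction of samples.
#'
#' @param n_per_population samples ascertained per population.
#' @param n_markers number of independent markers.
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`;
#'   the default 0.005 emulates closely related populations whose
#'   separation only emerges on the leading principal components.
#' @param maf_range bounds of the uniform ancestral-MAF distribution.
#' @param causal data frame with columns `index`, `or1`, `or2`: marker
#'   index plus the per-group per-allele odds ratios (e.g. 0.9 and 1.0
#'   for a group-1-specific protective effect). `NULL` for a fully null
#'   panel.
#' @param prevalence length-2 baseline (genotype 0) disease probability
#'   per population.
#' @param label_switch_rate probability that a sample's collection label
#'   disagrees with its true population, in `[0, 0.5]`.
#' @param case_control_ratio cases per control in the ascertained sample.
#' @param effect_scope `"ancestry"` (causal odds ratios follow the true
#'   population) or `"collection"` (they follow the collection label -
#'   a pure collection artefact for testing the sign of D).
#' @param seed integer master seed; fixes the dataset byte-for-byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_population = 1000, n_markers = 100,
                       fst = 0.005, maf_range = c(0.05, 0.5),
                       causal = NULL, prevalence = c(0.1, 0.1),
                       label_switch_rate = 0.2, case_control_ratio = 1,
                       effect_scope = c("ancestry", "collection"),
                       seed = 1) {
  effect_scope <- match.arg(effect_scope)
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (label_switch_rate < 0 || label_switch_rate > 0.5) {
    stop("label_switch_rate must lie in [0, 0.5]")
  }
  if (length(prevalence) == 1) prevalence <- rep(prevalence, 2)
  if (any(prevalence <= 0 | prevalence >= 1)) stop("prevalence must lie in (0, 1)")
  if (!is.null(causal)) {
    causal <- as.data.frame(causal)
    if (!all(c("index", "or1", "or2") %in% names(causal))) {
      stop("causal needs columns index, or1, or2")
    }
    if (any(causal$index < 1 | causal$index > n_markers)) {
      stop("causal marker indices must lie in 1..n_markers")
    }
  }
  structure(list(n_per_population = n_per_population, n_markers = n_markers,
                 fst = fst, maf_range = maf_range, causal = causal,
                 prevalence = prevalence,
                 label_switch_rate = label_switch_rate,
                 case_control_ratio = case_control_ratio,
                 effect_scope = effect_scope, seed = seed),
            class = "sim_config")
}

# Balding-Nichols population frequencies: Beta(p0 (1-F)/F, (1-p0)(1-F)/F)
# around each ancestral frequency; F = 0 degenerates to identical
# populations.
.draw_freqs <- function(cfg) {
  set.seed(mix_seed(cfg$seed, 1))
  m <- cfg$n_markers
  p0 <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  if (cfg$fst == 0) {
    freqs <- rbind(p0, p0)
  } else {
    a <- p0 * (1 - cfg$fst) / cfg$fst
    b <- (1 - p0) * (1 - cfg$fst) / cfg$fst
    freqs <- rbind(stats::rbeta(m, a, b), stats::rbeta(m, a, b))
  }
  freqs <- pmin(pmax(freqs, 1e-6), 1 - 1e-6)
  rownames(freqs) <- c("pop1", "pop2")
  list(p0 = p0, freqs = freqs)
}

# Ascertain one population's cases and controls by rejection sampling
# from the population disease model. Only causal genotypes are drawn
# before acceptance; disease is independent of the remaining markers, so
# they are filled in afterwards.
.ascertain_pop <- function(cfg, freqs, pop, n_cases, n_controls) {
  cz <- cfg$causal
  n_causal <- if (is.null(cz)) 0L else nrow(cz)
  got_case <- list(); got_ctrl <- list()
  n_case_have <- 0L; n_ctrl_have <- 0L
  prev <- cfg$prevalence[pop]
  max_draws <- min(5e6, ceiling(50 * (n_cases / prev + n_controls / (1 - prev)))) + 1e4
  drawn <- 0L
  batch <- min(200000L, max(2000L, 4L * ceiling(n_cases / prev)))
  while (n_case_have < n_cases || n_ctrl_have < n_controls) {
    if (drawn > max_draws) {
      stop("infeasible ascertainment: could not collect ", n_cases, " cases / ",
           n_controls, " controls for population ", pop,
           "; increase n or the baseline prevalence")
    }
    drawn <- drawn + batch
    coll_other <- stats::runif(batch) < cfg$label_switch_rate
    collection <- ifelse(coll_other, 3L - pop, pop)
    eta <- rep(logit(prev), batch)
    G <- NULL
    if (n_causal > 0) {
      G <- matrix(0, batch, n_causal)
      for (j in seq_len(n_causal)) {
        G[, j] <- stats::rbinom(batch, 2, freqs[pop, cz$index[j]])
        scope_grp <- if (cfg$effect_scope == "ancestry") rep(pop, batch) else collection
        lor <- ifelse(scope_grp == 1L, log(cz$or1[j]), log(cz$or2[j]))
        eta <- eta + lor * G[, j]
      }
    }
    disease <- stats::rbinom(batch, 1, expit(eta))
    take_case <- which(disease == 1)[seq_len(min(sum(disease == 1), n_cases - n_case_have))]
    take_ctrl <- which(disease == 0)[seq_len(min(sum(disease == 0), n_controls - n_ctrl_have))]
    pack <- function(idx, yval) {
      if (!length(idx)) return(NULL)
      list(y = rep(yval, length(idx)), collection = collection[idx],
           G = if (is.null(G)) NULL else G[idx, , drop = FALSE])
    }
    pc <- pack(take_case, 1); p0 <- pack(take_ctrl, 0)
    if (!is.null(pc)) { got_case[[length(got_case) + 1]] <- pc; n_case_have <- n_case_have + length(pc$y) }
    if (!is.null(p0)) { got_ctrl[[length(got_ctrl) + 1]] <- p0; n_ctrl_have <- n_ctrl_have + length(p0$y) }
  }
  all_parts <- c(got_case, got_ctrl)
  y <- unlist(lapply(all_parts, `[[`, "y"))
  collection <- unlist(lapply(all_parts, `[[`, "collection"))
  Gc <- if (n_causal > 0) do.call(rbind, lapply(all_parts, `[[`, "G")) else NULL
  n <- length(y)
  # non-causal markers drawn post-acceptance (independent of disease)
  dos <- matrix(stats::rbinom(n * cfg$n_markers, 2,
                              rep(freqs[pop, ], each = n)),
                nrow = n)
  if (n_causal > 0) dos[, cz$index] <- Gc
  list(y = y, collection = collection, dosages = dos,
       population = rep(pop, n))
}

#' Simulate a structured case-control GWAS dataset with known truth
#'
#' Generates a two-population dataset under the configuration from
#' [sim_config]: ancestral MAFs are drawn uniformly, population MAFs
#' follow the Balding-Nichols Beta model, genotypes are in
#' Hardy-Weinberg proportions within population, disease status follows
#' a logistic model with population-specific baseline risk and
#' group-specific log-odds at the causal markers, and cases/controls are
#' ascertained by rejection sampling to the configured ratio. The
#' collection label equals the true population flipped independently
#' with probability `label_switch_rate`. Markers are independent given
#' population (no LD is simulated).
#'
#' @param cfg a [sim_config].
#' @param id_prefix prefix for generated sample ids.
#' @return List with `dataset` (a [genotype_dataset], including a
#'   `gender` covariate with no phenotype effect) and `truth` (class
#'   `sim_truth`: true population per sample, realized per-population
#'   allele frequencies, ancestral frequencies, causal table).
#' @export
simulate_dataset <- function(cfg, id_prefix = "S") {
  stopifnot(inherits(cfg, "sim_config"))
  fr <- .draw_freqs(cfg)
  .simulate_samples(cfg, fr, id_prefix)
}

.simulate_samples <- function(cfg, fr, id_prefix = "S") {
  set.seed(mix_seed(cfg$seed, 2))
  ratio <- cfg$case_control_ratio
  n_cases_pop <- round(cfg$n_per_population * ratio / (1 + ratio))
  n_ctrl_pop <- cfg$n_per_population - n_cases_pop
  pops <- lapply(1:2, function(p)
    .ascertain_pop(cfg, fr$freqs, p, n_cases_pop, n_ctrl_pop))
  y <- c(pops[[1]]$y, pops[[2]]$y)
  collection <- c(pops[[1]]$collection, pops[[2]]$collection)
  population <- c(pops[[1]]$population, pops[[2]]$population)
  dos <- rbind(pops[[1]]$dosages, pops[[2]]$dosages)
  n <- length(y)
  perm <- sample.int(n)
  y <- y[perm]; collection <- collection[perm]
  population <- population[perm]; dos <- dos[perm, , drop = FALSE]
  gender <- stats::rbinom(n, 1, 0.5)
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  ds <- genotype_dataset(
    dos, y = y,
    collection = factor(c("coll_A", "coll_B")[collection]),
    W = matrix(gender, ncol = 1, dimnames = list(NULL, "gender")),
    sample_ids = ids,
    marker_ids = sprintf("mk%05d", seq_len(cfg$n_markers)),
    chrom = rep("1", cfg$n_markers),
    pos = seq_len(cfg$n_markers) * 5000)
  truth <- structure(list(population = population,
                          pop_freqs = fr$freqs,
                          ancestral_maf = fr$p0,
                          causal = cfg$causal,
                          config = cfg), class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' Simulate two discovery phases sharing a marker panel
#'
#' Independent sample draws from the same realized population allele
#' frequencies (and the same causal structure), mirroring a two-phase
#' discovery design. Phase 2 may genotype a subset of the phase 1 panel.
#'
#' @param cfg phase 1 [sim_config].
#' @param cfg2 phase 2 [sim_config]; its marker panel is
#'   `marker_subset` of phase 1's. Causal indices refer to the phase 1
#'   panel and must survive the subset.
#' @param marker_subset indices into the phase 1 panel kept for phase 2
#'   (default: all).
#' @return List of two `list(dataset, truth)` pairs with disjoint sample
#'   ids (`P1_`, `P2_` prefixes).
#' @export
make_two_phase <- function(cfg, cfg2 = cfg, marker_subset = seq_len(cfg$n_markers)) {
  stopifnot(inherits(cfg, "sim_config"), inherits(cfg2, "sim_config"))
  if (any(marker_subset < 1 | marker_subset > cfg$n_markers)) {
    stop("phase 2 marker panel must be a subset of the phase 1 panel")
  }
  fr <- .draw_freqs(cfg)
  phase1 <- .simulate_samples(cfg, fr, id_prefix = "P1_S")
  fr2 <- list(p0 = fr$p0[marker_subset],
              freqs = fr$freqs[, marker_subset, drop = FALSE])
  cfg2$n_markers <- length(marker_subset)
  if (!is.null(cfg2$causal)) {
    remap <- match(cfg2$causal$index, marker_subset)
    if (anyNA(remap)) stop("causal markers must be inside the phase 2 panel")
    cfg2$causal$index <- remap
  }
  phase2 <- .simulate_samples(cfg2, fr2, id_prefix = "P2_S")
  phase2$dataset$marker_ids <- phase1$dataset$marker_ids[marker_subset]
  colnames(phase2$dataset$dosages) <- phase2$dataset$marker_ids
  list(phase1 = phase1, phase2 = phase2)
}

#' Fixed synthetic phenotype scenario for null calibration
#'
#' A minimal deterministic study layout used to calibrate and validate
#' null thresholds without genotype data: two equal ancestry groups, a
#' collection label disagreeing with ancestry for `switch_rate` of the
#' samples, a binary phenotype with group-specific prevalence, and a
#' balanced binary covariate. Everything is reproducible from `seed`.
#'
#' @param n number of samples.
#' @param switch_rate ancestry/collection disagreement fraction.
#' @param prevalence length-2 per-ancestry-group phenotype probability.
#' @param seed integer seed.
#' @return List with `y`, `clustering_anc`, `clustering_coll`, `W`.
#' @export
make_null_scenario <- function(n = 1000, switch_rate = 0.2,
                               prevalence = c(0.45, 0.55), seed = 1) {
  set.seed(mix_seed(seed, 7))
  anc <- rep(1:2, length.out = n)
  coll <- ifelse(stats::runif(n) < switch_rate, 3L - anc, anc)
  y <- stats::rbinom(n, 1, prevalence[anc])
  W <- matrix(stats::rbinom(n, 1, 0.5), ncol = 1,
              dimnames = list(NULL, "gender"))
  list(y = y,
       clustering_anc = label_clustering(anc, source = "ancestry"),
       clustering_coll = label_clustering(coll, source = "collection"),
       W = W)
}
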