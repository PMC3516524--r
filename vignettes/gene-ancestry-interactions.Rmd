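---
title: "Detecting gene-ancestry interactions in multi-cohort GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-ancestry interactions in multi-cohort GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When genome-wide association studies on the same disease are run in
closely related populations (say, two cohorts collected in neighbouring
countries), a marker's effect may differ between genetic backgrounds.
A conventional meta-analysis averages such effects away, while a naive
interaction test on the *collection label* confounds true ancestry
interactions with artefacts of study design and execution: the label is
fixed by where a sample was recruited, not by what its genome says.

`ancestryx` separates the two. Individuals are re-grouped by *empirical
ancestry* - clusters in the space of the leading principal components of
the genotype matrix - and each marker is tested for heterogeneous
association across those clusters. The same test is run against the
collection grouping, and the difference of the two pieces of evidence
distinguishes ancestry-driven heterogeneity from collection artefacts:
if heterogeneity is real and genetic, re-grouping samples by relatedness
*sharpens* it; if it is an artefact of collection, re-grouping
*dilutes* it.

## The model

For a marker with dosage vector $x$ and a clustering of the $N$ samples
into $K$ groups with indicator matrix $Z$ ($z_{ic} = 1$ when sample $i$
is in cluster $c$), the heterogeneous model of association is the GLM

$$ g(E[y_i]) = \sum_{c=1}^{K} z_{ic}\,(\alpha_c + \beta_c x_i) + W_i\gamma $$

with a logit link for case-control phenotypes and the identity link for
quantitative traits. The $\alpha_c$ absorb cluster-specific baseline
disease rates, the $\beta_c$ are cluster-specific genetic effects, and
$W$ carries shared-effect adjustment covariates (a single $\gamma$
vector; typically gender plus any phenotype-associated leading PC). The
null model keeps the cluster intercepts but imposes one shared genetic
effect $\beta$ - this is crucial: differing background prevalence or
allele frequency between clusters must not masquerade as interaction.

Both models are fitted by iteratively re-weighted least squares
(`stats::glm.fit` behind `fit_glm()`), and evidence of heterogeneity is
the BIC difference

$$ T = \mathrm{BIC}_{\mathrm{null}} - \mathrm{BIC}_{\mathrm{het}}
     = 2(\ell_{\mathrm{het}} - \ell_{\mathrm{null}}) - (K-1)\log n, $$

so positive $T$ means the cluster-specific model is preferred even after
paying the $K-1$ extra-parameter penalty. With two groupings - ancestry
clustering $A$ and collection clustering $B$ - the difference statistic

$$ D = T_A - T_B $$

is positive when ancestry explains the heterogeneity better and negative
for collection artefacts. Both fits always use the identical sample
subset (samples missing the tested dosage are dropped from both models),
so the two BICs are comparable.

## Defining the ancestry space

* **Region exclusion and LD pruning.** Markers inside long-range-LD
  regions (bundled GRCh37 list via `default_ld_regions()`, overridable
  by any BED) are removed, then a sliding-window pairwise-$r^2$ pruner
  (threshold 0.2, window 50, step 5 - the classic `--indep-pairwise`
  settings) thins short-range LD. Within a violating pair the
  lower-MAF marker is dropped; ties drop the later-positioned one, a
  deterministic stand-in for the reference tool's internal order.
* **PCA.** EIGENSTRAT normalization: each marker centred by its mean
  and scaled by $\sqrt{\hat p(1-\hat p)}$ with the shrunk frequency
  estimate $\hat p = (1+\sum g)/(2+2n_{\mathrm{called}})$; missing
  dosages are mean-imputed before the decomposition only (I/O never
  imputes). Two components define the ancestry space by default -
  structured separation between closely related populations lives in
  the leading components - and `project_pca()` projects independent
  samples onto a fitted basis without refitting, which is how one
  checks that components represent ancestry rather than a collection
  artefact across phases.
* **Clustering.** `cluster_ancestry()` runs k-means (k-means++
  initialization, 25 seeded restarts, best within-SSE kept) for each
  $k$ in 2-6 and selects $k$ by a Gaussian-mixture BIC. The floor of 2
  is a default, not an assertion: heterogeneity testing needs at least
  two groups, and the bound is user-overridable.

**A modelling choice that matters.** The BIC used for selecting $k$
scores the hard clustering as an *axis-aligned* Gaussian mixture with
per-dimension variances shared across clusters (classification
likelihood including the $\sum_k n_k \log(n_k/n)$ mixing term;
$kd + d$ parameters). A fully spherical shared-variance score - the
other natural pairing with k-means - reliably over-splits PC scores:
trailing components are pure noise whose spread exceeds the
within-cluster spread of the structured leading component, so true
clusters are elongated and a spherical model buys likelihood by slicing
them. The shared per-dimension variance absorbs the axis scales; on the
generator's two-population data it selects $K = 2$ in 10/10 reseeds with
zero assignment error, and on a single Gaussian blob it correctly
collapses to the smallest allowed $k$. Omitting the mixing-weight term
has the same pathology (splitting a blob always gains more log
likelihood than $d\log n$), which is why it is included.

## Calibrating significance

There is no closed-form null for $D$, and case-control data are
ascertained retrospectively, so `estimate_thresholds()` simulates
*genotypes conditional on phenotype*: the observed phenotype, covariates
and both clusterings stay fixed while null genotypes are drawn under
Hardy-Weinberg proportions, independent of everything. Because the null
distribution of $D$ turns out not to depend on the MAF (checked by
pairwise Kolmogorov-Smirnov tests across strata in the test suite), the
simulations at a grid of MAFs - 0.05 to 0.50 in steps of 0.05, 10,000
draws each at the defaults - are pooled, and the significance threshold
is the empirical 99th centile with a strictly-greater exceedance rule.
The mirror 1st centile is reported too: markers *below* it are enriched
for collection heterogeneity, itself sometimes of interest (ascertainment
or technical artefacts). With a single cohort there is no collection
grouping to difference against; the same machinery then thresholds $T$
directly (`clustering_b = NULL`).

Every draw has its own substream seed derived from (master seed, MAF,
occurrence index), so thresholds are invariant to grid order and
reproducible in parallel or serial execution. Thresholds are calibrated
per dataset - the null depends on $n$, the clusterings, and the
covariates' contribution to the fit, so recycling a threshold across
cohorts is not supported.

## The scan and what follows it

`scan_markers()` computes $T_{\mathrm{anc}}$, $T_{\mathrm{coll}}$ and
$D$ for every marker, filters on $D$ above the calibrated threshold and
ranks candidates by $T_{\mathrm{anc}}$. The report carries an
`expected_by_chance` field - the exact integer
$M \times (100-\mathrm{centile})/100$ - because at genome scale the
D filter passes about 1% of null markers and the observed candidate
count should be read against that base rate. With two discovery phases,
`cross_phase_consistency()` keeps candidates passing the filter in both
phases whose per-cluster effect signs agree (sign agreement in every
matched cluster; cluster labels are assumed matched across phases, which
the PCA projection step justifies).

Replication cohorts typically lack genome-wide data, so ancestry cannot
be re-clustered; `replication_test()` instead uses the collection label
as a noisy proxy - unbiased for the group-specific effect, but with
power eroded by the label/ancestry switch rate. One-sided p-values in
the pre-registered discovery direction are reported per group, without
multiple-testing adjustment (targeted replication tests one marker).
`pooled_fit()` combines phases with free per-source intercepts and a
shared effect, mirroring the cluster-intercept philosophy of the null
model; an inverse-variance fixed-effect combination is used as a
cross-check in the tests, not as the estimator.

## Power under label switching

`power_switch()` quantifies the proxy-label power loss: a
"group-1-labelled" sample is truly group 1 with probability $1-s$,
genotypes are drawn retrospectively per case/control stratum from the
distributions implied by each true group's odds ratio and the MAF under
a logistic disease model, and power is the rejection rate of the
one-sided Wald test. The baseline (genotype-0) disease probability
defaults to 0.05, a generic common-disease figure; it enters only
through the retrospective genotype distributions and has little
leverage on power. The analytic counterpart `power_wald()` - limiting
logistic parameters under case-control sampling plus Fisher information
under the sampled genotype mixture - pins the $s = 0$ end of the curve,
and the simulated curve is monotone non-increasing in $s$, reflecting
the attenuation of the labelled-group effect (roughly
$\exp((1-s)\log \mathrm{OR_1} + s\log \mathrm{OR_2})$).

## The synthetic-data generator

`simulate_dataset()` is first-class, tested code, not a fixture: it is
the ground truth against which every stage is validated.

* Ancestral MAFs are uniform on a configured range; population MAFs
  follow the Balding-Nichols Beta model
  $\mathrm{Beta}(p_0(1-F)/F,\,(1-p_0)(1-F)/F)$. The default
  $F_{st} = 0.005$ emulates closely related populations: collection
  labels overlap heavily in any single marker, yet with enough markers
  the leading PC separates the populations cleanly (the between-group
  score separation grows like $\sqrt{8 F L}$ against a within-group
  noise scale of $\sqrt 2$, so 20,000 markers at $F = 0.005$ give
  nearly disjoint lobes).
* Disease follows a logistic model with per-population baseline
  prevalence and group-specific log-odds at causal markers; cases and
  controls are ascertained by rejection sampling to the configured
  ratio, matching the retrospective framing of the null calibration.
  The `effect_scope` switch makes the causal odds ratios follow either
  the true population (a genuine ancestry interaction) or the
  collection label (a pure artefact) - the latter is how the mirrored
  $D < 0$ behaviour is tested.
* Collection labels are the true population flipped independently with
  probability `label_switch_rate` (default 0.2).
* What it does **not** emulate: linkage disequilibrium between markers
  (markers are independent given population), admixture beyond the
  two-population mixture, genotyping error, or batch effects. Passing
  tests therefore demonstrate correctness of the statistics under the
  model's assumptions, not robustness to LD-induced redundancy or
  array artefacts in real data.

## Numerical choices and degenerate inputs

* GLM convergence: relative deviance change below $10^{-8}$, at most
  100 iterations; non-convergence is flagged on the result, never
  fatal mid-scan.
* Complete separation (e.g. a marker monomorphic among cases of one
  cluster): coefficients capped at $\pm 15$ log-odds and the fit
  flagged, so a genome scan completes; rank-deficient designs skip the
  marker with a logged reason.
* $K = 1$ clusterings make the heterogeneous and null models identical
  and $T = 0$ exactly; duplicated clusters force
  $T = -(K-1)\log n$, both of which are asserted in the tests.
* Quantile type for thresholds: inverse ECDF (type 1), so a 100th
  centile is the sample maximum and the exceedance rule
  (strictly greater) is exact.
* Seeds: every stochastic routine takes a master seed and derives
  bounded substream seeds; all defaults are below $2^{31}$.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run at desk scale, chosen
to keep each check statistically meaningful: threshold calibration uses
2,000 simulations per MAF (20,000 pooled) on an $n = 1000$ scenario,
validated against 20,000 fresh null markers; the $\chi^2_1$ null check
uses 10,000 simulations at $n = 2000$; cluster-count selection uses
2,000 samples by 20,000 markers; effect-recovery uses 50 replicates at
$n = 10{,}000$; power curves use 600 Monte-Carlo replicates per switch
rate. Genome-scale scans (hundreds of thousands of markers) are a
straightforward, embarrassingly parallel extension of `scan_markers()`.

## Known limitations

* Hard cluster assignments: uncertainty in cluster membership is not
  propagated into the association model; a probabilistic-clustering
  extension would be natural but is out of scope.
* Shared-effect covariates only ($W\gamma$ has no per-cluster
  structure).
* The switch-rate comparison requires equal cluster counts between the
  two groupings; the T/D machinery itself does not.
* No LD-aware marker selection beyond greedy pruning, and no
  genomic-control style inflation correction - the retrospective
  calibration plays that role for these statistics.
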