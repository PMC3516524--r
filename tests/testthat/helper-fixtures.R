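# Fixtures built in code; every helper is deterministic given its seed.

# Small random dataset with HWE genotypes independent of a binary phenotype.
tiny_dataset <- function(n = 60, m = 5, seed = 42, maf = 0.3,
                         with_W = FALSE, na_frac = 0) {
  set.seed(seed)
  dos <- matrix(stats::rbinom(n * m, 2, maf), n, m)
  if (na_frac > 0) dos[stats::runif(n * m) < na_frac] <- NA
  y <- rep(c(0, 1), length.out = n)
  W <- if (with_W) matrix(stats::rbinom(n, 1, 0.5), ncol = 1,
                          dimnames = list(NULL, "gender")) else NULL
  genotype_dataset(dos, y = y,
                   collection = factor(rep(c("A", "B"), length.out = n)),
                   W = W,
                   sample_ids = sprintf("S%03d", seq_len(n)),
                   marker_ids = sprintf("rs%03d", seq_len(m)),
                   chrom = rep("1", m), pos = seq_len(m) * 1000)
}

# Two well-separated spherical blobs in 2-D.
two_blob_scores <- function(n_per = 200, centers = c(-5, 5), sd = 1, seed = 1) {
  set.seed(seed)
  rbind(cbind(stats::rnorm(n_per, centers[1], sd), stats::rnorm(n_per, 0, sd)),
        cbind(stats::rnorm(n_per, centers[2], sd), stats::rnorm(n_per, 0, sd)))
}

# Dataset with genotypes drawn under HWE at random MAFs, independent of the
# phenotype of a make_null_scenario() layout -- a pure-null scan fixture.
null_scan_dataset <- function(n = 600, m = 300, seed = 9) {
  sc <- make_null_scenario(n, seed = seed)
  set.seed(mix_helper(seed))
  mafs <- stats::runif(m, 0.1, 0.5)
  dos <- matrix(0, n, m)
  for (j in seq_len(m)) dos[, j] <- stats::rbinom(n, 2, mafs[j])
  ds <- genotype_dataset(dos, y = sc$y,
                         collection = factor(c("A", "B")[sc$clustering_coll$assignment]),
                         sample_ids = sprintf("S%04d", seq_len(n)),
                         marker_ids = sprintf("mk%04d", seq_len(m)))
  list(ds = ds, scenario = sc)
}

mix_helper <- function(seed) (seed * 7919 + 13) %% 2147483647

# Minimal VCF text fixture (biallelic SNVs plus one multi-allelic record).
write_vcf_fixture <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0|0",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "2\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1")
  writeLines(lines, path)
  path
}

write_sample_sheet <- function(path, ids, y = rep(c(0, 1), length.out = length(ids)),
                               collection = rep("A", length(ids)), extra = NULL) {
  df <- data.frame(sample_id = ids, phenotype = y, collection = collection)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
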