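#' Construct a genotype dataset
#'
#' The central data container: an N x M matrix of additive allele dosages
#' (0, 1, 2 or `NA` for missing) together with the aligned sample sheet
#' (phenotype, collection label, optional covariates) and marker metadata.
#' Sample order is identical across all components; all accessors and
#' downstream functions rely on that alignment.
#'
#' @param dosages numeric matrix, samples in rows, markers in columns;
#'   entries must be 0, 1, 2 or `NA`. Missing dosages are preserved as-is:
#'   no imputation happens at construction or I/O time.
#' @param y phenotype vector of length N: binary 0/1 for case-control
#'   analyses (both classes must be present) or real-valued for
#'   quantitative traits.
#' @param collection factor (or coercible) of length N giving the
#'   collection-of-origin label fixed by study design.
#' @param W optional N x q numeric matrix of main-effect adjustment
#'   covariates, or `NULL`.
#' @param sample_ids,marker_ids identifiers; default to dimnames of
#'   `dosages` or generated ids.
#' @param chrom,pos optional marker chromosome labels and 1-based positions.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, y, collection, W = NULL,
                             sample_ids = NULL, marker_ids = NULL,
                             chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (n < 2) stop("a genotype dataset needs at least 2 samples")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosage entries must be 0, 1, 2 or NA")
  }
  sample_ids <- sample_ids %||% rownames(dosages) %||% sprintf("S%05d", seq_len(n))
  marker_ids <- marker_ids %||% colnames(dosages) %||% sprintf("mk%05d", seq_len(m))
  if (length(sample_ids) != n) stop("sample_ids length does not match dosage rows")
  if (length(marker_ids) != m) stop("marker_ids length does not match dosage columns")
  if (length(y) != n) stop("phenotype length does not match sample count")
  y <- as.numeric(y)
  if (all(y[!is.na(y)] %in% c(0, 1)) && length(unique(y[!is.na(y)])) < 2) {
    stop("binary phenotype must contain both cases and controls")
  }
  collection <- as.factor(collection)
  if (length(collection) != n) stop("collection length does not match sample count")
  if (!is.null(W)) {
    W <- as.matrix(W)
    storage.mode(W) <- "double"
    if (nrow(W) != n) stop("covariate matrix W must have one row per sample")
    if (is.null(colnames(W))) colnames(W) <- sprintf("cov%d", seq_len(ncol(W)))
  }
  if (is.null(chrom)) chrom <- rep(NA_character_, m)
  if (is.null(pos)) pos <- seq_len(m)
  if (length(chrom) != m || length(pos) != m) {
    stop("chrom/pos must have one entry per marker")
  }
  dimnames(dosages) <- list(sample_ids, marker_ids)
  structure(list(
    dosages = dosages,
    sample_ids = as.character(sample_ids),
    marker_ids = as.character(marker_ids),
    chrom = as.character(chrom),
    pos = as.numeric(pos),
    y = y,
    collection = collection,
    W = W
  ), class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d markers\n",
              length(x$sample_ids), length(x$marker_ids)))
  binary <- all(x$y[!is.na(x$y)] %in% c(0, 1))
  if (binary) {
    cat(sprintf("  phenotype: binary (%d cases / %d controls)\n",
                sum(x$y == 1, na.rm = TRUE), sum(x$y == 0, na.rm = TRUE)))
  } else {
    cat("  phenotype: quantitative\n")
  }
  cat(sprintf("  collections: %s\n",
              paste(sprintf("%s (%d)", levels(x$collection),
                            tabulate(x$collection)), collapse = ", ")))
  cat(sprintf("  covariates: %s\n",
              if (is.null(x$W)) "none" else paste(colnames(x$W), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

.read_sample_sheet <- function(samples_path) {
  sheet <- utils::read.delim(samples_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "phenotype", "collection")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) {
    stop("sample sheet is missing required column(s): ", paste(miss, collapse = ", "))
  }
  sheet
}

.check_sample_match <- function(geno_ids, sheet_ids) {
  only_geno <- setdiff(geno_ids, sheet_ids)
  only_sheet <- setdiff(sheet_ids, geno_ids)
  if (length(only_geno) || length(only_sheet)) {
    stop("sample sets disagree between genotype file and sample sheet.\n",
         "  only in genotypes: ",
         if (length(only_geno)) paste(utils::head(only_geno, 10), collapse = ", ") else "(none)",
         "\n  only in sample sheet: ",
         if (length(only_sheet)) paste(utils::head(only_sheet, 10), collapse = ", ") else "(none)")
  }
}

# Strip the PLINK counted-allele suffix ("rs123_A" -> "rs123").
.strip_allele_suffix <- function(ids) sub("_[ACGTacgt0-9]+$", "", ids)

.read_raw_matrix <- function(genotype_path) {
  tab <- utils::read.table(genotype_path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA")
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(tab)[seq_along(fixed)])) {
    stop("not a .raw dosage table: expected header to start with ",
         paste(fixed, collapse = " "))
  }
  marker_cols <- setdiff(names(tab), fixed)
  dos <- as.matrix(tab[, marker_cols, drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- as.character(tab$IID)
  colnames(dos) <- .strip_allele_suffix(marker_cols)
  dos
}

.read_vcf_matrix <- function(genotype_path) {
  v <- vcfR::read.vcfR(genotype_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  if (any(!biallelic)) {
    warning(sum(!biallelic), " non-biallelic VCF record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # alt-allele count from GT strings like 0/1, 1|1, ./.
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  dos <- t(apply(gt, c(1, 2), count_alt))  # samples x markers
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  colnames(dos) <- ids
  list(dosages = dos, chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]))
}

#' Read a genotype dataset from standard files
#'
#' Reads additive dosages from a PLINK `.raw`-style whitespace-delimited
#' table or a VCF (biallelic SNVs only; other records are skipped with a
#' warning), joins them with a tab-delimited sample sheet, and returns a
#' [genotype_dataset] with samples ordered as in the sample sheet.
#'
#' The sample sheet must contain columns `sample_id`, `phenotype` and
#' `collection`; any further columns become adjustment covariates `W`.
#' For `.raw` input, marker chromosome/position metadata is taken from a
#' `<genotype_path>.markers.tsv` sidecar (written by [write_dataset]) when
#' present; otherwise chromosomes are `NA` and positions default to the
#' column index.
#'
#' @param genotype_path path to the genotype file.
#' @param samples_path path to the sample sheet TSV.
#' @param format `"raw"` or `"vcf"`.
#' @return A [genotype_dataset].
#' @export
read_dataset <- function(genotype_path, samples_path, format = c("raw", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(genotype_path)) stop("genotype file not found: ", genotype_path)
  if (!file.exists(samples_path)) stop("sample sheet not found: ", samples_path)
  sheet <- .read_sample_sheet(samples_path)
  chrom <- NULL
  pos <- NULL
  if (format == "raw") {
    dos <- .read_raw_matrix(genotype_path)
    sidecar <- paste0(genotype_path, ".markers.tsv")
    if (file.exists(sidecar)) {
      mk <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
      idx <- match(colnames(dos), mk$marker_id)
      if (!anyNA(idx)) {
        chrom <- as.character(mk$chrom[idx])
        pos <- mk$pos[idx]
      }
    }
  } else {
    parsed <- .read_vcf_matrix(genotype_path)
    dos <- parsed$dosages
    chrom <- parsed$chrom
    pos <- parsed$pos
  }
  .check_sample_match(rownames(dos), sheet$sample_id)
  dos <- dos[match(sheet$sample_id, rownames(dos)), , drop = FALSE]
  covar_cols <- setdiff(names(sheet), c("sample_id", "phenotype", "collection"))
  W <- if (length(covar_cols)) as.matrix(sheet[, covar_cols, drop = FALSE]) else NULL
  genotype_dataset(dos,
                   y = sheet$phenotype,
                   collection = sheet$collection,
                   W = W,
                   sample_ids = sheet$sample_id,
                   marker_ids = colnames(dos),
                   chrom = chrom, pos = pos)
}

#' Write a genotype dataset
#'
#' Writes the `.raw`-style dosage table (header row `FID IID PAT MAT SEX
#' PHENOTYPE` followed by marker ids with a counted-allele `_A` suffix, one
#' row per sample, `NA` for missing) plus the sample sheet TSV and a
#' `<path>.markers.tsv` sidecar carrying marker chromosome/position so
#' that `read_dataset(write_dataset(ds))` round-trips losslessly.
#'
#' @param ds a [genotype_dataset].
#' @param genotype_path output path for the dosage table.
#' @param samples_path output path for the sample sheet; defaults to
#'   `<genotype_path>.samples.tsv`.
#' @param format only `"raw"` is supported for output.
#' @return Invisibly, `genotype_path`.
#' @export
write_dataset <- function(ds, genotype_path,
                          samples_path = paste0(genotype_path, ".samples.tsv"),
                          format = "raw") {
  format <- match.arg(format, "raw")
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- length(ds$sample_ids)
  tab <- data.frame(FID = ds$sample_ids, IID = ds$sample_ids,
                    PAT = 0L, MAT = 0L, SEX = 0L,
                    PHENOTYPE = ds$y, check.names = FALSE,
                    stringsAsFactors = FALSE)
  dos <- as.data.frame(ds$dosages)
  names(dos) <- paste0(ds$marker_ids, "_A")
  tab <- cbind(tab, dos)
  ok <- tryCatch({
    utils::write.table(tab, genotype_path, sep = " ", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write genotype file: ", conditionMessage(e)))
  mk <- data.frame(marker_id = ds$marker_ids, chrom = ds$chrom, pos = ds$pos)
  utils::write.table(mk, paste0(genotype_path, ".markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = ds$sample_ids, phenotype = ds$y,
                      collection = as.character(ds$collection),
                      stringsAsFactors = FALSE)
  if (!is.null(ds$W)) sheet <- cbind(sheet, as.data.frame(ds$W))
  utils::write.table(sheet, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(genotype_path)
}

#' Read a BED file of genomic regions
#'
#' Parses a BED file (0-based, half-open intervals) into an ordered region
#' list, typically the long-range linkage-disequilibrium exclusion regions
#' removed before the ancestry PCA. Coordinates are kept 0-based half-open
#' internally; conversion to the package's 1-based marker convention
#' happens in [markers_in_regions].
#'
#' @param path BED file path; the first three whitespace-separated columns
#'   (chrom, start, end) are used.
#' @return A `region_list` data frame with columns `chrom`, `start`, `end`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric()), class = c("region_list", "data.frame")))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  out <- data.frame(chrom = character(length(parts)),
                    start = numeric(length(parts)),
                    end = numeric(length(parts)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) stop("BED parse error at line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(p[2]))
    e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e)) stop("BED parse error at line ", i, ": non-numeric coordinates")
    if (s < 0) stop("BED parse error at line ", i, ": negative start")
    if (s >= e) stop("BED parse error at line ", i, ": start >= end")
    out$chrom[i] <- p[1]
    out$start[i] <- s
    out$end[i] <- e
  }
  structure(out, class = c("region_list", "data.frame"))
}

#' Bundled long-range LD exclusion regions
#'
#' The canonical list of long-range linkage-disequilibrium regions
#' (GRCh37 coordinates; MHC, chromosome 8 inversion, and the other
#' high-LD blocks routinely excluded before ancestry PCA), shipped as a
#' BED file. Any user-supplied BED passed to [prune_markers] overrides
#' it.
#'
#' @return A `region_list`.
#' @export
default_ld_regions <- function() {
  read_regions(system.file("extdata", "long_range_ld_grch37.bed",
                           package = "ancestryx", mustWork = TRUE))
}

#' Which markers fall inside a region list?
#'
#' Tests 1-based marker positions against 0-based half-open BED intervals:
#' a marker at 1-based position `pos` lies in `[start, end)` iff
#' `pos > start` and `pos <= end`. Overlapping regions are effectively
#' unioned; applying the exclusion twice changes nothing.
#'
#' @param chrom character vector of marker chromosomes.
#' @param pos numeric vector of 1-based marker positions.
#' @param regions a `region_list` from [read_regions].
#' @return Logical vector, `TRUE` where the marker falls inside a region.
#' @export
markers_in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  if (is.null(regions) || nrow(regions) == 0) return(hit)
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (!is.na(chrom) & chrom == regions$chrom[i] &
                    pos > regions$start[i] & pos <= regions$end[i])
  }
  hit
}
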