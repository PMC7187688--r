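#' Genotype matrix container
#'
#' Samples-by-variants additive genotype dosages (counted copies of the
#' declared effect allele, values 0/1/2 or `NA` for missing) together with
#' variant and sample metadata. This is the central genotype object passed
#' between QC, GRM construction, screening and prediction.
#'
#' @param values Integer or numeric matrix, `n_samples x n_variants`, with
#'   entries in `{0, 1, 2, NA}`.
#' @param variants `data.frame` with columns `id`, `chrom`, `pos`,
#'   `allele_effect`, `allele_other`; one row per variant column.
#' @param samples `data.frame` with columns `id` and optionally
#'   `reported_sex` (`"male"`, `"female"`, `"unknown"`); one row per sample
#'   row.
#'
#' @return An object of class `genotype_matrix` with elements `values`,
#'   `variants`, `samples`.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, 1L, 0L, 2L), nrow = 3),
#'   variants = data.frame(id = c("rs1", "rs2"), chrom = c(1, 1),
#'                         pos = c(100, 200),
#'                         allele_effect = c("A", "C"),
#'                         allele_other = c("G", "T")),
#'   samples = data.frame(id = c("s1", "s2", "s3")))
#' dim(g$values)
genotype_matrix <- function(values, variants, samples) {
  values <- as.matrix(values)
  fractional <- is.double(values) &&
    any(abs(values - round(values)) > 1e-12, na.rm = TRUE)
  if (!fractional) storage.mode(values) <- "integer"
  if (!is.data.frame(variants)) variants <- as.data.frame(variants)
  if (!is.data.frame(samples)) samples <- as.data.frame(samples)
  need_v <- c("id", "chrom", "pos", "allele_effect", "allele_other")
  miss <- setdiff(need_v, names(variants))
  if (length(miss))
    stopf("variant metadata is missing column(s): %s",
          paste(miss, collapse = ", "))
  if (!"id" %in% names(samples))
    stopf("sample metadata is missing an `id` column")
  if (!"reported_sex" %in% names(samples)) samples$reported_sex <- "unknown"
  if (nrow(variants) != ncol(values))
    stopf("genotype matrix has %d variant columns but metadata has %d rows",
          ncol(values), nrow(variants))
  if (nrow(samples) != nrow(values))
    stopf("genotype matrix has %d sample rows but metadata has %d rows",
          nrow(values), nrow(samples))
  if (anyDuplicated(variants$id))
    stopf("variant ids are not unique (e.g. %s)",
          variants$id[anyDuplicated(variants$id)])
  if (anyDuplicated(samples$id))
    stopf("sample ids are not unique")
  if (fractional) {
    ## mean-imputed dosages: anywhere on [0, 2]
    bad <- values[!is.na(values) & (values < 0 | values > 2)]
    if (length(bad))
      stopf("imputed dosages must lie in [0, 2]; found %s", bad[1])
  } else {
    bad <- values[!is.na(values) & !(values %in% 0:2)]
    if (length(bad))
      stopf("genotype dosages must be 0, 1, 2 or NA; found %s", bad[1])
  }
  if (any(variants$pos < 1)) stopf("variant positions must be >= 1")
  if (any(!nzchar(variants$allele_effect)) ||
      any(!nzchar(variants$allele_other)) ||
      any(variants$allele_effect == variants$allele_other))
    stopf("alleles must be non-empty and distinct")
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  dimnames(values) <- list(samples$id, variants$id)
  structure(list(values = values, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @param samples,variants Logical, integer or character index into sample
#'   rows / variant columns (default: keep all).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(g$values)) else samples
  if (is.character(si)) si <- match(si, g$samples$id)
  vi <- if (is.null(variants)) seq_len(ncol(g$values)) else variants
  if (is.character(vi)) vi <- match(vi, g$variants$id)
  if (anyNA(si)) stopf("unknown sample id in subset")
  if (anyNA(vi)) stopf("unknown variant id in subset")
  genotype_matrix(g$values[si, vi, drop = FALSE],
                  g$variants[vi, , drop = FALSE],
                  g$samples[si, , drop = FALSE])
}

## ---- PLINK binary (BED/BIM/FAM) ----
## SNP-major BED: magic bytes 0x6c 0x1b, mode 0x01, then one block of
## ceiling(n/4) bytes per variant; two bits per sample, 00 = two effect
## alleles (A1/A1), 10 = het, 11 = zero effect alleles, 01 = missing.

.sex_to_fam <- c(male = 1L, female = 2L, unknown = 0L)

#' Write genotypes to disk
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix (`<prefix>.bed/.bim/.fam` or
#'   `<prefix>.tsv`).
#' @param dialect `"plink_bed"` (binary, SNP-major) or `"tsv_dosage"`
#'   (plain text; one variant per row, five metadata columns then one dosage
#'   column per sample, missing as `NA`).
#' @return Invisibly, the paths written.
#' @export
write_genotypes <- function(g, prefix, dialect = c("plink_bed", "tsv_dosage")) {
  stopifnot(inherits(g, "genotype_matrix"))
  dialect <- match.arg(dialect)
  if (dialect == "plink_bed") .write_plink(g, prefix) else .write_tsv(g, prefix)
}

.write_plink <- function(g, prefix) {
  n <- nrow(g$values)
  bim <- data.frame(chrom = g$variants$chrom, id = g$variants$id, cm = 0,
                    pos = g$variants$pos, a1 = g$variants$allele_effect,
                    a2 = g$variants$allele_other)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  sex <- .sex_to_fam[as.character(g$samples$reported_sex)]
  sex[is.na(sex)] <- 0L
  fam <- data.frame(fid = g$samples$id, iid = g$samples$id, pat = 0, mat = 0,
                    sex = sex, phe = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ## dosage -> 2-bit code (per effect-allele count): 2->00, 1->10, 0->11, NA->01
  code <- matrix(3L, n, ncol(g$values))
  code[g$values == 2L] <- 0L
  code[g$values == 1L] <- 2L
  code[is.na(g$values)] <- 1L
  nb <- ceiling(n / 4)
  pad <- nb * 4L - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, ncol(code)))
  i4 <- seq(1L, nb * 4L, by = 4L)
  bytes <- code[i4, , drop = FALSE] + 4L * code[i4 + 1L, , drop = FALSE] +
    16L * code[i4 + 2L, , drop = FALSE] + 64L * code[i4 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

.write_tsv <- function(g, prefix) {
  path <- if (grepl("\\.tsv$", prefix)) prefix else paste0(prefix, ".tsv")
  tab <- cbind(g$variants[c("id", "chrom", "pos", "allele_effect",
                            "allele_other")],
               as.data.frame(t(g$values)))
  names(tab) <- c("id", "chrom", "pos", "allele_effect", "allele_other",
                  g$samples$id)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read genotypes from disk
#'
#' Round-trips losslessly with [write_genotypes()] for dosages in
#' `{0, 1, 2, NA}`; variant order is preserved.
#'
#' @inheritParams write_genotypes
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(prefix, dialect = c("plink_bed", "tsv_dosage")) {
  dialect <- match.arg(dialect)
  if (dialect == "plink_bed") .read_plink(prefix) else .read_tsv(prefix)
}

.read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stopf("file not found: %s", f)
  bim <- read.delim(paste0(prefix, ".bim"), header = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.delim(paste0(prefix, ".fam"), header = FALSE,
                    colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stopf("%s is not a PLINK BED file (bad magic bytes)", bed)
  if (raw[3] != as.raw(0x01))
    stopf("%s is not SNP-major (mode byte %s)", bed, raw[3])
  nb <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != nb * m)
    stopf("%s: genotype block has %d bytes, expected %d for %d x %d",
          bed, length(body), nb * m, n, m)
  ints <- as.integer(body)
  ## unpack 2-bit fields, little-endian within byte
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L, (ints %/% 16L) %% 4L,
                 ints %/% 64L)
  codes <- matrix(as.vector(codes), nrow = nb * 4L)[seq_len(n), , drop = FALSE]
  vals <- matrix(NA_integer_, n, m)
  vals[codes == 0L] <- 2L
  vals[codes == 2L] <- 1L
  vals[codes == 3L] <- 0L
  rs <- c(`1` = "male", `2` = "female")[fam[[5]]]
  rs[is.na(rs)] <- "unknown"
  genotype_matrix(vals,
                  data.frame(id = bim[[2]], chrom = bim[[1]], pos = bim[[4]],
                             allele_effect = bim[[5]], allele_other = bim[[6]]),
                  data.frame(id = fam[[2]], reported_sex = unname(rs)))
}

.read_tsv <- function(prefix) {
  path <- if (grepl("\\.tsv$", prefix)) prefix else paste0(prefix, ".tsv")
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  meta_cols <- c("id", "chrom", "pos", "allele_effect", "allele_other")
  if (!all(meta_cols %in% names(tab)[1:5]))
    stopf("%s: first five columns must be %s", path,
          paste(meta_cols, collapse = ", "))
  sample_ids <- names(tab)[-(1:5)]
  raw <- as.matrix(tab[, -(1:5), drop = FALSE])
  ok <- is.na(raw) | raw %in% c("0", "1", "2", "NA")
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stopf("%s: invalid dosage '%s' at variant row %d, sample column %s",
          path, raw[idx[1], idx[2]], idx[1], sample_ids[idx[2]])
  }
  vals <- t(matrix(suppressWarnings(as.integer(raw)), nrow = nrow(raw)))
  genotype_matrix(vals,
                  data.frame(id = tab$id, chrom = tab$chrom,
                             pos = as.integer(tab$pos),
                             allele_effect = tab$allele_effect,
                             allele_other = tab$allele_other),
                  data.frame(id = sample_ids))
}

#' Read / write a phenotype table
#'
#' The phenotype TSV carries one row per sample: `sample_id`, binary
#' `status`, the continuous `trait` (FEV1 analogue), clinical covariates
#' (`age`, `sex`, `height`, `pack_years`, `smoking_current`,
#' `family_history`) and an `ethnicity` label.
#'
#' @param path TSV file path.
#' @return `read_phenotypes()`: a `data.frame`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ph <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(ph))
    stopf("%s: phenotype table needs a `sample_id` column", path)
  ph
}

#' @rdname read_phenotypes
#' @param phen Phenotype `data.frame`.
#' @export
write_phenotypes <- function(phen, path) {
  write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

## Mean dosage per variant ignoring NAs; used by QC and standardization.
.col_means_dosage <- function(values) colMeans(values, na.rm = TRUE)

#' Mean-impute missing dosages
#'
#' Replaces missing dosages by the per-variant mean dosage (on the 0..2
#' scale). Required before the dense matrix algebra of GRM construction and
#' penalized fitting; applied after QC so that imputation never affects the
#' QC statistics themselves.
#'
#' @param g A [genotype_matrix()].
#' @return A list with `values` (numeric matrix, no missing entries) and the
#'   original metadata; class `genotype_matrix` is retained but `values`
#'   becomes numeric.
#' @export
mean_impute <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  vals <- g$values
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    mu <- .col_means_dosage(vals)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- mu[idx[, 2]]
  }
  out <- g
  out$values <- vals
  out
}
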