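#' QC thresholds
#'
#' Variant- and sample-level filter thresholds. Defaults follow common
#' GWAS practice for genotyping-array data: drop variants with missing call
#' rate above 5%, minor allele frequency below 5%, or Hardy-Weinberg exact
#' p-value below 1e-5, and samples with more than 5% missing genotypes.
#' Removal requires a strict threshold violation, so a variant exactly at a
#' boundary (e.g. MAF = 0.05) is retained.
#'
#' @param max_snp_missing Maximum tolerated variant missing call rate.
#' @param min_maf Minimum minor allele frequency.
#' @param min_hwe_p Minimum HWE exact-test p-value.
#' @param max_sample_missing Maximum tolerated per-sample missing rate.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_snp_missing = 0.05, min_maf = 0.05,
                          min_hwe_p = 1e-5, max_sample_missing = 0.05) {
  for (v in c("max_snp_missing", "min_maf", "min_hwe_p", "max_sample_missing"))
    check_prob(get(v), v)
  structure(list(max_snp_missing = max_snp_missing, min_maf = min_maf,
                 min_hwe_p = min_hwe_p,
                 max_sample_missing = max_sample_missing),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Probabilities follow the Levene-Haldane distribution of heterozygote
#' counts given allele counts under random mating; successive terms are
#' evaluated by the standard recurrence.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (homozygous, heterozygous,
#'   homozygous other).
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(100, 0, 0)   # monomorphic: p = 1
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (!is_count(n_AA) || !is_count(n_Aa) || !is_count(n_aa))
    stopf("genotype counts must be non-negative integers")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stopf("all genotype counts are zero: HWE test undefined")
  n1 <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # minor allele count
  if (n1 == 0) return(1)                       # monomorphic: single table
  h_min <- n1 %% 2
  h_max <- min(n1, 2 * n - n1)
  hs <- seq.int(h_min, h_max, by = 2L)
  ## unnormalized probabilities by recurrence:
  ## P(h+2)/P(h) = 4 * hom_r(h) * hom_c(h) / ((h+1)(h+2))
  logp <- numeric(length(hs))
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    hom_r <- (n1 - h) / 2
    hom_c <- n - hom_r - h
    logp[k] <- logp[k - 1] +
      log(4 * hom_r * hom_c) - log((h + 1) * (h + 2))
  }
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  obs <- match(n_Aa, hs)
  if (is.na(obs)) stopf("heterozygote count %d impossible for %d minor alleles",
                        n_Aa, n1)
  min(1, sum(p_all[p_all <= p_all[obs] * (1 + 1e-12)]))
}

## Per-variant QC statistics used by the filters (computed on observed
## genotypes only; missing dosages are ignored).
.variant_stats <- function(values) {
  n <- nrow(values)
  n_miss <- colSums(is.na(values))
  n_obs <- n - n_miss
  n_het <- colSums(values == 1L, na.rm = TRUE)
  n_hom2 <- colSums(values == 2L, na.rm = TRUE)
  n_hom0 <- n_obs - n_het - n_hom2
  af <- (2 * n_hom2 + n_het) / (2 * pmax(n_obs, 1L))
  maf <- pmin(af, 1 - af)
  maf[n_obs == 0] <- 0
  hwe_p <- vapply(seq_len(ncol(values)), function(j) {
    if (n_obs[j] == 0) return(1)
    hwe_exact_test(n_hom0[j], n_het[j], n_hom2[j])
  }, numeric(1))
  data.frame(missing_rate = n_miss / n, maf = maf, hwe_p = hwe_p)
}

.qc_report <- function(axis, ids_in, removed_by) {
  counts <- vapply(removed_by, length, integer(1))
  retained <- setdiff(ids_in, unlist(removed_by, use.names = FALSE))
  structure(list(axis = axis, n_in = length(ids_in),
                 removed = removed_by, n_removed = counts,
                 n_out = length(retained), retained = retained),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (%s): %d in, %d removed, %d retained\n",
              x$axis, x$n_in, sum(x$n_removed), x$n_out))
  for (r in names(x$n_removed))
    cat(sprintf("  removed by %-12s %d\n", paste0(r, ":"), x$n_removed[[r]]))
  invisible(x)
}

#' Variant-level QC filter
#'
#' Retains variants with missing call rate at or below the threshold, MAF
#' at or above the MAF floor, and HWE exact p-value at or above the HWE
#' floor; removal requires a strict violation. Removal reasons are
#' attributed in the fixed precedence missingness, then MAF, then HWE (the
#' precedence affects report bookkeeping only, never the retained set).
#'
#' @param g A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with elements `genotypes` (filtered matrix) and `report`
#'   (a `qc_report`).
#' @export
snp_qc_filter <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  if (ncol(g$values) == 0) {
    rep0 <- .qc_report("variant", character(0),
                       list(missingness = character(0), maf = character(0),
                            hwe = character(0)))
    return(list(genotypes = g, report = rep0))
  }
  st <- .variant_stats(g$values)
  fail_miss <- st$missing_rate > thresholds$max_snp_missing
  fail_maf <- st$maf < thresholds$min_maf
  fail_hwe <- st$hwe_p < thresholds$min_hwe_p
  ids <- g$variants$id
  removed <- list(missingness = ids[fail_miss],
                  maf = ids[!fail_miss & fail_maf],
                  hwe = ids[!fail_miss & !fail_maf & fail_hwe])
  keep <- !(fail_miss | fail_maf | fail_hwe)
  list(genotypes = subset_genotypes(g, variants = which(keep)),
       report = .qc_report("variant", ids, removed))
}

## Genetic sex from X-chromosome heterozygosity: males are hemizygous, so
## their called X het rate is near 0. Requires enough X variants to call.
.genetic_sex <- function(values_x, min_variants = 20L) {
  if (ncol(values_x) < min_variants) return(NULL)
  het <- rowMeans(values_x == 1L, na.rm = TRUE)
  ifelse(is.na(het), "unknown", ifelse(het < 0.2, "male", "female"))
}

#' Sample-level QC filter
#'
#' Removes samples with genotype missing rate strictly above the threshold,
#' reported-versus-genetic sex mismatch (only when X-chromosome genotypes
#' are available; otherwise the check is skipped and logged), or a missing
#' value in any of the clinical covariates age, sex, current smoking,
#' pack-years, family history. Attribution precedence: missingness, then
#' sex mismatch, then covariate completeness.
#'
#' @param g A [genotype_matrix()].
#' @param phen Phenotype `data.frame` with a `sample_id` column aligned to
#'   `g` (same ids, any order).
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes`, `phenotypes` (both filtered) and `report`.
#' @export
sample_qc_filter <- function(g, phen, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  if (!setequal(phen$sample_id, g$samples$id))
    stopf("sample ids differ between genotypes and phenotypes")
  phen <- phen[match(g$samples$id, phen$sample_id), , drop = FALSE]
  ids <- g$samples$id
  miss_rate <- rowMeans(is.na(g$values))
  fail_miss <- miss_rate > thresholds$max_sample_missing

  is_x <- g$variants$chrom %in% c("X", "x", "23")
  fail_sex <- rep(FALSE, length(ids))
  sex_checked <- FALSE
  if (any(is_x)) {
    gsex <- .genetic_sex(g$values[, is_x, drop = FALSE])
    if (!is.null(gsex)) {
      sex_checked <- TRUE
      rep_sex <- as.character(g$samples$reported_sex)
      fail_sex <- rep_sex %in% c("male", "female") & gsex != "unknown" &
        rep_sex != gsex
    }
  }
  if (!sex_checked)
    message("sample QC: sex-consistency check skipped ",
            "(insufficient X-chromosome data)")

  covars <- intersect(c("age", "sex", "smoking_current", "pack_years",
                        "family_history"), names(phen))
  fail_cov <- if (length(covars))
    !complete.cases(phen[, covars, drop = FALSE]) else rep(FALSE, length(ids))

  removed <- list(missingness = ids[fail_miss],
                  sex_mismatch = ids[!fail_miss & fail_sex],
                  covariates = ids[!fail_miss & !fail_sex & fail_cov])
  keep <- !(fail_miss | fail_sex | fail_cov)
  list(genotypes = subset_genotypes(g, samples = which(keep)),
       phenotypes = phen[keep, , drop = FALSE],
       report = .qc_report("sample", ids, removed))
}

## Ambiguous strand pairs cannot be harmonized across platforms.
.is_ambiguous_pair <- function(a1, a2) {
  p <- paste(pmin(a1, a2), pmax(a1, a2))
  p %in% c("A T", "C G")
}

#' Restrict cohorts to shared, allele-harmonized variants
#'
#' Keeps variants present in every cohort by id with consistent alleles.
#' When the effect/other labels of a later cohort are interchanged relative
#' to the first cohort, its dosages are flipped (`2 - dosage`). A/T and C/G
#' variants are strand-ambiguous and dropped; so are variants whose allele
#' labels cannot be reconciled at all.
#'
#' @param cohorts List of two or more [genotype_matrix()] objects.
#' @return List with `cohorts` (the harmonized matrices, identical variant
#'   panels in identical order) and `log` (a `data.frame` of dropped
#'   variants and reasons).
#' @export
intersect_variants <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) < 2)
    stopf("need at least two cohorts to intersect")
  for (g in cohorts) stopifnot(inherits(g, "genotype_matrix"))
  shared <- Reduce(intersect, lapply(cohorts, function(g) g$variants$id))
  if (length(shared) == 0)
    stopf("no variants shared across all cohorts")
  ref <- cohorts[[1]]$variants
  ref <- ref[match(shared, ref$id), ]
  drop_reason <- setNames(rep(NA_character_, length(shared)), shared)
  amb <- .is_ambiguous_pair(ref$allele_effect, ref$allele_other)
  drop_reason[amb] <- "strand_ambiguous"
  flip <- vector("list", length(cohorts))
  for (k in seq_along(cohorts)) {
    v <- cohorts[[k]]$variants
    v <- v[match(shared, v$id), ]
    same <- v$allele_effect == ref$allele_effect &
      v$allele_other == ref$allele_other
    swapped <- v$allele_effect == ref$allele_other &
      v$allele_other == ref$allele_effect
    bad <- !(same | swapped)
    drop_reason[bad & is.na(drop_reason)] <- "allele_mismatch"
    flip[[k]] <- swapped
  }
  keep <- is.na(drop_reason)
  if (!any(keep)) stopf("no variants remain after allele harmonization")
  kept_ids <- shared[keep]
  out <- vector("list", length(cohorts))
  for (k in seq_along(cohorts)) {
    gk <- subset_genotypes(cohorts[[k]], variants = kept_ids)
    fl <- flip[[k]][keep]
    if (any(fl)) {
      gk$values[, fl] <- 2L - gk$values[, fl]
      ## relabel so metadata matches the harmonized orientation
      tmp <- gk$variants$allele_effect[fl]
      gk$variants$allele_effect[fl] <- gk$variants$allele_other[fl]
      gk$variants$allele_other[fl] <- tmp
    }
    out[[k]] <- gk
  }
  dropped <- data.frame(id = shared[!keep],
                        reason = drop_reason[!keep], row.names = NULL)
  list(cohorts = out, log = dropped)
}
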