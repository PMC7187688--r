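## Standardize dosages to zero mean / unit variance under HWE:
## (g - 2*phat) / sqrt(2*phat*(1-phat)), phat = sample effect-allele freq.
## Missing dosages are mean-imputed first. Monomorphic variants cannot be
## standardized and are flagged for exclusion.
standardize_genotypes <- function(g) {
  vals <- mean_impute(g)$values
  phat <- colMeans(vals) / 2
  poly <- phat > 0 & phat < 1
  denom <- sqrt(2 * phat * (1 - phat))
  gs <- sweep(vals, 2, 2 * phat)
  gs <- sweep(gs, 2, ifelse(poly, denom, Inf), "/")
  list(matrix = gs, polymorphic = poly, phat = phat)
}

#' Genetic relationship matrix
#'
#' `K = (1/m) * Gs %*% t(Gs)` where `Gs` holds genotypes standardized by
#' the sample effect-allele frequency, `(g - 2p) / sqrt(2p(1-p))`.
#' Monomorphic variants are excluded with a warning. Under HWE simulation
#' the diagonal averages about 1.
#'
#' @param g A [genotype_matrix()].
#' @param variant_subset Optional variant ids or indices to use.
#' @return Object of class `grm`: `matrix` (n x n), `sample_ids`,
#'   `n_variants_used`.
#' @export
compute_grm <- function(g, variant_subset = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(variant_subset)) g <- subset_genotypes(g, variants = variant_subset)
  st <- standardize_genotypes(g)
  if (!all(st$polymorphic)) {
    warnf("%d monomorphic variant(s) excluded from the GRM",
          sum(!st$polymorphic))
  }
  gs <- st$matrix[, st$polymorphic, drop = FALSE]
  m <- ncol(gs)
  if (m < 1) stopf("no polymorphic variants available for a GRM")
  K <- tcrossprod(gs) / m
  structure(list(matrix = K, sample_ids = g$samples$id, n_variants_used = m),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d samples, %d variants used, mean diagonal %.3f\n",
              nrow(x$matrix), x$n_variants_used, mean(diag(x$matrix))))
  invisible(x)
}

## Eigendecomposition of a GRM, cached so REML and BLUP share one
## factorization. Small negative eigenvalues from finite-m noise are
## clamped at zero.
grm_eigen <- function(K) {
  if (inherits(K, "grm")) K <- K$matrix
  e <- eigen(K, symmetric = TRUE)
  e$values[e$values < 0] <- 0
  e
}
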