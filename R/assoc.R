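#' Per-SNP BLUP screening scores
#'
#' Computes the per-variant score `G' K^-1 (y - Z beta_hat) / sigma_g2`
#' with `G` the standardized genotype matrix used for the GRM. The
#' `1/sigma_g2` factor only rescales all scores jointly, so the
#' absolute-value ranking used for screening is unaffected by it; the
#' scores are a screening statistic, not calibrated SNP effects, and should
#' not be compared numerically with other software's SNP-BLUP output.
#'
#' @param g A [genotype_matrix()] (same variants used for the GRM).
#' @param K A [compute_grm()] result or matrix.
#' @param y Trait vector.
#' @param Z Covariates (intercept added if absent).
#' @param fit A [reml_fit()] result; its eigendecomposition is reused and a
#'   ridge jitter of `1e-8 * trace(K)/n` is added when the smallest
#'   eigenvalue is below `1e-10`.
#' @return A `data.frame` of class `blup_scores` with `id` and `score`.
#' @export
blup_snp_effects <- function(g, K, y, Z, fit) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(fit, "reml_fit"))
  if (fit$sigma_g2 <= 0)
    stopf(paste("sigma_g2 is on the zero boundary: BLUP screening",
                "undefined; use the p-value criterion instead"))
  e <- fit$eigen
  if (is.null(e)) e <- grm_eigen(K)
  n <- length(y)
  Zm <- .design_matrix(Z, n)
  beta <- fit$fixed_effects
  r <- drop(y - Zm %*% beta)
  d <- e$values
  if (min(d) < 1e-10) d <- d + 1e-8 * sum(d) / n
  kinv_r <- e$vectors %*% (crossprod(e$vectors, r) / d)
  st <- standardize_genotypes(g)
  scores <- drop(crossprod(st$matrix, kinv_r)) / fit$sigma_g2
  out <- data.frame(id = g$variants$id, score = scores)
  class(out) <- c("blup_scores", "data.frame")
  out
}

#' Single-SNP linear-regression association scan
#'
#' Ordinary least squares of the trait on covariates plus one variant at a
#' time, vectorized across variants via Frisch-Waugh residualization; the
#' p-value is the two-sided t-test on the genotype coefficient.
#'
#' @param g A [genotype_matrix()].
#' @param y Trait vector.
#' @param Z Covariates (intercept added if absent).
#' @return A `data.frame` of class `snp_assoc` with `id`, `beta`, `se`,
#'   `p`.
#' @export
per_snp_regression <- function(g, y, Z = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stopf("trait vector contains missing values")
  Zm <- .design_matrix(Z, n)
  q <- ncol(Zm)
  if (n < q + 2) stopf("too few samples for the covariate set")
  qz <- qr(Zm)
  G <- mean_impute(g)$values
  yr <- qr.resid(qz, y)
  Gr <- qr.resid(qz, G)
  gss <- colSums(Gr^2)
  ok <- gss > 1e-12
  beta <- se <- p <- rep(NA_real_, ncol(G))
  bb <- colSums(Gr[, ok, drop = FALSE] * yr) / gss[ok]
  rss <- sum(yr^2) - bb^2 * gss[ok]
  df <- n - q - 1
  ss <- sqrt(pmax(rss, 0) / (df * gss[ok]))
  tt <- bb / ss
  pp <- 2 * pt(-abs(tt), df)
  pp[pp <= 0] <- .Machine$double.xmin   # keep p in (0, 1]
  beta[ok] <- bb
  se[ok] <- ss
  p[ok] <- pp
  out <- data.frame(id = g$variants$id, beta = beta, se = se, p = p)
  class(out) <- c("snp_assoc", "data.frame")
  out
}
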