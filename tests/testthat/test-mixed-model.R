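test_that("GRM standardization matches hand arithmetic", {
  ## single variant, phat = 0.5: standardized (-sqrt2, 0, sqrt2)
  g <- make_geno(matrix(c(0L, 1L, 2L), 3, 1))
  K <- compute_grm(g)
  expect_equal(unname(diag(K$matrix)), c(2, 0, 2), tolerance = 1e-12)
  expect_equal(K$matrix[1, 3], -2, tolerance = 1e-12)

  ## identical genotype rows: off-diagonal equals the diagonals
  g2 <- make_geno(rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, 1L)))
  K2 <- compute_grm(g2)$matrix
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
  expect_equal(K2[1, 2], K2[2, 2], tolerance = 1e-12)

  ## monomorphic variants are excluded with a warning
  g3 <- make_geno(cbind(c(0L, 1L, 2L), c(0L, 0L, 0L)))
  expect_warning(K3 <- compute_grm(g3), "monomorphic")
  expect_equal(K3$n_variants_used, 1)
})

test_that("HWE-simulated GRM has mean diagonal near 1", {
  co <- sim_one_pop(n = 500, m = 1000, h2 = 0, n_causal = 0, seed = 21)
  K <- compute_grm(co$genotypes)
  expect_gt(mean(diag(K$matrix)), 0.95)
  expect_lt(mean(diag(K$matrix)), 1.05)
  expect_equal(K$matrix, t(K$matrix))
})

test_that("REML recovers a null and a planted heritability", {
  co0 <- sim_one_pop(n = 600, m = 800, h2 = 0, n_causal = 0, seed = 31,
                     covariate_effects = c(age = 0, sex = 0, height = 0,
                                           pack_years = 0))
  p0 <- co0$phenotypes
  f0 <- reml_fit(p0$trait, NULL, compute_grm(co0$genotypes))
  expect_lte(f0$h2, 0.05)

  co <- sim_one_pop(n = 600, m = 800, h2 = 0.5, n_causal = 100, seed = 32)
  p <- co$phenotypes
  Z <- as.matrix(p[, c("age", "sex", "height", "pack_years")])
  f <- reml_fit(p$trait, Z, compute_grm(co$genotypes))
  expect_lt(abs(f$h2 - 0.5), 0.15)
  expect_true(f$converged)
  expect_gte(f$sigma_g2, 0)
  expect_gt(f$sigma_e2, 0)
})

test_that("the optimizer is never beaten by a grid over the variance components", {
  co <- sim_one_pop(n = 200, m = 300, h2 = 0.4, n_causal = 20, seed = 33)
  p <- co$phenotypes
  Z <- as.matrix(p[, c("age", "sex", "height", "pack_years")])
  K <- compute_grm(co$genotypes)
  f <- reml_fit(p$trait, Z, K)
  vy <- var(p$trait)
  grid <- seq(1e-4, 2 * vy, length.out = 50)
  best_grid <- max(outer(grid, grid, Vectorize(function(a, b)
    reml_loglik(p$trait, Z, f$eigen, a, b))))
  expect_gte(f$loglik + 1e-4, best_grid)
})

test_that("REML is invariant to shifting the trait when an intercept is present", {
  co <- sim_one_pop(n = 150, m = 200, h2 = 0.4, n_causal = 10, seed = 34)
  p <- co$phenotypes
  Z <- as.matrix(p[, c("age", "sex")])
  K <- compute_grm(co$genotypes)
  f1 <- reml_fit(p$trait, Z, K)
  f2 <- reml_fit(p$trait + 100, Z, K)
  expect_equal(f1$sigma_g2, f2$sigma_g2, tolerance = 1e-6)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
  expect_equal(f2$fixed_effects[["(Intercept)"]] -
                 f1$fixed_effects[["(Intercept)"]], 100, tolerance = 1e-6)
})

test_that("collinear covariates are reported by name", {
  co <- sim_one_pop(n = 100, m = 60, seed = 35)
  p <- co$phenotypes
  Z <- cbind(age = p$age, age2 = p$age)
  expect_error(reml_fit(p$trait, Z, compute_grm(co$genotypes)), "collinear")
})

test_that("partitioned REML recovers concentration of signal on one chromosome", {
  cfg <- simulation_config(n_variants = 900, fst = 0.05, target_h2 = 0.5,
                           n_chromosomes = 3, seed = 36)
  ## all causal variants on chromosome 1 (first third of the panel)
  pop <- population_spec("P", 500, 0.3, causal_indices = seq(5, 295, by = 10))
  co <- simulate_cohort(cfg, list(pop))
  g <- co$genotypes
  grms <- lapply(split(seq_len(900), g$variants$chrom), function(ix)
    compute_grm(g, variant_subset = ix))
  p <- co$phenotypes
  Z <- as.matrix(p[, c("age", "sex", "height", "pack_years")])
  pf <- reml_fit_partitioned(p$trait, Z, grms)
  expect_true(pf$converged)
  expect_equal(sum(pf$shares), 1, tolerance = 1e-10)
  expect_gte(pf$shares[["1"]], 0.8)
})

test_that("partitioned REML agrees with the single-component fit", {
  co <- sim_one_pop(n = 250, m = 400, h2 = 0.4, n_causal = 40, seed = 37)
  p <- co$phenotypes
  Z <- as.matrix(p[, c("age", "sex")])
  K <- compute_grm(co$genotypes)
  f1 <- reml_fit(p$trait, Z, K)
  pf1 <- reml_fit_partitioned(p$trait, Z, list(K), tol_ll = 1e-12)
  expect_equal(pf1$sigma_c2[[1]], f1$sigma_g2, tolerance = 1e-6)
  expect_equal(pf1$loglik, f1$loglik, tolerance = 1e-8)
  ## duplicated component: only the total is identifiable
  pf2 <- reml_fit_partitioned(p$trait, Z, list(K, K))
  expect_equal(sum(pf2$sigma_c2), f1$sigma_g2, tolerance = 0.02)
})

test_that("partitioned REML finds nothing in a null simulation", {
  co <- sim_one_pop(n = 600, m = 450, h2 = 0, n_causal = 0, seed = 38)
  g <- co$genotypes
  grms <- lapply(split(seq_len(450), g$variants$chrom), function(ix)
    compute_grm(g, variant_subset = ix))
  p <- co$phenotypes
  pf <- reml_fit_partitioned(p$trait, NULL, grms)
  expect_true(all(pf$sigma_c2 <= 0.05 * var(p$trait)))
})

test_that("BLUP scores match the dense explicit-inverse evaluation", {
  co <- sim_one_pop(n = 200, m = 300, h2 = 0.5, n_causal = 20, seed = 39)
  p <- co$phenotypes
  Z <- as.matrix(p[, c("age", "sex", "height", "pack_years")])
  K <- compute_grm(co$genotypes)
  fit <- reml_fit(p$trait, Z, K)
  b <- blup_snp_effects(co$genotypes, K, p$trait, Z, fit)
  ## oracle: explicit inverse of (possibly jittered) K
  Km <- K$matrix
  if (min(eigen(Km, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    Km <- Km + diag(1e-8 * sum(diag(Km)) / nrow(Km), nrow(Km))
  Zm <- cbind(`(Intercept)` = 1, Z)
  r <- p$trait - drop(Zm %*% fit$fixed_effects)
  gs <- ethnoprs:::standardize_genotypes(co$genotypes)$matrix
  oracle <- unname(drop(crossprod(gs, solve(Km) %*% r))) / fit$sigma_g2
  expect_equal(b$score, oracle, tolerance = 1e-8)
})

test_that("BLUP annihilates a zero residual and is scale-equivariant in sigma_g2", {
  co <- sim_one_pop(n = 120, m = 150, h2 = 0.5, n_causal = 10, seed = 40)
  p <- co$phenotypes
  Z <- as.matrix(p[, c("age", "sex")])
  K <- compute_grm(co$genotypes)
  fit <- reml_fit(p$trait, Z, K)
  ## construct y lying exactly in the fixed-effect column space
  Zm <- cbind(1, Z)
  y0 <- drop(Zm %*% c(1, 0.5, -0.2))
  fit0 <- fit
  fit0$fixed_effects <- c(`(Intercept)` = 1, age = 0.5, sex = -0.2)
  b0 <- blup_snp_effects(co$genotypes, K, y0, Z, fit0)
  expect_true(all(abs(b0$score) < 1e-10))

  b1 <- blup_snp_effects(co$genotypes, K, p$trait, Z, fit)
  fit2 <- fit
  fit2$sigma_g2 <- fit$sigma_g2 * 3
  b2 <- blup_snp_effects(co$genotypes, K, p$trait, Z, fit2)
  expect_equal(b2$score * 3, b1$score, tolerance = 1e-10)
  expect_identical(order(-abs(b1$score)), order(-abs(b2$score)))

  fitz <- fit
  fitz$sigma_g2 <- 0
  expect_error(blup_snp_effects(co$genotypes, K, p$trait, Z, fitz),
               "boundary")
})

test_that("single-SNP regression matches a normal-equations oracle", {
  set.seed(41)
  n <- 12
  g <- make_geno(matrix(sample(0:2, n * 3, replace = TRUE), n, 3))
  y <- rnorm(n)
  Z <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  res <- per_snp_regression(g, y, Z)
  for (j in 1:3) {
    X <- cbind(1, Z, geno = g$values[, j])
    XtX <- crossprod(X)
    bh <- solve(XtX, crossprod(X, y))
    r <- y - X %*% bh
    s2 <- sum(r^2) / (n - ncol(X))
    se <- sqrt(s2 * solve(XtX)["geno", "geno"])
    tt <- bh["geno", 1] / se
    expect_equal(res$beta[j], unname(bh["geno", 1]), tolerance = 1e-10)
    expect_equal(res$se[j], unname(se), tolerance = 1e-10)
    expect_equal(res$p[j], unname(2 * pt(-abs(tt), n - ncol(X))),
                 tolerance = 1e-10)
  }
})

test_that("single-SNP regression p-values are calibrated under the null", {
  co <- sim_one_pop(n = 250, m = 3000, h2 = 0, n_causal = 0, seed = 42)
  p <- co$phenotypes
  res <- per_snp_regression(co$genotypes, p$trait,
                            as.matrix(p[, c("age", "sex")]))
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
  ## orthogonal genotype: effect near zero, p near one
  n <- 100
  y <- rnorm(n)
  gv <- rep(0:1, 50)
  y_orth <- y - gv * sum(y * (gv - mean(gv))) / sum((gv - mean(gv))^2) +
    mean(gv) * 0  # exact orthogonalization below
  r <- residuals(lm(y ~ gv))
  yo <- r   # residualized outcome is orthogonal to gv by construction
  g1 <- make_geno(matrix(as.integer(gv), n, 1))
  res2 <- per_snp_regression(g1, yo, NULL)
  expect_lt(abs(res2$beta[1]), 1e-10)
  expect_gt(res2$p[1], 0.999)
})
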