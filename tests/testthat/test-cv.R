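small_plan <- function(...) {
  cv_plan(n_outer = 3, n_inner = 4, p_grid = 20, penalty_grid = "ridge",
          lambda_grid = c(0.1, 0.01), seed = 5, ...)
}

test_that("stratified folds preserve the case proportion and the seed", {
  status <- rep(c(1, 0), c(30, 120))
  f1 <- make_stratified_folds(status, 5, seed = 3)
  f2 <- make_stratified_folds(status, 5, seed = 3)
  expect_identical(f1, f2)
  per_fold <- table(f1, status)
  expect_true(all(per_fold[, "1"] == 6))
  expect_true(all(per_fold[, "0"] == 24))
  f3 <- make_stratified_folds(status, 5, seed = 4)
  expect_false(identical(f1, f3))
})

test_that("a one-point tuning grid is selected and tuning is deterministic", {
  co <- sim_one_pop(n = 200, m = 100, h2 = 0.4, n_causal = 8, seed = 70)
  ranking <- co$genotypes$variants$id
  plan <- cv_plan(n_outer = 3, n_inner = 4, p_grid = 15,
                  penalty_grid = "ridge", lambda_grid = 0.05, seed = 9)
  t1 <- nested_cv_tune(co$genotypes, co$phenotypes, ranking, plan)
  expect_equal(t1$selected$p, 15)
  expect_equal(t1$selected$family, "ridge")
  expect_equal(t1$selected$lambda, 0.05)
  t2 <- nested_cv_tune(co$genotypes, co$phenotypes, ranking, plan)
  expect_identical(t1, t2)
})

test_that("tuning prefers the list size that isolates the signal", {
  ## causal variants sit at the head of the supplied ranking; the large
  ## list only adds pure noise columns
  co <- sim_one_pop(n = 400, m = 300, h2 = 0.6, n_causal = 10, seed = 71,
                    covariate_effects = c(age = 0, sex = 0, height = 0,
                                          pack_years = 0))
  causal_ids <- co$truth$POP$causal_ids
  ranking <- c(causal_ids, setdiff(co$genotypes$variants$id, causal_ids))
  plan <- cv_plan(n_outer = 3, n_inner = 5, p_grid = c(10, 300),
                  penalty_grid = "ridge", lambda_grid = c(0.05), seed = 12,
                  model = "genetics_only")
  sel <- nested_cv_tune(co$genotypes, co$phenotypes, ranking, plan)$selected
  expect_equal(sel$p, 10)
})

test_that("outer CV honors the leakage contract", {
  co <- sim_one_pop(n = 200, m = 150, h2 = 0.5, n_causal = 10, seed = 72)
  plan <- small_plan()
  cvres <- suppressWarnings(
    cross_validate_pipeline(co$genotypes, co$phenotypes, plan, "abs_blup"))
  expect_equal(nrow(cvres$fold_results), 3)
  expect_true(all(cvres$fold_results$auc >= 0 & cvres$fold_results$auc <= 1))
  ## permuting the held-out fold's phenotypes must leave the training-side
  ## screening output byte-identical
  k <- 1
  te <- which(cvres$folds == k)
  phen2 <- co$phenotypes
  set.seed(99)
  phen2$trait[te] <- sample(phen2$trait[te])
  phen2$status[te] <- sample(phen2$status[te])
  tr <- which(cvres$folds != k)
  g_tr <- subset_genotypes(co$genotypes, samples = tr)
  sc1 <- ethnoprs:::screen_scores(g_tr, co$phenotypes[tr, ], "abs_blup",
                                  plan$screen_covariates)
  sc2 <- ethnoprs:::screen_scores(g_tr, phen2[tr, ], "abs_blup",
                                  plan$screen_covariates)
  expect_identical(sc1, sc2)
  ## and rerunning the whole pipeline with the same seed reproduces it
  cvres2 <- suppressWarnings(
    cross_validate_pipeline(co$genotypes, co$phenotypes, plan, "abs_blup"))
  expect_identical(cvres$fold_results, cvres2$fold_results)
})

test_that("a covariates-only model runs and uses no variants", {
  co <- sim_one_pop(n = 200, m = 80, h2 = 0, n_causal = 0, seed = 73)
  plan <- small_plan(model = "covariates_only")
  cvres <- cross_validate_pipeline(co$genotypes, co$phenotypes, plan,
                                   "pvalue")
  expect_true(all(cvres$fold_results$p == 0))
  ## age and pack-years drive the trait, hence the thresholded status
  expect_gt(cvres$mean_auc, 0.6)
})

test_that("external validation is an identity on the training cohort", {
  co <- sim_one_pop(n = 200, m = 120, h2 = 0.5, n_causal = 10, seed = 74)
  mm <- ethnoprs:::build_model_matrix(co$genotypes, co$phenotypes,
                                      c("age", "sex", "pack_years"),
                                      co$truth$POP$causal_ids)
  fit <- fit_penalized_logistic(mm$X, co$phenotypes$status,
                                penalty_spec("ridge", 0.05), mm$mask,
                                variant_info = mm$variant_info)
  in_sample <- auc(predict_risk(fit, mm$X), co$phenotypes$status)
  ev <- external_validate(fit, co$genotypes, co$phenotypes)
  expect_equal(ev$auc, in_sample, tolerance = 1e-12)
  expect_equal(ev$n_matched, ev$n_model)
})

test_that("external validation harmonizes swapped alleles by dosage flip", {
  co <- sim_one_pop(n = 150, m = 60, h2 = 0.5, n_causal = 6, seed = 75)
  mm <- ethnoprs:::build_model_matrix(co$genotypes, co$phenotypes,
                                      "age", co$truth$POP$causal_ids)
  fit <- fit_penalized_logistic(mm$X, co$phenotypes$status,
                                penalty_spec("lasso", 0.01), mm$mask,
                                variant_info = mm$variant_info)
  base <- external_validate(fit, co$genotypes, co$phenotypes)
  ## swap allele labels and flip dosages: predictions must be unchanged
  g2 <- co$genotypes
  tmp <- g2$variants$allele_effect
  g2$variants$allele_effect <- g2$variants$allele_other
  g2$variants$allele_other <- tmp
  g2$values <- 2L - g2$values
  ev <- external_validate(fit, g2, co$phenotypes)
  expect_equal(ev$auc, base$auc, tolerance = 1e-12)

  ## unmatched variants trigger a warning below 50% and an error at zero
  g3 <- subset_genotypes(co$genotypes,
                         variants = co$truth$POP$causal_ids[1:2])
  expect_warning(ev3 <- external_validate(fit, g3, co$phenotypes),
                 "matched")
  expect_equal(ev3$n_matched, 2)
  g4 <- subset_genotypes(co$genotypes,
                         variants = setdiff(co$genotypes$variants$id,
                                            co$truth$POP$causal_ids))
  expect_error(external_validate(fit, g4, co$phenotypes), "no model variants")
  ## the two missing-variant policies coincide for additive scores
  ev_a <- suppressWarnings(external_validate(fit, g3, co$phenotypes,
                                             "drop_reweight"))
  ev_b <- suppressWarnings(external_validate(fit, g3, co$phenotypes,
                                             "zero_impute"))
  expect_equal(ev_a$auc, ev_b$auc)
})
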