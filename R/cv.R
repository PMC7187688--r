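#' Cross-validation plan
#'
#' Parameters of the nested cross-validation scheme: stratified outer
#' folds for performance estimation, stratified inner folds for tuning
#' (list size `p`, penalty family, lambda) by mean inner-validation AUC.
#'
#' @param n_outer Outer folds (default 5).
#' @param n_inner Inner folds (default 10).
#' @param p_grid Candidate screened-list sizes.
#' @param penalty_grid Candidate penalty families.
#' @param lambda_grid Fixed lambda grid, or `NULL` to derive one from the
#'   training data per (p, family) via [lambda_grid()].
#' @param n_lambda Grid size when `lambda_grid` is `NULL`.
#' @param covariates Clinical covariates entering the risk model
#'   unpenalized (default age, sex, pack-years).
#' @param screen_covariates Fixed effects of the screening mixed model.
#' @param model `"genetics_covariates"`, `"genetics_only"` or
#'   `"covariates_only"`.
#' @param alpha Elastic-net mixing for the `elastic_net` family.
#' @param seed Integer seed controlling fold assignment.
#' @return List of class `cv_plan`.
#' @export
cv_plan <- function(n_outer = 5L, n_inner = 10L,
                    p_grid = c(100L, 500L, 1000L, 5000L, 10000L),
                    penalty_grid = c("lasso", "ridge", "elastic_net"),
                    lambda_grid = NULL, n_lambda = 10L,
                    covariates = c("age", "sex", "pack_years"),
                    screen_covariates = c("age", "sex", "height",
                                          "pack_years"),
                    model = c("genetics_covariates", "genetics_only",
                              "covariates_only"),
                    alpha = 0.5, seed = 1L) {
  if (n_outer < 2 || n_inner < 2) stopf("folds must be >= 2")
  model <- match.arg(model)
  if (model != "covariates_only" && length(p_grid) < 1)
    stopf("`p_grid` must be non-empty")
  penalty_grid <- match.arg(penalty_grid,
                            c("lasso", "ridge", "elastic_net"),
                            several.ok = TRUE)
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 p_grid = as.integer(sort(p_grid)),
                 penalty_grid = penalty_grid, lambda_grid = lambda_grid,
                 n_lambda = as.integer(n_lambda), covariates = covariates,
                 screen_covariates = screen_covariates, model = model,
                 alpha = alpha, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Stratified fold assignment
#'
#' Shuffles cases and controls separately under the seed and deals each
#' class round-robin over the folds, preserving the case proportion per
#' fold.
#'
#' @param status Binary vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold labels in `1..k`.
#' @export
make_stratified_folds <- function(status, k, seed) {
  folds <- integer(length(status))
  with_seed(seed, {
    for (cls in unique(status)) {
      idx <- sample(which(status == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

## Design matrix for the risk model: clinical columns (unpenalized) +
## mean-imputed dosage columns for the selected variants (penalized).
build_model_matrix <- function(g, phen, covariates, variant_ids) {
  Xc <- if (length(covariates))
    as.matrix(phen[, covariates, drop = FALSE]) else
      matrix(0, nrow(phen), 0)
  if (length(variant_ids)) {
    gi <- subset_genotypes(g, variants = variant_ids)
    Gv <- mean_impute(gi)$values
    colnames(Gv) <- variant_ids
    X <- cbind(Xc, Gv)
    vi <- gi$variants[c("id", "allele_effect", "allele_other")]
  } else {
    X <- Xc
    vi <- NULL
  }
  list(X = X, mask = c(rep(FALSE, ncol(Xc)), rep(TRUE, length(variant_ids))),
       variant_info = vi)
}

## Fit a warm-started lambda path on one (X, y) and return AUCs on a
## validation set for each lambda.
.path_val_auc <- function(X, y, Xv, yv, family, lambdas, alpha, mask,
                          tol = 1e-6) {
  spec_a <- switch(family, lasso = 1, ridge = 0, elastic_net = alpha)
  binit <- NULL
  out <- numeric(length(lambdas))
  for (li in seq_along(lambdas)) {
    sp <- if (family == "elastic_net")
      penalty_spec(family, lambdas[li], alpha) else
        penalty_spec(family, lambdas[li])
    fit <- fit_penalized_logistic(X, y, sp, mask, tol = tol,
                                  beta_init = binit)
    binit <- fit$beta_internal
    out[li] <- auc(predict_risk(fit, Xv), yv)
  }
  out
}

#' Nested tuning of (p, penalty family, lambda) by inner-CV AUC
#'
#' For every grid point, the model is fitted on `n_inner - 1` stratified
#' inner folds of the training data and scored by AUC on the held-out
#' inner fold; the grid point with the largest mean AUC wins. Ties break
#' toward smaller `p`, then larger lambda (the sparser, more regularized
#' model). Inner folds whose validation part has a single class are
#' skipped with a warning. The screening ranking is computed once on the
#' whole training set and fixed during tuning.
#'
#' @param g Training-set [genotype_matrix()].
#' @param phen Training-set phenotype table.
#' @param ranking_ids Variant ids in screening-rank order (best first).
#' @param plan A [cv_plan()].
#' @return List: `selected` (`p`, `family`, `lambda`, `alpha`), `table`
#'   (mean inner AUC per grid point).
#' @export
nested_cv_tune <- function(g, phen, ranking_ids, plan) {
  stopifnot(inherits(plan, "cv_plan"))
  y <- phen$status
  ## a one-point grid needs no inner folds: the single candidate wins
  if (length(plan$p_grid) == 1 && length(plan$penalty_grid) == 1 &&
      length(plan$lambda_grid) == 1) {
    return(list(selected = list(p = min(plan$p_grid, length(ranking_ids)),
                                family = plan$penalty_grid,
                                lambda = plan$lambda_grid,
                                alpha = plan$alpha),
                table = data.frame(p = plan$p_grid,
                                   family = plan$penalty_grid,
                                   lambda = plan$lambda_grid,
                                   mean_auc = NA_real_, n_folds = 0L)))
  }
  folds <- make_stratified_folds(y, plan$n_inner,
                                 derive_seed(plan$seed, 31L))
  covs <- if (plan$model == "genetics_only") character(0) else
    intersect(plan$covariates, names(phen))
  p_grid <- pmin(plan$p_grid, length(ranking_ids))
  p_grid <- unique(p_grid)
  rows <- list()
  for (p in p_grid) {
    vids <- ranking_ids[seq_len(p)]
    mm <- build_model_matrix(g, phen, covs, vids)
    for (family in plan$penalty_grid) {
      lambdas <- plan$lambda_grid
      if (is.null(lambdas))
        lambdas <- lambda_grid(mm$X, y, mm$mask,
                               alpha = switch(family, lasso = 1, ridge = 0,
                                              elastic_net = plan$alpha),
                               n_lambda = plan$n_lambda)
      lambdas <- sort(lambdas, decreasing = TRUE)
      aucs <- matrix(NA_real_, plan$n_inner, length(lambdas))
      for (f in seq_len(plan$n_inner)) {
        tr <- folds != f; va <- !tr
        if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2) {
          warnf("inner fold %d skipped: single-class validation set", f)
          next
        }
        aucs[f, ] <- .path_val_auc(mm$X[tr, , drop = FALSE], y[tr],
                                   mm$X[va, , drop = FALSE], y[va],
                                   family, lambdas, plan$alpha, mm$mask)
      }
      usable <- colSums(!is.na(aucs)) > 0
      if (!any(usable)) stopf("all inner folds were skipped")
      rows[[length(rows) + 1L]] <- data.frame(
        p = p, family = family, lambda = lambdas,
        mean_auc = colMeans(aucs, na.rm = TRUE),
        n_folds = colSums(!is.na(aucs)))
    }
  }
  tab <- do.call(rbind, rows)
  ## argmax with deterministic ties: smaller p, then larger lambda, then
  ## penalty_grid order
  fam_rank <- match(tab$family, plan$penalty_grid)
  best <- order(-tab$mean_auc, tab$p, -tab$lambda, fam_rank)[1]
  list(selected = list(p = tab$p[best], family = tab$family[best],
                       lambda = tab$lambda[best], alpha = plan$alpha),
       table = tab)
}

#' Outer cross-validation of the full screening + prediction pipeline
#'
#' For each stratified outer fold: the screening stack (GRM, REML, BLUP or
#' single-SNP p-values) runs on the outer-training samples only, tuning
#' runs by [nested_cv_tune()] within the outer-training set, the selected
#' model is refitted on the whole outer-training set, and AUC is measured
#' on the held-out fold. Held-out samples never enter screening or tuning.
#' If REML puts `sigma_g2` on the zero boundary under the `abs_blup`
#' criterion, that fold falls back to the p-value ranking with a logged
#' notice.
#'
#' @param g A [genotype_matrix()] (after QC).
#' @param phen Aligned phenotype table with `status` and covariates.
#' @param plan A [cv_plan()].
#' @param criterion_kind `"abs_blup"` or `"pvalue"`.
#' @param folds Optional precomputed outer-fold labels (for reproducing a
#'   run); default stratified assignment under the plan seed.
#' @return List of class `cv_result`: `fold_results` (per-fold AUC and
#'   selected tuning), `mean_auc`, `sd_auc`, `models`, `rankings` (per-fold
#'   screening order), `folds`.
#' @export
cross_validate_pipeline <- function(g, phen, plan,
                                    criterion_kind = c("abs_blup", "pvalue"),
                                    folds = NULL) {
  stopifnot(inherits(plan, "cv_plan"))
  criterion_kind <- match.arg(criterion_kind)
  y <- phen$status
  if (is.null(folds))
    folds <- make_stratified_folds(y, plan$n_outer,
                                   derive_seed(plan$seed, 21L))
  res <- list(); models <- list(); rankings <- list()
  covs <- if (plan$model == "genetics_only") character(0) else
    intersect(plan$covariates, names(phen))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    g_tr <- subset_genotypes(g, samples = which(tr))
    ph_tr <- phen[tr, , drop = FALSE]
    if (plan$model == "covariates_only") {
      mm <- build_model_matrix(g_tr, ph_tr, covs, character(0))
      fit <- fit_penalized_logistic(mm$X, ph_tr$status,
                                    penalty_spec("lasso", 0), mm$mask)
      sel <- list(p = 0L, family = "none", lambda = 0)
      rankings[[k]] <- character(0)
    } else {
      sc <- screen_scores(g_tr, ph_tr, criterion_kind,
                          plan$screen_covariates)
      full <- select_top_snps(sc, screen_criterion(
        if ("score" %in% names(sc)) "abs_blup" else "pvalue",
        p = nrow(sc)), variants = g_tr$variants, source = paste0("fold", k))
      rankings[[k]] <- full$ids
      tune <- nested_cv_tune(g_tr, ph_tr, full$ids, plan)
      sel <- tune$selected
      vids <- full$ids[seq_len(sel$p)]
      mm <- build_model_matrix(g_tr, ph_tr, covs, vids)
      sp <- if (sel$family == "elastic_net")
        penalty_spec(sel$family, sel$lambda, sel$alpha) else
          penalty_spec(sel$family, sel$lambda)
      fit <- fit_penalized_logistic(mm$X, ph_tr$status, sp, mm$mask,
                                    variant_info = mm$variant_info)
    }
    te <- which(!tr)
    mm_te <- build_model_matrix(subset_genotypes(g, samples = te),
                                phen[te, , drop = FALSE], covs,
                                if (plan$model == "covariates_only")
                                  character(0) else
                                    names(which(fit$penalized)))
    fold_auc <- auc(predict_risk(fit, mm_te$X), y[te])
    res[[k]] <- data.frame(fold = k, p = sel$p, family = sel$family,
                           lambda = sel$lambda, auc = fold_auc)
    models[[k]] <- fit
  }
  fr <- do.call(rbind, res)
  structure(list(fold_results = fr, mean_auc = mean(fr$auc),
                 sd_auc = sd(fr$auc), models = models,
                 rankings = rankings, folds = folds, plan = plan,
                 criterion = criterion_kind),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validated AUC: %.3f (SD %.4f) over %d folds [%s]\n",
              x$mean_auc, x$sd_auc, nrow(x$fold_results), x$criterion))
  print(x$fold_results, row.names = FALSE)
  invisible(x)
}

#' Apply a fitted risk model to an independent cohort
#'
#' Matches the model's variants to the target cohort by id and alleles
#' (flipping dosages when effect/other labels are interchanged; mismatched
#' labels stay unmatched) and reports the AUC of the transferred model on
#' the target cohort. Unmatched model variants contribute nothing to the
#' linear predictor under either policy (`drop_reweight` and `zero_impute`
#' coincide for additive scores); counts are logged.
#'
#' @param model A [fit_penalized_logistic()] result carrying
#'   `variant_info`.
#' @param target_g Target cohort [genotype_matrix()].
#' @param target_phen Target phenotype table with `status` and the model's
#'   clinical covariates.
#' @param missing_policy `"drop_reweight"` or `"zero_impute"`.
#' @return List of class `external_validation`: `n_model`, `n_matched`,
#'   `auc`, `policy`, `log`.
#' @export
external_validate <- function(model, target_g, target_phen,
                              missing_policy = c("drop_reweight",
                                                 "zero_impute")) {
  stopifnot(inherits(model, "penalized_model"),
            inherits(target_g, "genotype_matrix"))
  missing_policy <- match.arg(missing_policy)
  vi <- model$variant_info
  n_model <- if (is.null(vi)) 0L else nrow(vi)
  tv <- target_g$variants
  matched_ids <- character(0); flip <- logical(0)
  if (n_model > 0) {
    mi <- match(vi$id, tv$id)
    found <- !is.na(mi)
    same <- found & tv$allele_effect[mi] == vi$allele_effect &
      tv$allele_other[mi] == vi$allele_other
    swap <- found & tv$allele_effect[mi] == vi$allele_other &
      tv$allele_other[mi] == vi$allele_effect
    keep <- which(same | swap)
    matched_ids <- vi$id[keep]
    flip <- swap[keep]
    if (length(matched_ids) == 0 && n_model > 0)
      stopf("no model variants could be matched in the target cohort")
    if (length(matched_ids) < 0.5 * n_model)
      warnf("only %d of %d model variants matched in the target cohort",
            length(matched_ids), n_model)
  }
  covs <- intersect(model$clinical, names(target_phen))
  if (length(covs) < length(model$clinical))
    stopf("target phenotypes lack clinical column(s): %s",
          paste(setdiff(model$clinical, covs), collapse = ", "))
  Xc <- if (length(covs)) as.matrix(target_phen[, covs, drop = FALSE]) else
    matrix(0, nrow(target_phen), 0)
  eta <- rep(model$coefficients[["(Intercept)"]], nrow(target_phen))
  if (length(covs))
    eta <- eta + drop(Xc %*% model$coefficients[covs])
  if (length(matched_ids)) {
    gd <- mean_impute(subset_genotypes(target_g,
                                       variants = matched_ids))$values
    gd[, flip] <- 2 - gd[, flip]
    eta <- eta + drop(gd %*% model$coefficients[matched_ids])
  }
  a <- auc(plogis(eta), target_phen$status)
  structure(list(n_model = n_model, n_matched = length(matched_ids),
                 auc = a, policy = missing_policy,
                 log = sprintf(
                   "%d/%d model variants matched (%d flipped); policy %s",
                   length(matched_ids), n_model, sum(flip), missing_policy)),
            class = "external_validation")
}
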