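#' Binomial deviance between observed status and predicted probabilities
#'
#' `Delta = sum_i { Y_i log(Y_i / mu_i) + (1 - Y_i) log((1 - Y_i)/(1 - mu_i)) }`
#' with the convention `0 * log 0 = 0`, which for binary `Y` reduces to
#' the Bernoulli cross-entropy `-sum( y log mu + (1-y) log(1-mu) )`.
#' No factor of two is applied. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param y Binary labels.
#' @param mu_hat Predicted probabilities.
#' @return Non-negative deviance.
#' @export
deviance_binary <- function(y, mu_hat) {
  if (length(y) != length(mu_hat))
    stopf("`y` and `mu_hat` differ in length")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("`y` must be binary 0/1")
  mu <- pmin(pmax(mu_hat, 1e-12), 1 - 1e-12)
  -sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' McFadden's pseudo R-squared (percent)
#'
#' `(1 - delta_full / delta_null) * 100`: the percentage of the null
#' deviance explained by the model. Can be negative when an overfit model
#' predicts out-of-fold worse than the prevalence.
#'
#' @param delta_full Deviance of the fitted model.
#' @param delta_null Deviance of the null (prevalence-only) model; must be
#'   positive.
#' @return Percentage.
#' @export
mcfadden_r2 <- function(delta_full, delta_null) {
  if (delta_null <= 0)
    stopf("null deviance is zero: outcome has a single class")
  (1 - delta_full / delta_null) * 100
}

#' Deviance decomposition of variable contributions
#'
#' Quantifies each variable group's share of outcome variability in the
#' selected risk model: the full model's explained variability is
#' McFadden's `(1 - Delta_F / Delta_0) * 100`, and the contribution of
#' group `i` is `(Delta_i - Delta_F) / Delta_0 * 100` where `Delta_i`
#' refits the model without that group. Groups are each clinical covariate
#' individually plus the whole SNP block (removal of the SNP block leaves
#' the covariate-only model; clinical-group removal leaves screening
#' untouched). By default all deviances come from out-of-fold predictions
#' over shared stratified folds, with the null model predicting each test
#' fold by its training-fold prevalence; `refit = "in_sample"` instead
#' refits once on all samples. Fold assignment and the tuning selection
#' are fixed across the leave-one-group-out refits so differences isolate
#' the removed group. Negative contributions (shared signal) are reported
#' as computed.
#'
#' @param g A [genotype_matrix()].
#' @param phen Aligned phenotype table.
#' @param model_spec List with `criterion` (`"abs_blup"`/`"pvalue"`), `p`,
#'   `family`, `lambda`, optional `alpha`, `covariates`,
#'   `screen_covariates`.
#' @param n_folds Folds for the out-of-fold protocol.
#' @param seed Seed for fold assignment.
#' @param refit `"out_of_fold"` (default) or `"in_sample"`.
#' @return List of class `deviance_report`: `delta_null`, `delta_full`,
#'   `mcfadden_pct`, `unexplained_pct`, `contributions` (named, percent,
#'   groups = covariates plus `SNPs`).
#' @export
variable_contributions <- function(g, phen, model_spec, n_folds = 5L,
                                   seed = 1L,
                                   refit = c("out_of_fold", "in_sample")) {
  refit <- match.arg(refit)
  covs <- model_spec$covariates
  if (is.null(covs)) covs <- c("age", "sex", "pack_years")
  covs <- intersect(covs, names(phen))
  screen_covs <- model_spec$screen_covariates
  if (is.null(screen_covs)) screen_covs <- c("age", "sex", "height",
                                             "pack_years")
  alpha <- if (is.null(model_spec$alpha)) 0.5 else model_spec$alpha
  groups <- c(covs, "SNPs")
  y <- phen$status
  spec_penalty <- function() {
    if (model_spec$family == "elastic_net")
      penalty_spec(model_spec$family, model_spec$lambda, alpha) else
        penalty_spec(model_spec$family, model_spec$lambda)
  }
  fit_variant <- function(g_tr, ph_tr, drop_group, vids) {
    use_covs <- setdiff(covs, drop_group)
    use_vids <- if (identical(drop_group, "SNPs")) character(0) else vids
    mm <- build_model_matrix(g_tr, ph_tr, use_covs, use_vids)
    if (ncol(mm$X) == 0)
      mm$X <- matrix(numeric(0), nrow(ph_tr), 0,
                     dimnames = list(NULL, character(0)))
    fit_penalized_logistic(mm$X, ph_tr$status, spec_penalty(), mm$mask,
                           variant_info = mm$variant_info)
  }
  predict_variant <- function(fit, g_te, ph_te) {
    vids <- names(which(fit$penalized))
    mm <- build_model_matrix(g_te, ph_te, fit$clinical, vids)
    predict_risk(fit, mm$X)
  }
  screen_ids <- function(g_tr, ph_tr) {
    sc <- screen_scores(g_tr, ph_tr, model_spec$criterion, screen_covs)
    kind <- if ("score" %in% names(sc)) "abs_blup" else "pvalue"
    select_top_snps(sc, screen_criterion(kind,
                                         min(model_spec$p, nrow(sc))),
                    variants = g_tr$variants)$ids
  }

  dn <- df <- 0
  di <- setNames(numeric(length(groups)), groups)
  if (refit == "out_of_fold") {
    folds <- make_stratified_folds(y, n_folds, derive_seed(seed, 41L))
    for (k in sort(unique(folds))) {
      tr <- folds != k; te <- !tr
      g_tr <- subset_genotypes(g, samples = which(tr))
      g_te <- subset_genotypes(g, samples = which(te))
      ph_tr <- phen[tr, , drop = FALSE]; ph_te <- phen[te, , drop = FALSE]
      vids <- screen_ids(g_tr, ph_tr)
      full <- fit_variant(g_tr, ph_tr, character(0), vids)
      df <- df + deviance_binary(y[te], predict_variant(full, g_te, ph_te))
      dn <- dn + deviance_binary(y[te], rep(mean(y[tr]), sum(te)))
      for (grp in groups) {
        red <- fit_variant(g_tr, ph_tr, grp, vids)
        di[grp] <- di[grp] +
          deviance_binary(y[te], predict_variant(red, g_te, ph_te))
      }
    }
  } else {
    vids <- screen_ids(g, phen)
    full <- fit_variant(g, phen, character(0), vids)
    df <- deviance_binary(y, predict_variant(full, g, phen))
    dn <- deviance_binary(y, rep(mean(y), length(y)))
    for (grp in groups) {
      red <- fit_variant(g, phen, grp, vids)
      di[grp] <- deviance_binary(y, predict_variant(red, g, phen))
    }
  }
  mcf <- mcfadden_r2(df, dn)
  contrib <- (di - df) / dn * 100
  if (any(contrib < 0))
    message("negative contribution(s) reported as computed: ",
            paste(names(contrib)[contrib < 0], collapse = ", "))
  structure(list(delta_null = dn, delta_full = df, mcfadden_pct = mcf,
                 unexplained_pct = 100 - mcf, contributions = contrib,
                 refit = refit),
            class = "deviance_report")
}

#' @export
print.deviance_report <- function(x, ...) {
  cat(sprintf("deviance decomposition (%s): Delta0 = %.2f, DeltaF = %.2f\n",
              x$refit, x$delta_null, x$delta_full))
  cat(sprintf("  Unexplained %6.2f%%\n", x$unexplained_pct))
  for (g in names(x$contributions))
    cat(sprintf("  %-12s %6.2f%%\n", g, x$contributions[[g]]))
  invisible(x)
}
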