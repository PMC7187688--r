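## End-to-end orchestration of the stratified polygenic-risk workflow.

#' Validate a pipeline configuration
#'
#' A configuration (R list or YAML file) holds exactly one data source —
#' a `simulation` block or an `inputs` block (`geno_prefix`, `dialect`,
#' `pheno`) — plus optional `qc` thresholds, a `cv` block (fields of
#' [cv_plan()]), a `screening` block (`criterion`, `p`), a `decomposition`
#' block, and a top-level `seed`.
#'
#' @param config List or path to a YAML file.
#' @return The validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or YAML path")
  has_sim <- !is.null(config$simulation)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stopf("config must have exactly one of `simulation` or `inputs`")
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (has_sim) {
    s <- config$simulation
    for (f in c("n_variants", "populations"))
      if (is.null(s[[f]])) stopf("simulation block needs `%s`", f)
    for (p in s$populations)
      for (f in c("label", "n_samples", "case_fraction"))
        if (is.null(p[[f]])) stopf("each population needs `%s`", f)
  } else {
    for (f in c("geno_prefix", "pheno"))
      if (is.null(config$inputs[[f]])) stopf("inputs block needs `%s`", f)
  }
  structure(config, class = c("pipeline_config", "list"))
}

.cfg_populations <- function(s, seed) {
  n_causal <- if (is.null(s$n_causal)) 20L else as.integer(s$n_causal)
  overlap <- if (is.null(s$causal_overlap)) 0 else s$causal_overlap
  if (length(s$populations) == 2 && is.null(s$populations[[1]]$causal_indices)) {
    return(two_population_specs(
      s$populations[[1]]$n_samples, s$populations[[2]]$n_samples,
      s$populations[[1]]$case_fraction, s$populations[[2]]$case_fraction,
      n_causal = n_causal, overlap = overlap, n_variants = s$n_variants,
      labels = c(s$populations[[1]]$label, s$populations[[2]]$label)))
  }
  lapply(s$populations, function(p) {
    ci <- p$causal_indices
    if (is.null(ci)) {
      k <- match(p$label, vapply(s$populations, `[[`, "", "label"))
      ci <- with_seed(derive_seed(seed, 900L + k),
                      sort(sample.int(s$n_variants, n_causal)))
    }
    population_spec(p$label, p$n_samples, p$case_fraction, ci)
  })
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  path
}

.report_to_list <- function(r) {
  list(axis = r$axis, n_in = r$n_in, n_out = r$n_out,
       n_removed = as.list(r$n_removed),
       removed = lapply(r$removed, as.character))
}

#' Run the full stratified polygenic-risk pipeline
#'
#' Executes: cohort acquisition (simulation or files), per-group variant
#' and sample QC, cross-group variant intersection, per-group heritability
#' estimation (REML), top-p screening, outer cross-validation with nested
#' tuning, best-model refit, between-group top-list overlap, pairwise
#' cross-group external validation, and deviance decomposition — writing a
#' TSV/JSON artifact tree plus a manifest of versions, seeds and file
#' hashes. Identical (config, seed) produce byte-identical numerical
#' artifacts.
#'
#' @param config A [pipeline_config()] (or list/YAML path coercible to
#'   one).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest list. On stage failure the error names
#'   the stage and partial artifacts are preserved.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(package = "ethnoprs",
                   version = as.character(utils::packageVersion("ethnoprs")),
                   seed = seed, stages = character(0))
  logf <- file.path(out_dir, "pipeline.log")
  cat(sprintf("[%s] pipeline start, seed %d\n",
              format(Sys.time()), seed), file = logf)
  log_line <- function(...) cat(sprintf(...), "\n", file = logf,
                                append = TRUE, sep = "")
  stage <- "init"
  on.exit({
    manifest$failed_stage <- stage
    .write_json(manifest, file.path(out_dir, "manifest.json"))
  })

  ## ---- Stage: acquire cohort ----
  stage <- "acquire"
  if (!is.null(config$simulation)) {
    s <- config$simulation
    cfg <- simulation_config(
      n_variants = s$n_variants,
      fst = if (is.null(s$fst)) 0.1 else s$fst,
      target_h2 = if (is.null(s$target_h2)) 0.4 else s$target_h2,
      n_chromosomes = if (is.null(s$n_chromosomes)) 5L else s$n_chromosomes,
      seed = seed)
    pops <- .cfg_populations(s, seed)
    cohort <- simulate_cohort(cfg, pops)
    g_all <- cohort$genotypes
    phen_all <- cohort$phenotypes
    .write_json(lapply(cohort$truth, function(t)
      t[c("causal_ids", "scaled_effects", "realized_h2",
          "case_fraction_realized")]),
      file.path(out_dir, "truth.json"))
  } else {
    dialect <- if (is.null(config$inputs$dialect)) "plink_bed" else
      config$inputs$dialect
    g_all <- read_genotypes(config$inputs$geno_prefix, dialect)
    phen_all <- read_phenotypes(config$inputs$pheno)
  }
  groups <- split(seq_len(nrow(phen_all)), phen_all$ethnicity)
  log_line("acquired %d samples x %d variants in %d group(s)",
           nrow(g_all$values), ncol(g_all$values), length(groups))

  ## ---- Stage: QC per group ----
  stage <- "qc"
  thr <- do.call(qc_thresholds, if (is.null(config$qc)) list() else
    config$qc)
  qcd <- list()
  for (lab in names(groups)) {
    gi <- subset_genotypes(g_all, samples = groups[[lab]])
    pi <- phen_all[groups[[lab]], , drop = FALSE]
    sres <- snp_qc_filter(gi, thr)
    mres <- suppressMessages(sample_qc_filter(sres$genotypes, pi, thr))
    qcd[[lab]] <- list(g = mres$genotypes, phen = mres$phenotypes)
    .write_json(list(variants = .report_to_list(sres$report),
                     samples = .report_to_list(mres$report)),
                file.path(out_dir, sprintf("qc_%s.json", lab)))
    log_line("QC %s: variants %d -> %d, samples %d -> %d", lab,
             sres$report$n_in, sres$report$n_out,
             mres$report$n_in, mres$report$n_out)
  }

  ## ---- Stage: variant intersection across groups ----
  stage <- "intersect"
  if (length(qcd) > 1) {
    iv <- intersect_variants(lapply(qcd, `[[`, "g"))
    for (k in seq_along(qcd)) qcd[[k]]$g <- iv$cohorts[[k]]
    write.table(iv$log, file.path(out_dir, "intersection_dropped.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("intersection: %d shared variants retained",
             ncol(qcd[[1]]$g$values))
  }

  ## ---- Stage: per-group heritability, screening, CV ----
  stage <- "per_group"
  scr <- config$screening
  crit_kind <- if (is.null(scr$criterion)) "abs_blup" else scr$criterion
  top_p <- if (is.null(scr$p)) 100L else as.integer(scr$p)
  cv_args <- if (is.null(config$cv)) list() else config$cv
  top_lists <- list(); best_models <- list(); herit <- list()
  for (lab in names(qcd)) {
    gi <- qcd[[lab]]$g; pi <- qcd[[lab]]$phen
    plan <- do.call(cv_plan, modifyList(
      list(seed = derive_seed(seed, 100L + match(lab, names(qcd)))),
      cv_args))
    scov <- intersect(plan$screen_covariates, names(pi))
    K <- compute_grm(gi)
    fit <- reml_fit(pi$trait, as.matrix(pi[, scov, drop = FALSE]), K)
    herit[[lab]] <- list(sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                         h2 = fit$h2, se_h2 = unname(fit$se[["h2"]]))
    sc <- screen_scores(gi, pi, crit_kind, scov)
    kind_eff <- if ("score" %in% names(sc)) "abs_blup" else "pvalue"
    tl <- select_top_snps(sc, screen_criterion(kind_eff,
                                               min(top_p, nrow(sc))),
                          variants = gi$variants, source = lab)
    top_lists[[lab]] <- tl
    write.table(data.frame(rank = seq_along(tl$ids), id = tl$ids),
                file.path(out_dir, sprintf("top_snps_%s.tsv", lab)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cvres <- cross_validate_pipeline(gi, pi, plan, crit_kind)
    write.table(cvres$fold_results,
                file.path(out_dir, sprintf("cv_%s.tsv", lab)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ## best model: refit on all samples with the most frequently selected
    ## tuning (ties toward the better mean AUC fold)
    seltab <- cvres$fold_results
    key <- paste(seltab$p, seltab$family, signif(seltab$lambda, 8))
    pick <- seltab[key == names(sort(table(key), decreasing = TRUE))[1], ][1, ]
    ranking <- select_top_snps(sc, screen_criterion(kind_eff, nrow(sc)),
                               variants = gi$variants)$ids
    covs <- if (plan$model == "genetics_only") character(0) else
      intersect(plan$covariates, names(pi))
    mm <- build_model_matrix(gi, pi, covs, ranking[seq_len(pick$p)])
    sp <- if (pick$family == "elastic_net")
      penalty_spec(pick$family, pick$lambda, plan$alpha) else
        penalty_spec(pick$family, pick$lambda)
    best <- fit_penalized_logistic(mm$X, pi$status, sp, mm$mask,
                                   variant_info = mm$variant_info)
    best_models[[lab]] <- best
    .write_json(list(group = lab, p = pick$p, family = pick$family,
                     lambda = pick$lambda,
                     cv_mean_auc = cvres$mean_auc, cv_sd_auc = cvres$sd_auc,
                     coefficients = as.list(best$coefficients),
                     variants = best$variant_info),
                file.path(out_dir, sprintf("best_model_%s.json", lab)))
    log_line("%s: h2 = %.3f, cv AUC = %.3f (SD %.3f), best (p=%d, %s, lambda=%.4g)",
             lab, fit$h2, cvres$mean_auc, cvres$sd_auc, pick$p,
             pick$family, pick$lambda)
  }
  .write_json(herit, file.path(out_dir, "heritability.json"))

  ## ---- Stage: between-group overlap ----
  stage <- "overlap"
  if (length(top_lists) > 1) {
    ov <- overlap_between_groups(top_lists)
    .write_json(list(p = ov$p, pairwise = ov$pairwise,
                     allway_count = ov$allway_count,
                     allway_proportion = ov$allway_proportion,
                     null_expected_pairwise = ov$null_expected_pairwise),
                file.path(out_dir, "overlap.json"))
  }

  ## ---- Stage: pairwise external validation ----
  stage <- "external_validation"
  if (length(best_models) > 1) {
    rows <- list()
    for (a in names(best_models)) for (b in names(qcd)) {
      ev <- suppressWarnings(
        external_validate(best_models[[a]], qcd[[b]]$g, qcd[[b]]$phen))
      rows[[paste(a, b)]] <- data.frame(model = a, target = b,
                                        n_model = ev$n_model,
                                        n_matched = ev$n_matched,
                                        auc = ev$auc)
    }
    write.table(do.call(rbind, rows),
                file.path(out_dir, "external_validation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- Stage: deviance decomposition ----
  stage <- "decomposition"
  dec_cfg <- config$decomposition
  if (is.null(dec_cfg$skip) || !isTRUE(dec_cfg$skip)) {
    for (lab in names(qcd)) {
      bm <- jsonlite::read_json(file.path(out_dir,
                                          sprintf("best_model_%s.json", lab)))
      spec <- list(criterion = crit_kind, p = bm$p, family = bm$family,
                   lambda = bm$lambda)
      dr <- suppressMessages(variable_contributions(
        qcd[[lab]]$g, qcd[[lab]]$phen, spec,
        seed = derive_seed(seed, 300L + match(lab, names(qcd))),
        refit = if (is.null(dec_cfg$refit)) "out_of_fold" else dec_cfg$refit))
      tab <- data.frame(
        variable = c("Unexplained", names(dr$contributions)),
        percent = c(dr$unexplained_pct, unname(dr$contributions)))
      write.table(tab, file.path(out_dir, sprintf("deviance_%s.tsv", lab)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## ---- Stage: manifest ----
  stage <- "manifest"
  files <- setdiff(list.files(out_dir), c("manifest.json", "pipeline.log"))
  manifest$stages <- c("acquire", "qc", "intersect", "per_group", "overlap",
                       "external_validation", "decomposition")
  manifest$files <- as.list(tools::md5sum(file.path(out_dir, sort(files))))
  names(manifest$files) <- sort(files)
  on.exit()   # success: no failed_stage entry
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  log_line("pipeline complete")
  invisible(manifest)
}
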