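#' Screening criterion
#'
#' @param kind `"abs_blup"` (rank by largest absolute BLUP score) or
#'   `"pvalue"` (rank by smallest association p-value).
#' @param p Number of variants to keep.
#' @return List of class `screen_criterion`.
#' @export
screen_criterion <- function(kind = c("abs_blup", "pvalue"), p = 100L) {
  kind <- match.arg(kind)
  if (!is_count(p) || p < 1) stopf("`p` must be a positive integer")
  structure(list(kind = kind, p = as.integer(p)), class = "screen_criterion")
}

#' Select the top-p variants from screening scores
#'
#' Ranks by descending `|score|` (`abs_blup`) or ascending `p`
#' (`pvalue`); ties are broken by ascending (chromosome, position, id) so
#' the selection is a deterministic total order. Smaller lists are always
#' prefixes of larger ones built from the same scores.
#'
#' @param scores A [blup_snp_effects()] or [per_snp_regression()] result
#'   (any data.frame with `id` and `score` or `p`).
#' @param criterion A [screen_criterion()].
#' @param variants Optional variant metadata (`id`, `chrom`, `pos`) for the
#'   genomic tie-break; without it ties fall back to id order.
#' @param panel Optional character vector of panel variant ids recorded for
#'   overlap bookkeeping (defaults to all score ids).
#' @param source Label describing the originating cohort/fold.
#' @return List of class `topsnp_list`: `ids` (ranking order), `criterion`,
#'   `source`, `panel`.
#' @export
select_top_snps <- function(scores, criterion, variants = NULL,
                            panel = NULL, source = "") {
  stopifnot(inherits(criterion, "screen_criterion"))
  if (nrow(scores) < 1) stopf("no scores supplied")
  key <- if (criterion$kind == "abs_blup") {
    if (!"score" %in% names(scores))
      stopf("abs_blup criterion needs a `score` column")
    -abs(scores$score)
  } else {
    if (!"p" %in% names(scores)) stopf("pvalue criterion needs a `p` column")
    scores$p
  }
  if (!is.null(variants)) {
    mi <- match(scores$id, variants$id)
    chrom <- variants$chrom[mi]; pos <- variants$pos[mi]
  } else {
    chrom <- rep(0L, nrow(scores)); pos <- rep(0L, nrow(scores))
  }
  ## numeric chromosomes sort numerically, others lexically after them
  chrom_n <- suppressWarnings(as.numeric(chrom))
  ord <- order(key, !is.finite(chrom_n), chrom_n, as.character(chrom),
               pos, scores$id)
  p_eff <- criterion$p
  if (p_eff > nrow(scores)) {
    warnf("requested top %d of %d variants; returning all", p_eff,
          nrow(scores))
    p_eff <- nrow(scores)
  }
  structure(list(ids = scores$id[ord[seq_len(p_eff)]], criterion = criterion,
                 source = source,
                 panel = if (is.null(panel)) sort(scores$id) else sort(panel)),
            class = "topsnp_list")
}

#' Overlap of top-SNP lists between groups
#'
#' Exact set intersections of same-sized top lists built over a shared
#' variant panel: all pairwise counts plus the all-way intersection, with
#' proportions relative to the list size `p`. The hypergeometric null
#' expectation for a pairwise intersection (`p^2 / n_panel`) is reported
#' alongside for reference.
#'
#' @param lists Named list of two or more [select_top_snps()] results.
#' @param mode Bookkeeping label, `"between_groups"` or
#'   `"within_group_splits"`.
#' @return List of class `overlap_report`.
#' @export
overlap_between_groups <- function(lists, mode = "between_groups") {
  if (length(lists) < 2) stopf("need at least two lists")
  for (l in lists) stopifnot(inherits(l, "topsnp_list"))
  panel <- lists[[1]]$panel
  for (l in lists[-1])
    if (!identical(l$panel, panel))
      stopf("top-SNP lists were built over non-identical variant panels")
  sizes <- vapply(lists, function(l) length(l$ids), integer(1))
  p <- max(sizes)
  nm <- names(lists)
  if (is.null(nm)) nm <- paste0("group", seq_along(lists))
  pairs <- utils::combn(seq_along(lists), 2)
  pr <- data.frame(a = nm[pairs[1, ]], b = nm[pairs[2, ]],
                   count = apply(pairs, 2, function(ij)
                     length(intersect(lists[[ij[1]]]$ids,
                                      lists[[ij[2]]]$ids))))
  pr$proportion <- pr$count / p
  allway <- length(Reduce(intersect, lapply(lists, `[[`, "ids")))
  structure(list(mode = mode, p = p, sizes = setNames(sizes, nm),
                 pairwise = pr, allway_count = allway,
                 allway_proportion = allway / p,
                 null_expected_pairwise = p^2 / length(panel),
                 n_panel = length(panel)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap report (%s), p = %d, panel = %d variants\n",
              x$mode, x$p, x$n_panel))
  print(x$pairwise, row.names = FALSE)
  cat(sprintf("  all-way: %d (%.3f); hypergeometric null pairwise: %.2f\n",
              x$allway_count, x$allway_proportion,
              x$null_expected_pairwise))
  invisible(x)
}

## Screening stack for one cohort: GRM -> REML -> BLUP (or single-SNP
## p-values). Falls back to the p-value criterion when sigma_g2 hits the
## zero boundary under abs_blup.
screen_scores <- function(g, phen, kind = c("abs_blup", "pvalue"),
                          covariates = c("age", "sex", "height",
                                         "pack_years")) {
  kind <- match.arg(kind)
  covariates <- intersect(covariates, names(phen))
  Z <- as.matrix(phen[, covariates, drop = FALSE])
  y <- phen$trait
  if (kind == "pvalue") return(per_snp_regression(g, y, Z))
  K <- compute_grm(g)
  fit <- reml_fit(y, Z, K)
  if (fit$sigma_g2 <= 1e-10 * var(y)) {
    message("sigma_g2 at the zero boundary; falling back to p-value ranking")
    return(per_snp_regression(g, y, Z))
  }
  blup_snp_effects(g, K, y, Z, fit)
}

#' Within-group overlap of top-SNP lists from disjoint splits
#'
#' Partitions one cohort into `n_splits` disjoint equal-size subgroups at
#' random and runs the full screening stack (GRM, REML, BLUP or single-SNP
#' p-values, top-p selection) independently within each subgroup, so no
#' sample is shared between the compared lists. The resulting overlap is
#' the within-group analogue of the between-ethnicity comparison.
#'
#' @param g A [genotype_matrix()].
#' @param phen Phenotype table aligned with `g`.
#' @param criterion A [screen_criterion()].
#' @param n_splits Number of disjoint subgroups.
#' @param seed Integer seed for the random partition.
#' @param covariates Covariate columns used in the screening model.
#' @return An `overlap_report` (mode `"within_group_splits"`) with the
#'   per-split lists attached as attribute `"lists"`.
#' @export
within_group_overlap <- function(g, phen, criterion, n_splits = 3L,
                                 seed = 1L,
                                 covariates = c("age", "sex", "height",
                                                "pack_years")) {
  stopifnot(inherits(criterion, "screen_criterion"))
  n <- nrow(g$values)
  size <- n %/% n_splits
  if (size < 30) stopf("subgroups of %d samples are too small to screen", size)
  idx <- with_seed(derive_seed(seed, 11L), sample.int(n))
  lists <- vector("list", n_splits)
  names(lists) <- paste0("split", seq_len(n_splits))
  for (s in seq_len(n_splits)) {
    take <- idx[((s - 1) * size + 1):(s * size)]
    gs <- subset_genotypes(g, samples = take)
    ps <- phen[take, , drop = FALSE]
    sc <- tryCatch(screen_scores(gs, ps, criterion$kind, covariates),
                   error = function(e)
                     stopf("screening failed in %s: %s", names(lists)[s],
                           conditionMessage(e)))
    ## screen_scores may have fallen back to the p-value ranking on a
    ## REML zero boundary; rank by whichever statistic it returned
    crit_eff <- screen_criterion(
      if ("score" %in% names(sc)) "abs_blup" else "pvalue", criterion$p)
    lists[[s]] <- select_top_snps(sc, crit_eff, variants = gs$variants,
                                  source = names(lists)[s])
  }
  rep <- overlap_between_groups(lists, mode = "within_group_splits")
  attr(rep, "lists") <- lists
  rep
}
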