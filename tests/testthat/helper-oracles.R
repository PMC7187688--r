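## Independent oracles used across the suite. These deliberately take a
## different computational route from the package internals.

## HWE exact test by direct closed-form enumeration of the Levene-Haldane
## distribution via log-factorials (the package uses a term recurrence).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n1 <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n1 == 0) return(1)
  hs <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  logp <- vapply(hs, function(h) {
    hr <- (n1 - h) / 2
    hc <- n - hr - h
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(n1) + lfactorial(2 * n - n1) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(n_Aa, hs)] * (1 + 1e-12)])
}

## AUC by explicit case-control pair counting (ties credited 0.5).
auc_oracle <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Hudson-type Fst ratio-of-averages estimator from two population
## frequency vectors.
fst_hudson <- function(p1, p2) {
  sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))
}

## Small deterministic genotype fixture with hand-controllable columns.
make_geno <- function(values, chrom = NULL, pos = NULL,
                      a1 = NULL, a2 = NULL, ids = NULL) {
  values <- as.matrix(values)
  m <- ncol(values)
  genotype_matrix(
    values,
    variants = data.frame(
      id = if (is.null(ids)) sprintf("v%03d", seq_len(m)) else ids,
      chrom = if (is.null(chrom)) rep(1L, m) else chrom,
      pos = if (is.null(pos)) seq_len(m) * 10L else pos,
      allele_effect = if (is.null(a1)) rep("A", m) else a1,
      allele_other = if (is.null(a2)) rep("G", m) else a2),
    samples = data.frame(id = sprintf("s%03d", seq_len(nrow(values)))))
}

## One-population simulated cohort used by many tests.
sim_one_pop <- function(n = 300, m = 400, h2 = 0.4, n_causal = 10,
                        case_fraction = 0.3, seed = 1, fst = 0.05,
                        covariate_effects = NULL) {
  args <- list(n_variants = m, fst = fst, target_h2 = h2, seed = seed)
  if (!is.null(covariate_effects)) args$covariate_effects <- covariate_effects
  cfg <- do.call(simulation_config, args)
  causal <- if (n_causal > 0) round(seq(1, m, length.out = n_causal)) else
    integer(0)
  pop <- population_spec("POP", n, case_fraction, causal)
  simulate_cohort(cfg, list(pop))
}
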