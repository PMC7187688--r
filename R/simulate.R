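#' Population specification for the cohort simulator
#'
#' Describes one simulated population: its size, the target case fraction
#' of the dichotomous outcome, and which panel variants are causal for the
#' continuous trait (with their relative effect sizes).
#'
#' @param label Population identifier (used as the `ethnicity` label).
#' @param n_samples Number of individuals (>= 2).
#' @param case_fraction Target proportion of cases, in (0, 1).
#' @param causal_indices Integer indices into the shared variant panel.
#' @param causal_effects Per-causal-variant effect sizes on the continuous
#'   trait (relative scale; rescaled internally to meet the target
#'   heritability). Defaults to equal effects.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(label, n_samples, case_fraction,
                            causal_indices = integer(0),
                            causal_effects = NULL) {
  if (!is_count(n_samples) || n_samples < 2)
    stopf("`n_samples` must be an integer >= 2")
  check_prob(case_fraction, "case_fraction", open_left = TRUE,
             open_right = TRUE)
  causal_indices <- as.integer(causal_indices)
  if (is.null(causal_effects)) causal_effects <- rep(1, length(causal_indices))
  if (length(causal_effects) != length(causal_indices))
    stopf("`causal_effects` must match `causal_indices` in length")
  structure(list(label = as.character(label), n_samples = as.integer(n_samples),
                 case_fraction = case_fraction,
                 causal_indices = causal_indices,
                 causal_effects = as.numeric(causal_effects)),
            class = "population_spec")
}

#' Simulation configuration
#'
#' Global parameters of the multi-ethnic cohort simulator. Population
#' divergence follows the Balding-Nichols model with a single Fst knob;
#' the continuous trait (an FEV1 analogue) gets `target_h2` of its
#' covariate-adjusted variance from the causal variants.
#'
#' @param n_variants Size of the shared variant panel.
#' @param fst Balding-Nichols divergence parameter, in `[0, 1)`.
#' @param ancestral_maf_range Interval within (0, 0.5] from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param target_h2 SNP heritability of the continuous trait, in `[0, 1)`,
#'   defined conditionally on covariates: `var(g) / (var(g) + var(e))`.
#' @param covariate_effects Named coefficients of `age`, `sex`, `height`,
#'   `pack_years` on the trait (trait units per covariate unit; the trait's
#'   genetic-plus-noise part has unit variance).
#' @param n_chromosomes Number of chromosome labels spread over the panel
#'   (contiguous blocks), for partitioned-heritability analyses.
#' @param seed Integer seed; the entire cohort is a deterministic function
#'   of (config, populations, seed).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_variants, fst = 0.1,
                              ancestral_maf_range = c(0.05, 0.5),
                              target_h2 = 0.4,
                              covariate_effects = c(age = -0.03, sex = 0.3,
                                                    height = 0.02,
                                                    pack_years = -0.015),
                              n_chromosomes = 5L, seed = 1L) {
  if (!is_count(n_variants) || n_variants < 1)
    stopf("`n_variants` must be a positive integer")
  if (!is.numeric(fst) || length(fst) != 1 || fst < 0 || fst >= 1)
    stopf("`fst` must lie in [0, 1)")
  if (length(ancestral_maf_range) != 2 ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      diff(ancestral_maf_range) < 0)
    stopf("`ancestral_maf_range` must be an interval within (0, 0.5]")
  if (!is.numeric(target_h2) || length(target_h2) != 1 ||
      target_h2 < 0 || target_h2 >= 1)
    stopf("`target_h2` must lie in [0, 1)")
  structure(list(n_variants = as.integer(n_variants), fst = fst,
                 ancestral_maf_range = as.numeric(ancestral_maf_range),
                 target_h2 = target_h2,
                 covariate_effects = covariate_effects,
                 n_chromosomes = as.integer(n_chromosomes),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw per-population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on the configured MAF range; each
#' population's frequency at ancestral frequency `p` is a Beta draw with
#' mean `p` and variance `fst * p * (1 - p)`. With `fst = 0` the
#' populations share the ancestral frequencies exactly.
#'
#' @param config A [simulation_config()].
#' @param populations List of [population_spec()].
#' @return List with `ancestral` (length `n_variants`) and `by_population`
#'   (matrix, one row per population, rownames = labels).
#' @export
draw_allele_frequencies <- function(config, populations) {
  stopifnot(inherits(config, "simulation_config"))
  for (p in populations) stopifnot(inherits(p, "population_spec"))
  m <- config$n_variants
  with_seed(derive_seed(config$seed, 1L), {
    anc <- runif(m, config$ancestral_maf_range[1],
                 config$ancestral_maf_range[2])
    fr <- matrix(NA_real_, length(populations), m,
                 dimnames = list(vapply(populations, `[[`, "", "label"), NULL))
    if (config$fst == 0) {
      fr[] <- rep(anc, each = length(populations))
    } else {
      scale <- (1 - config$fst) / config$fst
      for (k in seq_along(populations))
        fr[k, ] <- rbeta(m, anc * scale, (1 - anc) * scale)
      ## keep frequencies strictly inside (0, 1)
      fr <- pmin(pmax(fr, 1e-6), 1 - 1e-6)
    }
    list(ancestral = anc, by_population = fr)
  })
}

.chrom_blocks <- function(n_variants, n_chrom) {
  sizes <- diff(round(seq(0, n_variants, length.out = n_chrom + 1)))
  rep(seq_len(n_chrom), times = sizes)
}

#' Generate genotypes for all populations
#'
#' Genotypes are binomial(2, freq) per individual and variant, i.e. in
#' Hardy-Weinberg proportions within each population, coded as counts of
#' the effect allele (the ancestral minor allele by construction).
#'
#' @param freqs Output of [draw_allele_frequencies()].
#' @param populations List of [population_spec()].
#' @param config A [simulation_config()] (supplies panel layout and seed).
#' @return A [genotype_matrix()] stacking all populations; the originating
#'   population of each sample is recoverable from its id prefix.
#' @export
generate_genotypes <- function(freqs, populations, config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$n_variants
  fr <- freqs$by_population
  if (any(fr <= 0 | fr >= 1)) stopf("allele frequencies must lie in (0, 1)")
  with_seed(derive_seed(config$seed, 2L), {
    blocks <- lapply(seq_along(populations), function(k) {
      n <- populations[[k]]$n_samples
      matrix(rbinom(n * m, 2L, rep(fr[k, ], each = n)), nrow = n)
    })
    vals <- do.call(rbind, blocks)
    chrom <- .chrom_blocks(m, config$n_chromosomes)
    pos <- as.integer(stats::ave(seq_len(m), chrom, FUN = seq_along)) * 1000L
    variants <- data.frame(id = sprintf("snp%06d", seq_len(m)),
                           chrom = chrom, pos = pos,
                           allele_effect = "A", allele_other = "G")
    ids <- unlist(lapply(populations, function(p)
      sprintf("%s_%05d", p$label, seq_len(p$n_samples))), use.names = FALSE)
    genotype_matrix(vals, variants, data.frame(id = ids))
  })
}

## Column standardization by within-population sample mean/sd.
.standardize_cols <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- Inf   # monomorphic column contributes nothing
  sweep(sweep(x, 2, mu), 2, s, "/")
}

#' Generate phenotypes and covariates
#'
#' Per population: covariates are drawn (age normal, sex Bernoulli(0.5),
#' height normal by sex, pack-years zero-inflated gamma, current smoking and
#' family history Bernoulli), the continuous trait is
#' `standardized causal genotypes %*% effects + covariate term + noise`
#' with the genetic part rescaled so its in-sample variance equals
#' `target_h2` (noise variance `1 - target_h2`), and case status is 1 when
#' the trait falls below the population's `case_fraction` quantile (low
#' lung function defines disease).
#'
#' @param genotypes Output of [generate_genotypes()].
#' @param populations List of [population_spec()].
#' @param config A [simulation_config()].
#' @return List of class `simulated_phenotypes`: `phenotypes` (data.frame)
#'   and `truth` (per-population causal sets, scaled effects, realized
#'   heritability).
#' @export
generate_phenotypes <- function(genotypes, populations, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "simulation_config"))
  h2 <- config$target_h2
  ce <- config$covariate_effects
  with_seed(derive_seed(config$seed, 3L), {
    rows <- list(); truth <- list()
    offset <- 0L
    for (p in populations) {
      n <- p$n_samples
      idx <- offset + seq_len(n)
      offset <- offset + n
      age <- rnorm(n, 55, 8)
      sex <- rbinom(n, 1, 0.5)                       # 1 = male
      height <- ifelse(sex == 1, rnorm(n, 175, 7), rnorm(n, 162, 6))
      never <- rbinom(n, 1, 0.35)
      pack_years <- ifelse(never == 1, 0, rgamma(n, shape = 2, scale = 12))
      smoking_current <- ifelse(never == 1, 0L, rbinom(n, 1, 0.4))
      family_history <- rbinom(n, 1, 0.15)

      gval <- rep(0, n)
      beta <- numeric(0)
      if (h2 > 0 && length(p$causal_indices)) {
        gs <- .standardize_cols(
          genotypes$values[idx, p$causal_indices, drop = FALSE] * 1.0)
        raw <- drop(gs %*% p$causal_effects)
        s <- sd(raw)
        if (s > 0) {
          gval <- raw * sqrt(h2) / s
          beta <- p$causal_effects * sqrt(h2) / s
        }
      }
      noise <- rnorm(n, 0, sqrt(1 - h2))
      cov_term <- ce[["age"]] * age + ce[["sex"]] * sex +
        ce[["height"]] * height + ce[["pack_years"]] * pack_years
      trait <- gval + noise + cov_term
      cut <- quantile(trait, p$case_fraction, type = 1)
      status <- as.integer(trait <= cut)
      rows[[p$label]] <- data.frame(
        sample_id = genotypes$samples$id[idx], status = status, trait = trait,
        age = age, sex = sex, height = height, pack_years = pack_years,
        smoking_current = smoking_current, family_history = family_history,
        ethnicity = p$label)
      truth[[p$label]] <- list(
        causal_indices = p$causal_indices,
        causal_ids = genotypes$variants$id[p$causal_indices],
        scaled_effects = beta,
        realized_h2 = if (h2 > 0 && sd(gval) > 0)
          var(gval) / (var(gval) + var(noise)) else 0,
        case_fraction_target = p$case_fraction,
        case_fraction_realized = mean(status))
    }
    phen <- do.call(rbind, rows)
    rownames(phen) <- NULL
    structure(list(phenotypes = phen, truth = truth),
              class = "simulated_phenotypes")
  })
}

#' Simulate a complete multi-ethnic cohort
#'
#' Runs [draw_allele_frequencies()], [generate_genotypes()] and
#' [generate_phenotypes()] under seeds derived from the config seed.
#' Identical (config, populations) give byte-identical cohorts.
#'
#' @inheritParams draw_allele_frequencies
#' @return List of class `simulated_cohort`: `genotypes`, `phenotypes`,
#'   `truth` (including per-population allele frequencies).
#' @export
simulate_cohort <- function(config, populations) {
  for (p in populations)
    if (length(p$causal_indices) &&
        max(p$causal_indices) > config$n_variants)
      stopf("causal indices of population '%s' exceed the variant panel",
            p$label)
  freqs <- draw_allele_frequencies(config, populations)
  g <- generate_genotypes(freqs, populations, config)
  ph <- generate_phenotypes(g, populations, config)
  truth <- ph$truth
  for (k in seq_along(populations))
    truth[[populations[[k]]$label]]$allele_freq <- freqs$by_population[k, ]
  structure(list(genotypes = g, phenotypes = ph$phenotypes, truth = truth,
                 config = config, populations = populations),
            class = "simulated_cohort")
}

#' Convenience builder: two populations with controlled causal overlap
#'
#' Builds two [population_spec()]s over a shared panel whose causal sets
#' overlap in a configurable proportion, the simulator-level analogue of
#' shared versus ethnicity-specific genetic architecture.
#'
#' @param n1,n2 Sample sizes.
#' @param case_fraction1,case_fraction2 Case fractions.
#' @param n_causal Causal variants per population.
#' @param overlap Proportion of causal variants shared between the two
#'   populations, in `[0, 1]`.
#' @param n_variants Panel size.
#' @param labels Population labels.
#' @return List of two `population_spec`s.
#' @export
two_population_specs <- function(n1, n2, case_fraction1 = 0.3,
                                 case_fraction2 = 0.3, n_causal = 20,
                                 overlap = 0, n_variants,
                                 labels = c("POP1", "POP2")) {
  check_prob(overlap, "overlap")
  n_shared <- round(overlap * n_causal)
  n_specific <- n_causal - n_shared
  need <- n_shared + 2 * n_specific
  if (n_variants < need)
    stopf("panel too small: need %d variants for the causal layout", need)
  ## deterministic layout: spread causal variants over the panel
  all_idx <- round(seq(1, n_variants, length.out = need))
  shared <- all_idx[seq_len(n_shared)]
  sp1 <- all_idx[n_shared + seq_len(n_specific)]
  sp2 <- all_idx[n_shared + n_specific + seq_len(n_specific)]
  list(population_spec(labels[1], n1, case_fraction1, sort(c(shared, sp1))),
       population_spec(labels[2], n2, case_fraction2, sort(c(shared, sp2))))
}
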