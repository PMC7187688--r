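test_that("HWE exact p-values match the enumeration oracle", {
  cases <- list(c(25, 50, 25), c(0, 100, 0), c(100, 0, 0), c(3, 5, 2),
                c(0, 1, 0), c(10, 0, 10), c(40, 20, 40), c(1, 2, 1))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12,
                 info = paste(cs, collapse = ","))
  ## extreme heterozygote excess fails the conventional 1e-5 floor
  expect_lt(hwe_exact_test(0, 100, 0), 1e-5)
  expect_identical(hwe_exact_test(100, 0, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("HWE exact test agrees with the oracle over an exhaustive small sweep", {
  for (n in c(5L, 12L, 25L)) {
    for (a in 0:n) for (b in 0:(n - a)) {
      cc <- n - a - b
      expect_equal(hwe_exact_test(a, b, cc), hwe_oracle(a, b, cc),
                   tolerance = 1e-12,
                   info = sprintf("(%d,%d,%d)", a, b, cc))
    }
  }
})

test_that("variant QC removes exactly the planted failures and balances", {
  ## 10 samples x 5 variants: one MAF failure, one missingness failure,
  ## one HWE failure, two clean survivors
  ok1 <- c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 1L)  # MAF 0.45
  ok2 <- c(2L, 1L, 0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L)
  low_maf <- c(rep(0L, 9), 1L)                        # MAF 0.05 -> boundary
  low_maf_fail <- c(rep(0L, 10))                      # monomorphic
  miss_fail <- c(NA, NA, 0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L)  # 20% missing
  hwe_fail <- rep(1L, 10)   # all het: p = 0.0069, the n=10 extreme
  ## at n = 10 the exact test cannot reach very small p, so the fixture
  ## raises the HWE floor to a level its planted failure can cross
  thr <- qc_thresholds(min_hwe_p = 0.01)
  g <- make_geno(cbind(ok1, low_maf_fail, miss_fail, hwe_fail, ok2))
  res <- snp_qc_filter(g, thr)
  expect_setequal(res$genotypes$variants$id, c("v001", "v005"))
  expect_equal(res$report$n_removed[["missingness"]], 1)
  expect_equal(res$report$n_removed[["maf"]], 1)
  expect_equal(res$report$n_removed[["hwe"]], 1)
  expect_equal(res$report$n_in - sum(res$report$n_removed), res$report$n_out)

  ## boundary semantics: MAF exactly at the floor survives
  g2 <- make_geno(cbind(ok1, low_maf))
  res2 <- snp_qc_filter(g2, qc_thresholds())
  expect_true("v002" %in% res2$genotypes$variants$id)
  ## strictly below is removed and attributed to MAF
  g3 <- make_geno(cbind(ok1, c(rep(0L, 10))))
  res3 <- snp_qc_filter(g3, qc_thresholds())
  expect_equal(res3$report$removed$maf, "v002")
})

test_that("variant QC is idempotent and its report balances under fuzzing", {
  set.seed(77)
  for (rep in 1:5) {
    vals <- matrix(sample(c(0:2, NA), 40 * 30, replace = TRUE,
                          prob = c(0.45, 0.3, 0.2, 0.05)), 40, 30)
    g <- make_geno(vals)
    r1 <- snp_qc_filter(g)
    expect_equal(r1$report$n_in - sum(r1$report$n_removed), r1$report$n_out)
    r2 <- snp_qc_filter(r1$genotypes)
    expect_equal(sum(r2$report$n_removed), 0)
    expect_identical(r2$genotypes$values, r1$genotypes$values)
  }
})

test_that("sample QC removes high-missingness and covariate-incomplete samples", {
  set.seed(8)
  vals <- matrix(sample(0:2, 10 * 50, replace = TRUE), 10, 50)
  vals[1, 1:4] <- NA            # 8% missing -> removed
  vals[2, 1] <- NA              # 2% missing -> retained
  g <- make_geno(vals)
  phen <- data.frame(sample_id = g$samples$id, status = rep(0:1, 5),
                     trait = rnorm(10), age = 50, sex = 1, height = 170,
                     pack_years = 10, smoking_current = 0,
                     family_history = 0, ethnicity = "X")
  phen$pack_years[3] <- NA      # covariate incomplete -> removed
  res <- suppressMessages(sample_qc_filter(g, phen, qc_thresholds()))
  expect_setequal(res$report$removed$missingness, "s001")
  expect_setequal(res$report$removed$covariates, "s003")
  expect_equal(res$report$n_out, 8)
  expect_true("s002" %in% res$phenotypes$sample_id)
  expect_error(sample_qc_filter(g, phen[-1, ], qc_thresholds()), "ids")
})

test_that("variant intersection harmonizes swapped alleles and drops ambiguous pairs", {
  v1 <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L, 0L, 0L, 1L), 3)
  g1 <- make_geno(v1, a1 = c("A", "C", "A"), a2 = c("G", "T", "T"),
                  ids = c("r1", "r2", "r3"))
  ## cohort 2: r2 has swapped alleles; r3 is A/T (ambiguous) everywhere
  v2 <- matrix(c(1L, 1L, 0L, 0L, 1L, 2L, 2L, 1L, 1L), 3)
  g2 <- make_geno(v2, a1 = c("A", "T", "A"), a2 = c("G", "C", "T"),
                  ids = c("r1", "r2", "r3"))
  res <- intersect_variants(list(g1, g2))
  expect_setequal(res$cohorts[[1]]$variants$id, c("r1", "r2"))
  expect_equal(res$log$reason[res$log$id == "r3"], "strand_ambiguous")
  ## flipped dosages: cohort-2 r2 column is 2 - original
  expect_equal(unname(res$cohorts[[2]]$values[, "r2"]), 2 - c(0L, 1L, 2L))
  ## after harmonization both cohorts declare the same alleles
  expect_equal(res$cohorts[[2]]$variants$allele_effect,
               res$cohorts[[1]]$variants$allele_effect)

  ## identical cohorts intersect to the full non-ambiguous panel
  res2 <- intersect_variants(list(g1, g1))
  expect_setequal(res2$cohorts[[1]]$variants$id, c("r1", "r2"))
  expect_identical(res2$cohorts[[1]]$values, res2$cohorts[[2]]$values)

  ## zero shared variants is an explicit error
  g3 <- make_geno(matrix(0:2, 3, 1), ids = "zzz")
  expect_error(intersect_variants(list(g1, g3)), "shared")
})
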