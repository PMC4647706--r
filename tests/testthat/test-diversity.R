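# Per-locus diversity statistics and association tests.

gm_from_dosage <- function(d) {
  d <- as.matrix(d)
  genotype_matrix(d, rep("A", ncol(d)), rep("G", ncol(d)))
}

test_that("allele frequencies exclude missing calls and count copies", {
  # calls {AA, AG, GG} -> p = 0.5; {AA, AA} -> 1; {AG, NN} -> 0.5, n = 1
  gm <- gm_from_dosage(cbind(c(2L, 1L, 0L), c(2L, 2L, NA), c(1L, NA, NA)))
  fr <- locus_frequencies(gm)
  expect_equal(fr$p_ref, c(0.5, 1, 0.5))
  expect_equal(fr$n_called, c(3L, 2L, 1L))
  expect_equal(fr$maf, c(0.5, 0, 0.5))
})

test_that("PIC = 1 - sum(p^2)", {
  expect_equal(pic(c(0.5, 0.5)), 0.5)
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.7, 0.3)), 0.42)
  expect_error(pic(c(0.7, 0.7)), "sum to 1")
})

test_that("observed and expected heterozygosity at one locus", {
  gm <- gm_from_dosage(cbind(c(1L, 1L), c(2L, 0L), c(2L, 2L)))
  expect_equal(heterozygosities(gm, 1), c(h_obs = 1, h_exp = 0.5))
  expect_equal(heterozygosities(gm, 2), c(h_obs = 0, h_exp = 0.5))
  expect_equal(heterozygosities(gm, 3), c(h_obs = 0, h_exp = 0))
  # unbiased switch: 2n/(2n-1) with n = 2
  expect_equal(heterozygosities(gm, 1, unbiased = TRUE)[["h_exp"]], 0.5 * 4 / 3)
  gm_na <- gm_from_dosage(cbind(c(NA_integer_, NA_integer_)))
  expect_error(heterozygosities(gm_na, 1), "no called genotype")
})

test_that("F_S spans HWE, heterozygote excess and fixation", {
  expect_equal(fixation_fs(0.5, 0.5), 0)
  expect_equal(fixation_fs(0.5, 1.0), -1)
  expect_equal(fixation_fs(0.5, 0), 1)
  expect_true(is.na(fixation_fs(0, 0)))
})

test_that("F_ST matches hand-computed two-deme cases", {
  # fixed alternate alleles, equal sizes: H_S = 0, H_T = 0.5, F_ST = 1
  gm <- gm_from_dosage(cbind(c(2L, 2L, 0L, 0L)))
  part <- c(1, 1, 2, 2)
  fst <- fixation_fst(gm, part)
  expect_equal(fst$h_s, 0)
  expect_equal(fst$h_t, 0.5)
  expect_equal(fst$f_st, 1)

  # identical frequencies: F_ST = 0
  gm2 <- gm_from_dosage(cbind(c(2L, 0L, 2L, 0L)))
  expect_equal(fixation_fst(gm2, part)$f_st, 0)

  # p = 0.6 vs 0.4, equal sizes: H_S = 0.48, H_T = 0.5, F_ST = 0.04
  # subpop 1: dosages {2,2,1,1,0} -> p = 0.6; subpop 2 mirrored
  gm3 <- gm_from_dosage(cbind(c(2L, 2L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 2L)))
  part3 <- rep(1:2, each = 5)
  fst3 <- fixation_fst(gm3, part3)
  expect_equal(fst3$h_s, 0.48)
  expect_equal(fst3$h_t, 0.5)
  expect_equal(fst3$f_st, 0.04)
})

test_that("H_S <= H_T for any partition, so F_ST >= 0 as implemented", {
  for (seed in 1:10) {
    gm <- random_genotypes(24, 40, miss = 0.1, seed = seed)
    part <- sample(rep(1:2, length.out = 24))
    fst <- fixation_fst(gm, part)
    ok <- !is.na(fst$f_st)
    expect_true(all(fst$h_s[ok] <= fst$h_t[ok] + 1e-12))
    expect_true(all(fst$f_st[ok] >= -1e-12))
  }
})

test_that("per-locus table ties PIC to H_exp for biallelic loci", {
  gm <- random_genotypes(30, 50, miss = 0.05, seed = 3)
  ld <- locus_diversity(gm)
  expect_equal(ld$pic, ld$h_exp)
  expect_true(all(ld$pic <= 0.5 + 1e-12))
  expect_true(all(ld$maf >= 0 & ld$maf <= 0.5))
})

test_that("median per-locus F_ST recovers generative differentiation in the
           many-deme regime", {
  # With K demes the pooled-H_T estimator carries a (1 - 1/K) factor and the
  # per-locus ratio is right-skewed; at K = 8 with large within-deme samples
  # the median sits within +-0.015 of F for F <= 0.1.
  for (F in c(0.03, 0.08)) {
    meds <- vapply(1:3, function(seed) {
      sc <- collection_scenario(n_samples = 240, n_loci = 250, K = 8,
                                fst = F, admixed_fraction = 0,
                                missing_rate = 0)
      sim <- simulate_collection(sc, seed = 1000 + seed)
      fst <- fixation_fst(sim$genotypes, sim$partition)
      median(fst$f_st, na.rm = TRUE)
    }, 0)
    expect_true(all(abs(meds - F) <= 0.015),
                info = sprintf("F = %.2f, medians = %s", F,
                               paste(round(meds, 4), collapse = ", ")))
  }
})

test_that("a Hardy-Weinberg subpopulation has median F_S near zero", {
  # the plug-in H_exp carries a -1/(2n) bias, so the HWE check uses the
  # unbiased 2n/(2n-1) estimator the package provides for exactly this
  meds <- vapply(1:20, function(seed) {
    sc <- collection_scenario(n_samples = 60, n_loci = 300, K = 2,
                              fst = 0.05, admixed_fraction = 0,
                              missing_rate = 0)
    sim <- simulate_collection(sc, seed = 500 + seed)
    sub <- sim$genotypes[sim$partition == 1, ]
    ld <- locus_diversity(sub, unbiased = TRUE)
    median(ld$f_s, na.rm = TRUE)
  }, 0)
  expect_true(all(abs(meds) < 0.05))
})

test_that("planted heterozygote excess drives median F_S negative", {
  # genotypes with P(het) = 0.7 at p = 0.5 (HWE would give 0.5)
  set.seed(42)
  n <- 40; L <- 100
  d <- matrix(sample(c(0L, 1L, 2L), n * L, replace = TRUE,
                     prob = c(0.15, 0.7, 0.15)), n, L)
  gm <- gm_from_dosage(d)
  ld <- locus_diversity(gm)
  expect_lt(median(ld$f_s, na.rm = TRUE), 0)
  sr <- suppressWarnings(wilcox.test(ld$f_s, mu = 0))
  expect_lt(sr$p.value, 0.01)
})

test_that("two-subpopulation summary reports medians and the three tests", {
  sim <- simulate_collection(collection_scenario(n_samples = 50, n_loci = 150,
                                                 K = 2, fst = 0.1,
                                                 admixed_fraction = 0,
                                                 missing_rate = 0.02),
                             seed = 77)
  s <- summarize_partition(sim$genotypes, sim$partition)
  expect_identical(nrow(s$per_subpop), 2L)
  expect_true(all(s$per_subpop$f_s_p_value >= 0 & s$per_subpop$f_s_p_value <= 1))
  expect_true(s$f_st_median >= 0)
  expect_lt(s$f_st_test$p_value, 0.001)  # F_ST > 0 under real differentiation
  expect_true(is.numeric(s$h_exp_test$p_value))
})

test_that("degenerate signed-rank input is flagged with p = 1", {
  # identical H_obs and H_exp at every locus -> F_S identically 0
  gm <- gm_from_dosage(matrix(rep(c(1L, 1L, 0L, 2L), 10), 4, 10))
  ld <- locus_diversity(gm)
  expect_true(all(ld$f_s == 0, na.rm = TRUE))
  sr <- germdiv:::.signed_rank(ld$f_s)
  expect_true(sr$degenerate)
  expect_equal(sr$p_value, 1)
})

test_that("Fisher exact test matches enumeration on reference tables", {
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$p_value, 2 / 252)
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1)))$p_value, 1)
  # embryony-style table: validated against the enumeration oracle and
  # stats::fisher.test, the two independent routes
  tab <- rbind(c(13, 5), c(40, 11))
  p <- fisher_exact_2x2(tab)$p_value
  expect_equal(p, oracle_fisher_p(tab))
  expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  # zero margin convention
  z <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4)))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
})

test_that("Fisher exact test agrees with stats::fisher.test on random tables", {
  set.seed(8)
  for (rep in 1:50) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("chi-square homogeneity handles proportions and paired vectors", {
  r0 <- chi_square_homogeneity(c(50, 50), expected_props = c(0.5, 0.5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r1 <- chi_square_homogeneity(c(30, 70), expected_props = c(0.5, 0.5))
  expect_equal(r1$statistic, 16)
  expect_identical(r1$df, 1L)
  expect_equal(r1$p_value,
               chisq.test(c(30, 70), p = c(0.5, 0.5))$p.value)

  r2 <- chi_square_homogeneity(c(10, 20, 30), observed2 = c(12, 18, 33))
  expect_equal(r2$statistic,
               unname(suppressWarnings(
                 chisq.test(rbind(c(10, 20, 30), c(12, 18, 33)))$statistic)))
  expect_identical(r2$df, 2L)

  expect_error(chi_square_homogeneity(c(30, 70), expected_props = c(.5, .5),
                                      df = 3), "does not match")
})
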