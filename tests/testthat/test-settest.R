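test_that("set statistic arithmetic and monotonicity", {
  expect_equal(set_statistic(c(0.1, 0.01)), 3.0, tolerance = 1e-12)
  expect_equal(set_statistic(rep(1, 7)), 0)
  p <- c(0.2, 0.05, 0.9)
  for (j in seq_along(p)) {
    p2 <- p
    p2[j] <- p[j] * 1.5
    expect_lt(set_statistic(pmin(p2, 1)), set_statistic(p))
  }
  expect_error(set_statistic(numeric(0)), "empty")
  expect_error(set_statistic(c(0.5, 0)), "0, 1")
  # the z^2 variant agrees with its definition
  expect_equal(set_statistic(c(0.05, 0.5), method = "sumz2"),
               qnorm(0.025)^2 + qnorm(0.25)^2, tolerance = 1e-12)
})

test_that("empirical p follows the (1+count)/(1+B) counting rule", {
  co <- small_cohort(n = 100, seed = 91)
  set_snps <- co$genotypes$snps$snp_id
  # plant an overwhelming signal so T_obs beats every permutation
  y <- as.numeric(scale(co$genotypes$dosages[, 1])) + rnorm(100, sd = 0.05)
  res <- self_contained_test(co$genotypes, y, set_snps, B = 99, seed = 5)
  expect_true(all(res$T_perm < res$T_obs))
  expect_equal(res$p_emp, 1 / 100)

  # null phenotype: p reproduces the exceedance count exactly
  y0 <- rnorm(100)
  res0 <- self_contained_test(co$genotypes, y0, set_snps, B = 199, seed = 6)
  expect_equal(res0$p_emp,
               (1 + sum(res0$T_perm >= res0$T_obs)) / 200)
  expect_gte(res0$p_emp, 1 / 200)
  expect_lte(res0$p_emp, 1)

  # determinism under the seed
  res0b <- self_contained_test(co$genotypes, y0, set_snps, B = 199, seed = 6)
  expect_identical(res0$T_perm, res0b$T_perm)
  expect_error(self_contained_test(co$genotypes, rep(1, 100), set_snps,
                                   B = 9, seed = 1), "constant phenotype")
})

test_that("observed statistic equals the per-SNP scan aggregation", {
  co <- small_cohort(n = 150, seed = 92, missing_rate = 0.01)
  y <- rnorm(150)
  set_snps <- co$genotypes$snps$snp_id
  res <- self_contained_test(co$genotypes, y, set_snps, B = 9, seed = 2)
  tab <- gwas(co$genotypes, y, snps = res$snp_ids)
  expect_equal(res$T_obs, set_statistic(tab$p), tolerance = 1e-10)
})

test_that("permutation test is calibrated under the null", {
  co <- small_cohort(n = 100, seed = 93)
  prep <- snpsetmeta:::prepare_set_matrix(co$genotypes,
                                          co$genotypes$snps$snp_id)
  set.seed(94)
  pvals <- vapply(1:400, function(i) {
    self_contained_test(prep, rnorm(100), B = 99, seed = 7000 + i)$p_emp
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  ci <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
  # p is discrete-uniform on the permutation grid under the null
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)
})

test_that("a strong planted signal pins p at the permutation floor", {
  co <- simulate_cohort(cohort_config("sig", 500, small_panel(), seed = 95))
  set_snps <- co$genotypes$snps$snp_id
  beta <- allocate_effects(set_snps, 5, seed = 96)
  floor_hit <- vapply(1:12, function(i) {
    y <- simulate_power_phenotypes(co, beta, 0.10, 1, seed = 960 + i)[, 1]
    res <- self_contained_test(co$genotypes, y, set_snps, B = 999,
                               seed = 97)
    res$p_emp == 1 / 1000
  }, logical(1))
  expect_gte(sum(floor_hit), 11)
})

test_that("Stouffer combination reproduces closed forms and symmetries", {
  # all p at 0.5 -> combined p 0.5 for any weights
  ms <- stouffer_meta(rep(0.5, 4), c(10, 400, 33, 7))
  expect_equal(ms$p_meta, 0.5, tolerance = 1e-12)
  # one cohort: p round-trips through the z transform
  expect_equal(stouffer_meta(0.2, 57)$p_meta, 0.2, tolerance = 1e-10)
  # invariant to cohort order
  p <- c(0.68, 0.76, 0.62, 0.18, 0.20)
  n <- c(505, 989, 350, 754, 805)
  expect_equal(stouffer_meta(p, n)$p_meta,
               stouffer_meta(rev(p), rev(n))$p_meta, tolerance = 1e-12)
  # hand-computed oracle
  expect_equal(stouffer_meta(c(0.1, 0.9), c(100, 100))$Z_meta,
               (10 * qnorm(0.9) + 10 * qnorm(0.1)) / sqrt(200),
               tolerance = 1e-12)
  # a permutation p of exactly 1 yields the continuous limit p_meta = 1
  expect_equal(stouffer_meta(c(1, 0.5), c(50, 50))$p_meta, 1)
  expect_error(stouffer_meta(c(0.5, 0), c(10, 10)), "0, 1")
})

test_that("empirical p is monotone non-increasing in the observed statistic", {
  co <- small_cohort(n = 80, seed = 98)
  res <- self_contained_test(co$genotypes, rnorm(80),
                             co$genotypes$snps$snp_id, B = 199, seed = 8)
  grid <- sort(c(res$T_obs, res$T_perm)) + 1e-9
  p_at <- vapply(grid, function(t0) (1 + sum(res$T_perm >= t0)) / 200,
                 numeric(1))
  expect_true(all(diff(p_at) <= 0))
})
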