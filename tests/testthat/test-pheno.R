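test_that("QC removes SNPs and individuals at the published thresholds", {
  # 100 individuals, 3 clean SNPs
  set.seed(31)
  d <- cbind(rbinom(100, 2, 0.3), rbinom(100, 2, 0.4), rbinom(100, 2, 0.25))
  # SNP 4: rare (MAF 0.005 = 1 alt allele in 200)
  rare <- c(1, rep(0, 99))
  # SNP 5: gross HWE violation (90 AA, 0 AB, 10 BB)
  hwe_bad <- c(rep(0, 90), rep(2, 10))
  d <- cbind(d, rare, hwe_bad)
  colnames(d) <- c("s1", "s2", "s3", "rare", "hwe_bad")
  # individual 1 misses 6 of 100 SNPs -> needs >= 100 SNPs; pad with clean ones
  pad <- replicate(95, rbinom(100, 2, 0.35))
  colnames(pad) <- paste0("p", 1:95)
  d <- cbind(d, pad)
  d[1, 6:11] <- NA  # call rate 94/100 < 0.95
  g <- genotype_matrix(d, snp_panel(colnames(d), "1", seq_len(ncol(d)) * 10,
                                    maf = 0.3))
  out <- qc_genotypes(g)
  expect_true("ind0001" %in% out$report$individuals_removed$individual_id)
  rem <- out$report$snps_removed
  expect_true("rare" %in% rem$snp_id[rem$reason == "maf"])
  expect_true("hwe_bad" %in% rem$snp_id[rem$reason == "hwe"])
  expect_false("s1" %in% rem$snp_id)
  # the HWE failure is confirmed by the independent enumeration oracle
  expect_lt(hwe_enum_oracle(90, 0, 10), 0.001)
})

test_that("exact HWE test agrees with the enumeration oracle", {
  cases <- list(c(90, 0, 10), c(25, 50, 25), c(5, 1, 5), c(0, 10, 0),
                c(57, 14, 50), c(300, 150, 50), c(1, 0, 0))
  for (cs in cases) {
    # the oracle's enumeration is unnormalised, so agreement is to ~1e-9
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_enum_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-9)
  }
  # equilibrium-looking counts are not rejected
  expect_gt(hwe_exact_test(49, 42, 9), 0.05)
})

test_that("QC is idempotent", {
  co <- small_cohort(n = 150, seed = 33, missing_rate = 0.02)
  once <- qc_genotypes(co$genotypes)
  twice <- qc_genotypes(once$genotypes)
  expect_identical(twice$genotypes$dosages, once$genotypes$dosages)
  expect_equal(nrow(twice$report$individuals_removed), 0L)
  expect_equal(nrow(twice$report$snps_removed), 0L)
})

test_that("structure axes are orthogonal and detect true structure only", {
  wide <- random_panel(200, seed = 40)
  co <- simulate_cohort(cohort_config("str", 1000, wide,
                                      structure_shift = 0.1, seed = 41))
  ax <- compute_structure_axes(co$genotypes, k = 4)
  nrm <- sweep(ax, 2L, sqrt(colSums(ax^2)), "/")
  off <- crossprod(nrm) - diag(4)
  expect_lt(max(abs(off)), 1e-6)
  expect_gt(abs(cor(ax[, 1], co$covariates$subpop)), 0.5)

  co0 <- simulate_cohort(cohort_config("nostr", 2000, wide,
                                       structure_shift = 0, seed = 42))
  ax0 <- compute_structure_axes(co0$genotypes, k = 4)
  expect_lt(max(abs(cor(ax0, co0$covariates$subpop))), 0.1)
  expect_error(compute_structure_axes(co0$genotypes, k = 2000), "smaller")
})

test_that("fluid factor recovers the latent ability and degrades gracefully", {
  co <- simulate_cohort(cohort_config("fa", 1000, small_panel(),
                                      loadings = rep(0.7, 4), seed = 51))
  battery <- co$battery[, -1]
  f <- derive_fluid_factor(battery)
  expect_gt(cor(f, co$latent_g), 0.85)

  # permuting individuals permutes scores identically
  perm <- sample(nrow(battery))
  expect_equal(derive_fluid_factor(battery[perm, ]), f[perm],
               tolerance = 1e-10, ignore_attr = TRUE)

  # one test column -> its z-scores
  one <- battery[, 1, drop = FALSE]
  expect_equal(derive_fluid_factor(one), as.numeric(scale(one[[1]])),
               tolerance = 1e-12, ignore_attr = TRUE)

  bad <- battery
  bad$test_1 <- 1
  expect_error(derive_fluid_factor(bad), "zero-variance")
})

test_that("residualisation matches the OLS oracle and is a projector", {
  y <- c(1, 2, 3, 4, 5, 6)
  x <- c(1, 1, 2, 2, 3, 3)
  pv <- residualise(y, data.frame(x = x))
  X <- cbind(1, x)
  r_hand <- y - X %*% solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(pv$values), as.numeric(scale(r_hand)),
               tolerance = 1e-10)
  expect_lt(abs(cor(pv$values, x)), 1e-10)
  expect_equal(mean(pv$values), 0, tolerance = 1e-8)
  expect_equal(sd(pv$values), 1, tolerance = 1e-8)

  # projector: residualising the residuals changes nothing
  pv2 <- residualise(pv$values, data.frame(x = x))
  expect_equal(unname(pv2$values), unname(pv$values), tolerance = 1e-10)

  # covariate orthogonal to y -> plain z-scores
  set.seed(6)
  y2 <- rnorm(50)
  z <- rnorm(50)
  z <- residualise(z, data.frame(y2 = y2))$values  # orthogonalised covariate
  pv3 <- residualise(y2, data.frame(z = unname(z)))
  expect_equal(unname(pv3$values), as.numeric(scale(y2)), tolerance = 1e-6)

  expect_error(residualise(x * 2 + 3, data.frame(x = x)), "zero residual")
  expect_error(residualise(y, data.frame(a = x, b = 2 * x)), "collinear.*b")
})

test_that("age-correction rescales to the IQ metric exactly", {
  set.seed(7)
  score <- rnorm(300)
  age <- runif(300, 10.5, 11.5)
  iq <- age11_iq(score, age)
  expect_equal(mean(iq), 100, tolerance = 1e-8)
  expect_equal(sd(iq), 15, tolerance = 1e-8)
  expect_lt(abs(cor(iq, age)), 1e-10)

  # constant age: pure rescaling of the score
  iq2 <- age11_iq(score, rep(11, 300))
  expect_equal(iq2, as.numeric(100 + 15 * scale(score)), tolerance = 1e-10)
  expect_error(age11_iq(3 * age + 1, age), "zero residual")
})

test_that("factor recovery improves with loading magnitude", {
  cors <- vapply(c(0.4, 0.6, 0.8), function(l) {
    co <- simulate_cohort(cohort_config("mono", 800, small_panel(),
                                        loadings = rep(l, 4), seed = 61))
    cor(derive_fluid_factor(co$battery[, -1]), co$latent_g)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})
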