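test_that("gene p-values match chi-square closed forms at the LD extremes", {
  # single SNP, z = 2: chi-square_1 tail at 4
  gs <- vegas_gene_p(2, n_sim = 1e5, seed = 11)
  truth <- pchisq(4, df = 1, lower.tail = FALSE)  # 0.0455
  expect_lt(abs(gs$p_gene - truth), 3 * sqrt(truth * (1 - truth) / 1e5) + 1e-4)

  # two perfectly correlated SNPs, z = (2, 2): tail of 2 * chi-square_1 at 8,
  # not the independent chi-square_2 tail
  ld1 <- matrix(1, 2, 2)
  gs2 <- vegas_gene_p(c(2, 2), ld1, n_sim = 1e5, seed = 12)
  expect_lt(abs(gs2$p_gene - truth), 3 * sqrt(truth * (1 - truth) / 1e5) + 1e-4)
  expect_gt(abs(gs2$p_gene - pchisq(8, df = 2, lower.tail = FALSE)), 0.01)

  # independent SNPs: chi-square_k tail
  z <- c(1.2, -0.5, 2.1, 0.3, -1.7)
  gs5 <- vegas_gene_p(z, diag(5), n_sim = 1e5, seed = 13)
  truth5 <- pchisq(sum(z^2), df = 5, lower.tail = FALSE)
  expect_lt(abs(gs5$p_gene - truth5),
            3 * sqrt(truth5 * (1 - truth5) / 1e5) + 1e-4)

  # null z: p near 1; determinism; input validation
  expect_gt(vegas_gene_p(rep(0, 3), n_sim = 1000, seed = 14)$p_gene, 0.99)
  expect_identical(vegas_gene_p(z, diag(5), n_sim = 1000, seed = 15)$p_gene,
                   vegas_gene_p(z, diag(5), n_sim = 1000, seed = 15)$p_gene)
  expect_error(vegas_gene_p(c(1, 2), diag(3)), "square")
  expect_error(vegas_gene_p(c(1, NA)), "finite")
})

test_that("gene tables cover the candidate roster and are simulation-stable", {
  fx <- make_annotation_fixture(n_background = 10, seed = 21,
                                imputed_scale = 0.05)
  co <- lapply(1:2, function(i) {
    simulate_cohort(cohort_config(paste0("c", i), 250, fx$imputed_panel,
                                  ld_rho = 0.2, seed = 210 + i))
  })
  studies <- lapply(co, function(x) gwas(x$genotypes, rnorm(250)))
  meta <- meta_inverse_variance(studies)
  map <- map_snps_to_genes(fx$imputed_panel, fx$annotation,
                           symmetric_flank = 50000)
  pooled <- snpsetmeta:::pool_genotypes(co)
  tab <- gene_table(meta, map, pooled, n_sim_start = 500, n_sim_max = 5000,
                    seed = 22)
  expect_true(all(fx$candidate_set %in% tab$gene))
  expect_true(all(tab$p_gene >= 1 / 5001 & tab$p_gene <= 1))

  # doubling the simulation count moves p by less than 2 MC standard errors
  g1 <- tab$gene[1]
  ids <- map$gene_to_snps[[g1]]
  z <- meta$z_meta[match(ids, meta$snp_id)]
  ld <- cor(snpsetmeta:::mean_impute(pooled$dosages[, ids, drop = FALSE]))
  pa <- vegas_gene_p(z, ld, n_sim = 4000, seed = 23)$p_gene
  pb <- vegas_gene_p(z, ld, n_sim = 8000, seed = 24)$p_gene
  se <- sqrt(pa * (1 - pa) / 4000) + sqrt(pb * (1 - pb) / 8000)
  expect_lt(abs(pa - pb), 2.5 * se + 1e-3)

  # under the null phenotype, gene p-values are roughly calibrated
  frac <- mean(tab$p_gene < 0.05)
  ci_hi <- qbinom(0.995, nrow(tab), 0.05) / nrow(tab)
  expect_lte(frac, ci_hi + 1e-9)
})

test_that("enrichment walk matches hand-computed and brute-force oracles", {
  # candidate genes occupy the top ranks -> maximal score 1
  gp <- data.frame(gene = paste0("g", 1:10),
                   p_gene = seq(0.01, 0.9, length.out = 10))
  top <- gsea_enrichment(gp, c("g1", "g2", "g3"), n_perm = 99, seed = 31)
  expect_equal(top$ES_obs, 1, tolerance = 1e-12)

  # worked 4-gene example with unit weights: running sum (0.5, 0, 0.5, 0)
  gp4 <- data.frame(gene = c("a", "b", "c", "d"),
                    p_gene = c(0.1, 0.2, 0.3, 0.4))
  es <- gsea_enrichment(gp4, c("a", "c"), n_perm = 9, seed = 32,
                        weight_scheme = "unit")
  expect_equal(es$ES_obs, 0.5, tolerance = 1e-12)

  # unit-weight ES equals the classic K-S walk on random short lists
  set.seed(33)
  for (i in 1:25) {
    N <- sample(5:20, 1)
    m <- sample(seq_len(N - 1), 1)
    gp_r <- data.frame(gene = sprintf("g%02d", 1:N),
                       p_gene = runif(N))
    cand <- sample(gp_r$gene, m)
    es_r <- gsea_enrichment(gp_r, cand, n_perm = 1, seed = i,
                            weight_scheme = "unit")
    ord <- order(gp_r$p_gene, gp_r$gene)
    expect_ks_extremum(es_r$ES_obs, ks_walk_oracle(gp_r$gene[ord] %in% cand))
  }
})

test_that("enrichment p is calibrated and invariant to non-candidate labels", {
  set.seed(34)
  gp <- data.frame(gene = sprintf("g%03d", 1:80), p_gene = runif(80))
  # null calibration: random candidate sets give uniform p_enrich
  pvals <- vapply(1:300, function(i) {
    cand <- sample(gp$gene, 10)
    gsea_enrichment(gp, cand, n_perm = 199, seed = 340 + i)$p_enrich
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)

  # relabelling non-candidate genes changes nothing
  cand <- gp$gene[1:10]
  e1 <- gsea_enrichment(gp, cand, n_perm = 199, seed = 35)
  gp2 <- gp
  out <- !gp2$gene %in% cand
  gp2$gene[out] <- paste0(gp2$gene[out], "x")
  e2 <- gsea_enrichment(gp2, cand, n_perm = 199, seed = 35)
  expect_equal(e1$ES_obs, e2$ES_obs, tolerance = 1e-12)
  expect_equal(e1$p_enrich, e2$p_enrich)

  expect_error(gsea_enrichment(gp, gp$gene), "set size")
  expect_error(gsea_enrichment(gp, "nope"), "absent")
})
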