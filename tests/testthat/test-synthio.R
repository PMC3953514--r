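test_that("dosages stay in {0,1,2} and simulation is seed-deterministic", {
  p <- snp_panel("s1", "1", 100, maf = 0.5)
  g <- simulate_genotypes(4, p, seed = 3)
  expect_equal(dim(g$dosages), c(4L, 1L))
  expect_true(all(g$dosages %in% c(0, 1, 2)))

  g2 <- simulate_genotypes(4, p, seed = 3)
  expect_identical(g$dosages, g2$dosages)

  cfg <- cohort_config("c", 60, small_panel(), seed = 11,
                       structure_shift = 0.05, missing_rate = 0.01)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))

  expect_error(simulate_genotypes(0, p), "positive")
  expect_error(snp_panel("s1", "1", 100, maf = 0.6), "maf")
  expect_error(snp_panel(c("a", "a"), "1", c(1, 2), maf = 0.1), "duplicate")
})

test_that("without LD the per-SNP dosage law is Binomial(2, maf) in HWE", {
  p <- snp_panel("s1", "1", 100, maf = 0.2)
  g <- simulate_genotypes(10000, p, ld_rho = 0, seed = 1)
  maf_hat <- mean(g$dosages) / 2
  expect_lt(abs(maf_hat - 0.2), 0.01)

  hwe_ok <- vapply(1:30, function(s) {
    d <- simulate_genotypes(3000, p, ld_rho = 0, seed = 1000 + s)$dosages
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2)) > 0.001
  }, logical(1))
  expect_gte(sum(hwe_ok), 29)
})

test_that("AR(1) blocks induce LD within genes but not across them", {
  pan <- snp_panel(c("a1", "a2", "b1"), "1", c(100, 200, 300),
                   maf = c(0.3, 0.3, 0.3), gene = c("gA", "gA", "gB"))
  g <- simulate_genotypes(10000, pan, ld_rho = 0.9, seed = 2)
  expect_gt(cor(g$dosages[, "a1"], g$dosages[, "a2"]), 0.5)
  expect_lt(abs(cor(g$dosages[, "a2"], g$dosages[, "b1"])), 0.05)
})

test_that("battery tracks latent g and no-structure cohorts are unstructured", {
  co <- simulate_cohort(cohort_config("hi", 500, small_panel(),
                                      loadings = rep(0.99, 4), seed = 4))
  for (j in 1:4) {
    expect_gt(cor(co$battery[[paste0("test_", j)]], co$latent_g), 0.9)
  }
  co0 <- simulate_cohort(cohort_config("null", 5000, small_panel(),
                                       structure_shift = 0, seed = 5))
  r <- cor(co0$covariates$subpop, rowMeans(co0$genotypes$dosages))
  expect_lt(abs(r), 0.05)
})

test_that("annotation fixture reproduces the candidate-set template", {
  fx0 <- make_annotation_fixture(n_background = 0, seed = 7)
  expect_equal(nrow(fx0$annotation), 27L)
  expect_length(fx0$candidate_set, 27L)
  expect_equal(sum(fx0$imputed_panel$gene == "GNAZ"), 138L)
  expect_equal(nrow(fx0$genotyped_panel), 470L)
  # chip-style panel covers 24 genes (three dropped for lack of coverage)
  expect_equal(length(unique(fx0$genotyped_panel$gene)), 24L)

  fx <- make_annotation_fixture(n_background = 30, seed = 7)
  expect_equal(nrow(fx$annotation), 57L)
  bg <- fx$annotation[grepl("^BG", fx$annotation$gene), ]
  expect_true(all(bg$start <= bg$stop))
  # background windows stay clear of the candidate gene windows
  cand <- gene_window(fx$annotation[!grepl("^BG", fx$annotation$gene), ],
                      symmetric_flank = 50000)
  expect_true(min(bg$start) - 50000 > max(cand$win_stop))
})

test_that("dosage-tsv and VCF round-trips preserve the matrix and missingness", {
  co <- small_cohort(n = 30, seed = 21, missing_rate = 0.05)
  g <- co$genotypes
  expect_true(anyNA(g$dosages))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(g, tsv)
  g_tsv <- read_dosage_tsv(tsv)
  expect_identical(g_tsv$dosages, g$dosages)
  expect_identical(g_tsv$snps[, c("snp_id", "chrom", "pos", "ref", "alt")],
                   g$snps[, c("snp_id", "chrom", "pos", "ref", "alt")])

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_file(g, vcf)
  g_vcf <- read_vcf_file(vcf)
  expect_identical(unname(g_vcf$dosages), unname(g$dosages))
  expect_identical(is.na(g_vcf$dosages), is.na(g$dosages))
})

test_that("malformed genotype files raise parse errors, not silent truncation", {
  co <- small_cohort(n = 10, seed = 22)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(co$genotypes, tsv)
  lines <- readLines(tsv)
  truncated <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(lines[1:3], substr(lines[4], 1, 20)), truncated)
  expect_error(read_dosage_tsv(truncated), "malformed|invalid")

  bad <- withr::local_tempfile(fileext = ".tsv")
  lines4 <- strsplit(lines[4], "\t")[[1]]
  lines4[7] <- "3"
  writeLines(c(lines[1:3], paste(lines4, collapse = "\t")), bad)
  expect_error(read_dosage_tsv(bad), "data line 3")
})

test_that("cohort directory round-trip restores all tables", {
  co <- small_cohort(n = 25, seed = 23)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, genotype_format = "dosage-tsv")
  back <- read_cohort(dir)
  expect_identical(back$genotypes$dosages, co$genotypes$dosages)
  expect_equal(back$covariates, co$covariates)
  expect_equal(back$battery, co$battery)
  expect_equal(back$latent_g, co$latent_g)
  expect_identical(back$name, co$name)
})

test_that("GMT and annotation readers round-trip and convert BED starts", {
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g9"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_equal(read_gmt(gmt), sets)

  ann <- data.frame(gene = "g1", chrom = "2", start = 10L, stop = 20L,
                    strand = "+", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, f)
  expect_equal(read_annotation_tsv(f), ann)
  ann0 <- ann
  ann0$start <- 9L  # BED-style 0-based half-open start
  write_annotation_tsv(ann0, f)
  expect_equal(read_annotation_tsv(f, zero_based = TRUE)$start, 10L)
})
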