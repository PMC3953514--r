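# Shared builders, memoised so expensive fixtures are constructed once per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small multi-gene panel for unit tests: 3 genes x 8 SNPs.
small_panel <- function(seed = 5) {
  random_panel(24, chrom = "1", spacing = 500,
               gene = rep(c("gA", "gB", "gC"), each = 8), seed = seed)
}

# One small cohort on the small panel.
small_cohort <- function(n = 200, seed = 9, ...) {
  simulate_cohort(cohort_config("toy", n, small_panel(), ld_rho = 0.2,
                                seed = seed, ...))
}

# Full candidate fixture + the five fluid-ability-sized cohorts, shared by
# the heavier calibration and acceptance tests.
fluid_fixture <- function() {
  cached("fluid_fixture", make_annotation_fixture(seed = 101))
}

fluid_cohorts <- function() {
  cached("fluid_cohorts", {
    fx <- fluid_fixture()
    ns <- c(505, 989, 350, 754, 805)
    lapply(seq_along(ns), function(i) {
      simulate_cohort(cohort_config(sprintf("cohort%d", i), ns[i],
                                    fx$genotyped_panel, ld_rho = 0.2,
                                    seed = 100 + i))
    })
  })
}

fluid_set_snps <- function() {
  cached("fluid_set_snps", {
    fx <- fluid_fixture()
    map <- map_snps_to_genes(fx$genotyped_panel, fx$annotation)
    suppressMessages(build_set_snplist(fx$candidate_set, map))
  })
}

# Brute-force interval scan: the mapping oracle.
naive_map <- function(panel, windows) {
  out <- lapply(seq_len(nrow(windows)), function(i) {
    hit <- panel$chrom == windows$chrom[i] &
      panel$pos >= windows$win_start[i] & panel$pos <= windows$win_stop[i]
    ids <- panel$snp_id[hit]
    ids[order(panel$pos[hit], ids)]
  })
  names(out) <- windows$gene
  out
}

# Exact HWE oracle: direct enumeration of the conditional distribution of
# the heterozygote count given allele counts, written independently of the
# package implementation.
hwe_enum_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na <- 2 * aa + ab
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hets, function(h) {
    hom_a <- (na - h) / 2
    hom_b <- n - hom_a - h
    exp(lfactorial(n) - lfactorial(hom_a) - lfactorial(h) - lfactorial(hom_b) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }, numeric(1))
  p_obs <- pr[hets == ab]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# Brute-force unit-weight running-sum K-S walk for short ranked lists.
ks_walk_oracle <- function(member) {
  n <- length(member)
  m <- sum(member)
  walk <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (member[i]) 1 / m else -1 / (n - m)
    walk[i] <- acc
  }
  walk
}

# The enrichment score must be the maximum-magnitude deviation of the walk;
# when the positive and negative extremes tie in magnitude, either signed
# value is a valid K-S deviation (the tie is broken by accumulated rounding).
expect_ks_extremum <- function(es, walk) {
  expect_equal(abs(es), max(abs(walk)), tolerance = 1e-12)
  expect_lt(min(abs(es - max(walk)), abs(es - min(walk))), 1e-12)
}
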