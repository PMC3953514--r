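# Synthetic genotype and cohort generation.
#
# Genotypes are additive dosages in {0, 1, 2} drawn from a Gaussian-copula
# model: each of the two allele draws is a latent standard-normal vector with
# AR(1) correlation along contiguous same-gene SNP runs, thresholded at the
# quantile implied by the SNP's minor allele frequency.  At ld_rho = 0 the two
# allele indicators are independent Bernoulli(maf) draws, so genotype counts
# satisfy Hardy-Weinberg equilibrium by construction.

#' Construct a SNP panel
#'
#' A SNP panel is a data frame describing the markers of a genotype matrix:
#' identifier, chromosome, 1-based position, reference and alternate allele,
#' minor allele frequency, and an optional gene tag used to delimit LD blocks
#' during simulation.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome labels (character).
#' @param pos 1-based base-pair positions (integers >= 1).
#' @param ref,alt single-character alleles.
#' @param maf minor allele frequencies in (0, 0.5]; `NA` is allowed for
#'   panels read from disk where the design frequency is unknown.
#' @param gene optional gene tag; contiguous runs of the same tag form one
#'   AR(1) LD block in [simulate_genotypes()].
#' @return a `data.frame` of class `snp_panel`.
#' @export
snp_panel <- function(snp_id, chrom, pos, ref = "A", alt = "G",
                      maf = NA_real_, gene = NA_character_) {
  n <- length(snp_id)
  p <- data.frame(snp_id = as.character(snp_id),
                  chrom = rep_len(as.character(chrom), n),
                  pos = as.integer(pos),
                  ref = rep_len(as.character(ref), n),
                  alt = rep_len(as.character(alt), n),
                  maf = rep_len(as.numeric(maf), n),
                  gene = rep_len(as.character(gene), n),
                  stringsAsFactors = FALSE)
  validate_snp_panel(p)
}

validate_snp_panel <- function(p) {
  if (anyDuplicated(p$snp_id)) stop("duplicate snp_id in panel", call. = FALSE)
  if (any(p$pos < 1L)) stop("SNP positions must be >= 1", call. = FALSE)
  bad <- !is.na(p$maf) & !(p$maf > 0 & p$maf <= 0.5)
  if (any(bad)) {
    stop(sprintf("maf outside (0, 0.5] for: %s",
                 paste(utils::head(p$snp_id[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  class(p) <- c("snp_panel", "data.frame")
  p
}

#' Random SNP panel for simulations
#'
#' Convenience generator: `n_snps` markers on one chromosome with evenly
#' spaced positions and MAFs drawn Uniform(0.05, 0.45) (the post-QC common
#' variant range the analysis assumes).
#'
#' @param n_snps number of SNPs.
#' @param chrom chromosome label.
#' @param start first position; SNPs are spaced `spacing` bp apart.
#' @param spacing inter-SNP spacing in bp.
#' @param maf_range range from which MAFs are drawn uniformly.
#' @param gene optional gene tag(s), recycled.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return a [snp_panel()].
#' @export
random_panel <- function(n_snps, chrom = "1", start = 1000L, spacing = 1000L,
                         maf_range = c(0.05, 0.45), gene = NA_character_,
                         seed = NULL) {
  with_seed(seed, {
    snp_panel(snp_id = sprintf("snp%04d", seq_len(n_snps)),
              chrom = chrom,
              pos = start + spacing * (seq_len(n_snps) - 1L),
              maf = stats::runif(n_snps, maf_range[1], maf_range[2]),
              gene = gene)
  })
}

#' Construct a genotype matrix
#'
#' Couples an individuals-by-SNPs dosage matrix (entries in \{0, 1, 2\} or
#' `NA`) with its SNP panel.
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns.
#' @param snps a [snp_panel()] with one row per column of `dosages`.
#' @param individual_ids unique individual identifiers; defaults to the row
#'   names of `dosages` or `ind0001`-style labels.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snps, individual_ids = NULL) {
  snps <- validate_snp_panel(as.data.frame(snps))
  if (is.null(individual_ids)) {
    individual_ids <- rownames(dosages)
    if (is.null(individual_ids)) {
      individual_ids <- sprintf("ind%04d", seq_len(nrow(dosages)))
    }
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual ids", call. = FALSE)
  }
  if (ncol(dosages) != nrow(snps)) {
    stop("ncol(dosages) must equal nrow(snps)", call. = FALSE)
  }
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("non-missing dosages must be 0, 1 or 2", call. = FALSE)
  }
  dimnames(dosages) <- list(individual_ids, snps$snp_id)
  structure(list(dosages = dosages, snps = snps,
                 individual_ids = as.character(individual_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Block ids for AR(1) latent correlation: contiguous runs of one gene tag
# form a block; untagged SNPs are singleton blocks.
ld_blocks <- function(gene) {
  g <- as.character(gene)
  m <- length(g)
  if (m == 0L) return(integer(0))
  new <- rep(TRUE, m)
  if (m > 1L) {
    same <- !is.na(g[-1]) & !is.na(g[-m]) & g[-1] == g[-m]
    new[-1] <- !same
  }
  cumsum(new)
}

# Latent n x m standard-normal matrix with AR(1) correlation `rho` along
# columns within each block.
ar1_latent <- function(n, blocks, rho) {
  m <- length(blocks)
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0 && m > 1L) {
    a <- sqrt(1 - rho^2)
    for (j in 2:m) {
      if (blocks[j] == blocks[j - 1L]) z[, j] <- rho * z[, j - 1L] + a * z[, j]
    }
  }
  z
}

#' Simulate additive genotype dosages
#'
#' Draws diploid dosages under a Gaussian-copula LD model: per allele copy, a
#' latent standard-normal vector with AR(1) correlation `ld_rho` within
#' contiguous same-gene SNP runs is thresholded at `qnorm(maf)`; the dosage
#' is the sum of the two allele indicators.  With `ld_rho = 0` each SNP's
#' genotype is Binomial(2, maf), i.e. Hardy-Weinberg by construction.
#'
#' Optional two-subpopulation structure shifts each SNP's allele frequency by
#' `structure_shift` (random sign per SNP) in subpopulation 1, and optional
#' missingness is injected completely at random.
#'
#' @param n_ind number of individuals (> 0).
#' @param panel a [snp_panel()] with non-missing `maf`.
#' @param ld_rho within-block latent correlation in `[0, 1)`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param missing_rate per-entry missingness probability in `[0, 1)`.
#' @param subpop optional 0/1 vector of length `n_ind` assigning individuals
#'   to the two subpopulations.
#' @param structure_shift allele-frequency divergence (>= 0) applied to
#'   subpopulation 1.
#' @param individual_ids optional identifiers.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_ind, panel, ld_rho = 0, seed = NULL,
                               missing_rate = 0, subpop = NULL,
                               structure_shift = 0, individual_ids = NULL) {
  if (length(n_ind) != 1L || n_ind < 1) stop("n_ind must be positive", call. = FALSE)
  n_ind <- as.integer(n_ind)
  panel <- validate_snp_panel(as.data.frame(panel))
  if (nrow(panel) == 0L) stop("panel must be non-empty", call. = FALSE)
  if (anyNA(panel$maf)) stop("panel maf must be known for simulation", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)", call. = FALSE)
  if (structure_shift < 0) stop("structure_shift must be >= 0", call. = FALSE)
  m <- nrow(panel)
  with_seed(seed, {
    shift_dir <- sample(c(-1, 1), m, replace = TRUE)
    p0 <- panel$maf
    p1 <- pmin(pmax(p0 + structure_shift * shift_dir, 0.005), 0.995)
    thr <- matrix(stats::qnorm(p0), n_ind, m, byrow = TRUE)
    if (!is.null(subpop) && structure_shift > 0) {
      stopifnot(length(subpop) == n_ind)
      sel <- subpop == 1
      if (any(sel)) {
        thr[sel, ] <- matrix(stats::qnorm(p1), sum(sel), m, byrow = TRUE)
      }
    }
    blocks <- ld_blocks(panel$gene)
    d <- (ar1_latent(n_ind, blocks, ld_rho) < thr) +
         (ar1_latent(n_ind, blocks, ld_rho) < thr)
    storage.mode(d) <- "double"
    if (missing_rate > 0) {
      d[stats::runif(length(d)) < missing_rate] <- NA_real_
    }
    genotype_matrix(d, panel, individual_ids)
  })
}

#' Cohort simulation configuration
#'
#' Bundles the parameters of one synthetic cohort: sample size, SNP panel,
#' LD, the latent-ability test battery (per-test factor loadings), optional
#' two-subpopulation structure, missingness, and a seed.
#'
#' @param name cohort label (also salts the cohort's RNG stream downstream).
#' @param n_individuals sample size (> 0).
#' @param panel a [snp_panel()].
#' @param ld_rho within-gene latent LD correlation in `[0, 1)`.
#' @param n_test_battery number of cognitive tests in the battery (>= 1).
#' @param loadings per-test factor loadings in (0, 1), length
#'   `n_test_battery`.
#' @param structure_shift allele-frequency divergence of subpopulation 1 and
#'   the additive shift of latent ability for that subpopulation.
#' @param missing_rate genotype missingness rate.
#' @param age_range range of the uniform age distribution (years).
#' @param seed integer seed making the cohort fully reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(name, n_individuals, panel, ld_rho = 0.2,
                          n_test_battery = 4L,
                          loadings = rep(0.7, n_test_battery),
                          structure_shift = 0, missing_rate = 0,
                          age_range = c(65, 80), seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be > 0", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)", call. = FALSE)
  if (n_test_battery < 1) stop("n_test_battery must be >= 1", call. = FALSE)
  if (length(loadings) != n_test_battery) {
    stop("loadings must have length n_test_battery", call. = FALSE)
  }
  if (!all(loadings > 0 & loadings < 1)) {
    stop("loadings must lie in (0, 1)", call. = FALSE)
  }
  structure(list(name = name, n_individuals = as.integer(n_individuals),
                 panel = validate_snp_panel(as.data.frame(panel)),
                 ld_rho = ld_rho, n_test_battery = as.integer(n_test_battery),
                 loadings = loadings, structure_shift = structure_shift,
                 missing_rate = missing_rate, age_range = age_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate one cohort
#'
#' Generates genotypes via [simulate_genotypes()], a latent general-ability
#' score `g ~ N(0, 1)` (shifted by `structure_shift` in subpopulation 1), a
#' test battery where test `j` scores `loading_j * g + N(0, 1 - loading_j^2)`
#' noise, uniform ages, Bernoulli(0.5) sex, and the subpopulation labels.
#' The latent `g` is retained as synthetic truth for recovery tests.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort` with elements `name`, `genotypes`,
#'   `covariates` (individual_id, age, sex, subpop), `battery`
#'   (individual_id, test_1, ...), and `latent_g`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_individuals
  with_seed(config$seed, {
    ids <- sprintf("%s_%05d", config$name, seq_len(n))
    subpop <- stats::rbinom(n, 1L, 0.5)
    geno <- simulate_genotypes(n, config$panel, ld_rho = config$ld_rho,
                               missing_rate = config$missing_rate,
                               subpop = subpop,
                               structure_shift = config$structure_shift,
                               individual_ids = ids)
    g <- stats::rnorm(n) + config$structure_shift * subpop
    battery <- vapply(config$loadings, function(l) {
      l * g + stats::rnorm(n, sd = sqrt(1 - l^2))
    }, numeric(n))
    battery <- as.data.frame(battery)
    names(battery) <- sprintf("test_%d", seq_along(config$loadings))
    battery <- cbind(data.frame(individual_id = ids, stringsAsFactors = FALSE),
                     battery)
    covar <- data.frame(individual_id = ids,
                        age = stats::runif(n, config$age_range[1], config$age_range[2]),
                        sex = stats::rbinom(n, 1L, 0.5),
                        subpop = subpop,
                        stringsAsFactors = FALSE)
    structure(list(name = config$name, genotypes = geno, covariates = covar,
                   battery = battery, latent_g = g, config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: n = %d, %d SNPs, %d battery tests\n",
              x$name, nrow(x$covariates), ncol(x$genotypes$dosages),
              ncol(x$battery) - 1L))
  invisible(x)
}
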