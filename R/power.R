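# Monte-Carlo power study for the meta-analysed self-contained set test.
#
# Design: effects beta_j ~ N(0, 1) are allocated to k randomly chosen set
# SNPs (the same allocation applies in every cohort); the genetic component
# g_i = sum_j X_ij beta_j (centred dosages) is fixed per cohort per
# allocation, and phenotype replicates add Gaussian noise scaled so that g
# explains a target fraction v of the phenotypic variance
# (sigma^2_noise = var(g) (1 - v) / v, using the empirical variance of g).
# Every replicate runs the permutation set test in each cohort and combines
# the empirical p-values by sqrt(N)-weighted Stouffer; power is the
# proportion of replicates with combined p below alpha.

#' Power-study configuration
#'
#' @param k_effect number of effect SNPs (0 allowed for the null
#'   configuration).
#' @param v fraction of phenotypic variance explained by the effect SNPs,
#'   in `[0, 1)`; `v = 0` generates pure-noise phenotypes.
#' @param n_phenotypes phenotype replicates per allocation.
#' @param n_allocations independent redraws of the effect allocation.
#' @param alpha significance threshold for the combined p-value.
#' @param B permutations per set test (>= 99 so the permutation floor
#'   resolves alpha).
#' @param seed master seed; every nested stream derives from it.
#' @param method set statistic (see [set_statistic()]).
#' @return an object of class `power_config`.
#' @export
power_config <- function(k_effect, v, n_phenotypes = 1000L,
                         n_allocations = 100L, alpha = 0.05, B = 10000L,
                         seed = 1L, method = c("sumlog", "sumz2")) {
  method <- match.arg(method)
  if (v < 0 || v >= 1) stop("v must lie in [0, 1)", call. = FALSE)
  stop_if_not_prob(alpha, "alpha")
  if (k_effect < 0) stop("k_effect must be >= 0", call. = FALSE)
  if (n_phenotypes < 1 || n_allocations < 1) {
    stop("replicate counts must be >= 1", call. = FALSE)
  }
  structure(list(k_effect = as.integer(k_effect), v = v,
                 n_phenotypes = as.integer(n_phenotypes),
                 n_allocations = as.integer(n_allocations),
                 alpha = alpha, B = as.integer(B), seed = as.integer(seed),
                 method = method),
            class = "power_config")
}

#' Allocate sparse SNP effects
#'
#' Exactly `k_effect` of the set SNPs (chosen uniformly without
#' replacement) receive i.i.d. N(0, 1) effects; the rest are zero.
#'
#' @param set_snps SNP ids of the set.
#' @param k_effect number of effect SNPs (<= set size).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return a named numeric effect vector over `set_snps`.
#' @export
allocate_effects <- function(set_snps, k_effect, seed = NULL) {
  m <- length(set_snps)
  if (k_effect > m) stop("k_effect exceeds the set size", call. = FALSE)
  with_seed(seed, {
    beta <- stats::setNames(numeric(m), set_snps)
    if (k_effect > 0) {
      idx <- sample.int(m, k_effect)
      beta[idx] <- stats::rnorm(k_effect)
    }
    beta
  })
}

# Centred (mean-imputed) dosage matrix over the set SNPs, in set order.
centred_set_dosages <- function(g, set_snps) {
  if (inherits(g, "cohort")) g <- g$genotypes
  x <- mean_impute(g$dosages[, set_snps, drop = FALSE])
  sweep(x, 2L, colMeans(x))
}

#' Simulate phenotype replicates at a target variance fraction
#'
#' The predicted genetic score is `g = Xc beta` (centred dosages); each
#' phenotype column is `g` plus Gaussian noise with variance
#' `var(g) (1 - v) / v`, so `g` explains fraction `v` of the phenotypic
#' variance in expectation.  `v = 0` returns pure N(0, 1) noise columns.
#'
#' @param g a [genotype_matrix()] or `cohort`.
#' @param beta named effect vector (names are set SNP ids).
#' @param v variance fraction in `[0, 1)`.
#' @param n_phenotypes number of replicate columns.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return an n-by-`n_phenotypes` matrix of phenotypes.
#' @export
simulate_power_phenotypes <- function(g, beta, v, n_phenotypes, seed = NULL) {
  if (v < 0 || v >= 1) stop("v must lie in [0, 1)", call. = FALSE)
  if (inherits(g, "cohort")) g <- g$genotypes
  n <- nrow(g$dosages)
  with_seed(seed, {
    if (v == 0) {
      return(matrix(stats::rnorm(n * n_phenotypes), n, n_phenotypes))
    }
    if (all(beta == 0)) {
      stop("beta is all zero but v > 0", call. = FALSE)
    }
    xc <- centred_set_dosages(g, names(beta))
    gen <- as.numeric(xc %*% beta)
    sd_noise <- sqrt(stats::var(gen) * (1 - v) / v)
    gen + matrix(stats::rnorm(n * n_phenotypes, sd = sd_noise),
                 n, n_phenotypes)
  })
}

#' Estimate power of the meta-analysed set test
#'
#' For each of `n_allocations` effect allocations and `n_phenotypes`
#' phenotype replicates: simulate one phenotype per cohort, run
#' [self_contained_test()] in each cohort (B permutations), combine the
#' empirical p-values with [stouffer_meta()] using sqrt(N) weights, and
#' count combined p-values below `alpha`.  Fully deterministic under the
#' master seed, including the nested permutation streams.
#'
#' @param cohorts list of `cohort` or [genotype_matrix()] objects sharing
#'   the SNP panel.
#' @param set_snps SNP ids of the candidate set.
#' @param config a [power_config()].
#' @return an object of class `power_estimate`: pooled `power`, `mc_se`,
#'   `per_allocation` powers, `n_replicates`, and the config.
#' @export
estimate_power <- function(cohorts, set_snps, config) {
  stopifnot(inherits(config, "power_config"), length(cohorts) >= 1L)
  if (config$B < 99L) stop("B must be >= 99 so 1/(B+1) resolves alpha",
                           call. = FALSE)
  names(cohorts) <- vapply(seq_along(cohorts), function(i) {
    co <- cohorts[[i]]
    if (inherits(co, "cohort") && !is.null(co$name)) co$name
    else sprintf("cohort%d", i)
  }, character(1))
  preps <- lapply(cohorts, prepare_set_matrix, set_snps = set_snps)
  xcs <- lapply(cohorts, centred_set_dosages, set_snps = set_snps)
  ns <- vapply(preps, `[[`, integer(1), "n")
  R <- config$n_phenotypes
  hits <- matrix(NA, nrow = config$n_allocations, ncol = R)
  for (a in seq_len(config$n_allocations)) {
    beta <- allocate_effects(set_snps, config$k_effect,
                             seed = stream_seed(config$seed,
                                                sprintf("alloc%03d", a)))
    # per cohort: replicate phenotype matrix and observed statistics
    p_cohort <- matrix(NA_real_, nrow = R, ncol = length(cohorts))
    for (ci in seq_along(cohorts)) {
      nm <- names(cohorts)[ci]
      Y <- simulate_power_phenotypes(
        cohorts[[ci]], beta, config$v, R,
        seed = stream_seed(config$seed, sprintf("pheno_%s_%03d", nm, a)))
      for (r in seq_len(R)) {
        res <- self_contained_test(
          preps[[ci]], Y[, r], B = config$B,
          seed = stream_seed(config$seed,
                             sprintf("perm_%s_%03d_%04d", nm, a, r)),
          cohort = nm, method = config$method)
        p_cohort[r, ci] <- res$p_emp
      }
    }
    for (r in seq_len(R)) {
      meta <- stouffer_meta(p_cohort[r, ], ns, cohorts = names(cohorts))
      hits[a, r] <- meta$p_meta < config$alpha
    }
  }
  per_alloc <- rowMeans(hits)
  total <- length(hits)
  pw <- mean(hits)
  structure(list(power = pw,
                 mc_se = sqrt(pw * (1 - pw) / total),
                 per_allocation = per_alloc,
                 n_replicates = total,
                 config = config),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "<power_estimate> k = %d, v = %.3f: power = %.3f (MC SE %.3f, %d replicates)\n",
    x$config$k_effect, x$config$v, x$power, x$mc_se, x$n_replicates))
  invisible(x)
}

#' Power over a grid of effect-SNP counts and variance fractions
#'
#' One [estimate_power()] per (k, v) cell, each on its own deterministic
#' sub-stream of `seed`.
#'
#' @param cohorts,set_snps as in [estimate_power()].
#' @param k_list effect-SNP counts.
#' @param v_list variance fractions.
#' @param n_phenotypes,n_allocations,alpha,B,seed shared replicate settings
#'   (see [power_config()]).
#' @return a data.frame: `k_effect`, `v`, `n_phenotypes`, `n_allocations`,
#'   `B`, `power`, `mc_se`, `seed`.
#' @export
power_grid <- function(cohorts, set_snps, k_list, v_list,
                       n_phenotypes = 400L, n_allocations = 5L,
                       alpha = 0.05, B = 999L, seed = 1L) {
  if (!length(k_list) || !length(v_list)) {
    stop("k_list and v_list must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (k in k_list) {
    for (v in v_list) {
      cell_seed <- stream_seed(seed, sprintf("cell_k%d_v%g", k, v))
      est <- estimate_power(cohorts, set_snps,
                            power_config(k, v, n_phenotypes, n_allocations,
                                         alpha, B, seed = cell_seed))
      rows[[length(rows) + 1L]] <-
        data.frame(k_effect = k, v = v, n_phenotypes = n_phenotypes,
                   n_allocations = n_allocations, B = B, power = est$power,
                   mc_se = est$mc_se, seed = cell_seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
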