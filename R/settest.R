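# Self-contained SNP-set test by phenotype permutation, and weighted
# Stouffer combination of per-cohort empirical p-values.
#
# The set statistic is T = sum over set SNPs of -log10(p_SNP), with p_SNP
# the two-sided t-test p-value of the per-SNP additive regression.  Because
# the phenotype is residualised before testing, each per-SNP regression
# reduces to a correlation test, so the whole permutation null can be
# computed with one matrix product per batch of permutations.

#' Aggregate per-SNP p-values into a set statistic
#'
#' `sumlog` (default): `T = sum(-log10 p)`; `sumz2`: `T = sum(qnorm(p/2)^2)`
#' (the sum of squared two-sided normal deviates), kept behind a switch for
#' comparison.  Degenerate SNPs must be excluded upstream.
#'
#' @param p_values per-SNP p-values in (0, 1].
#' @param method `"sumlog"` or `"sumz2"`.
#' @return the scalar set statistic (>= 0).
#' @export
set_statistic <- function(p_values, method = c("sumlog", "sumz2")) {
  method <- match.arg(method)
  if (!length(p_values)) stop("empty p-value list", call. = FALSE)
  stop_if_not_prob(p_values, "p_values", open_left = TRUE, open_right = FALSE)
  if (method == "sumlog") sum(-log10(p_values))
  else sum(stats::qnorm(p_values / 2)^2)
}

# Prepare a centred, unit-variance SNP matrix for the permutation engine:
# mean-impute missing dosages, drop constant SNPs (logged via attribute),
# and scale columns.  Reused across replicates in the power study.
prepare_set_matrix <- function(g, set_snps) {
  if (inherits(g, "cohort")) g <- g$genotypes
  stopifnot(inherits(g, "genotype_matrix"))
  miss <- setdiff(set_snps, colnames(g$dosages))
  if (length(miss)) stop("set SNPs absent from genotypes: ",
                         paste(utils::head(miss, 5), collapse = ", "),
                         call. = FALSE)
  x <- mean_impute(g$dosages[, set_snps, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) x <- x[, sds > 0, drop = FALSE]
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 individuals", call. = FALSE)
  if (!ncol(x)) stop("no polymorphic SNPs in the set", call. = FALSE)
  xs <- scale(x)
  structure(list(xs = xs, n = n, m = ncol(xs), snp_ids = colnames(xs),
                 df = n - 2L, dropped = dropped),
            class = "prepared_set_matrix")
}

# T statistics for a matrix of standardised phenotypes: columns of `ys` are
# centred unit-variance phenotype vectors; returns one T per column.
# Correlation -> t -> two-sided p at df = n - 2 -> sum(-log10 p), identical
# to per-SNP OLS on the same data.
set_stat_from_scaled <- function(prep, ys, method = "sumlog") {
  r <- crossprod(prep$xs, ys) / (prep$n - 1)
  r2 <- pmin(r * r, 1 - 1e-12)
  tstat <- abs(r) * sqrt(prep$df / (1 - r2))
  p <- pmax(2 * stats::pt(tstat, df = prep$df, lower.tail = FALSE),
            .Machine$double.xmin)
  if (method == "sumlog") colSums(-log10(p))
  else colSums(stats::qnorm(p / 2)^2)
}

scale_vec <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("constant phenotype", call. = FALSE)
  (y - mean(y)) / s
}

#' Self-contained SNP-set association test
#'
#' Computes the observed set statistic from the per-SNP p-values on the
#' observed phenotype, then permutes the phenotype across individuals `B`
#' times, recomputing the statistic each time; the empirical p-value is
#' `(1 + #\{T_b >= T_obs\}) / (1 + B)` (never zero by construction, floored
#' at `1/(B+1)`).
#'
#' @param g a [genotype_matrix()], `cohort`, or pre-computed
#'   `prepared_set_matrix`.
#' @param y phenotype: numeric vector in genotype row order or a
#'   `phenotype_vector` (then `g` must carry the same individuals in the
#'   same order after alignment by id).
#' @param set_snps SNP ids forming the set (ignored when `g` is already
#'   prepared).
#' @param B number of permutations (>= 1; default 10000).
#' @param seed integer seed; the permutation stream is fully reproducible.
#' @param cohort label stored on the result.
#' @param method set statistic, see [set_statistic()].
#' @return an object of class `set_test_result`: `cohort`, `snp_ids`,
#'   `T_obs`, `B`, `p_emp`, `seed`, `n`, and the permutation statistics
#'   `T_perm`.
#' @export
self_contained_test <- function(g, y, set_snps = NULL, B = 10000L,
                                seed = 1L, cohort = NA_character_,
                                method = c("sumlog", "sumz2")) {
  method <- match.arg(method)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  prep <- if (inherits(g, "prepared_set_matrix")) g
          else prepare_set_matrix(g, set_snps)
  if (inherits(y, "phenotype_vector")) {
    idx <- match(rownames(prep$xs), y$individual_ids)
    if (anyNA(idx)) stop("phenotype must cover all genotyped individuals",
                         call. = FALSE)
    y <- unname(y$values[idx])
  }
  stopifnot(length(y) == prep$n)
  ys <- scale_vec(y)
  T_obs <- set_stat_from_scaled(prep, matrix(ys, ncol = 1L), method)
  T_perm <- with_seed(seed, {
    perm <- vapply(seq_len(B), function(b) ys[sample.int(prep$n)],
                   numeric(prep$n))
    set_stat_from_scaled(prep, perm, method)
  })
  p_emp <- (1 + sum(T_perm >= T_obs)) / (1 + B)
  structure(list(cohort = cohort, snp_ids = prep$snp_ids, T_obs = T_obs,
                 B = as.integer(B), p_emp = p_emp, seed = as.integer(seed),
                 n = prep$n, method = method, T_perm = T_perm,
                 dropped_snps = prep$dropped),
            class = "set_test_result")
}

#' @export
print.set_test_result <- function(x, ...) {
  cat(sprintf(
    "<set_test_result> %s: %d SNPs, n = %d, T_obs = %.3f, B = %d, p_emp = %.4g\n",
    ifelse(is.na(x$cohort), "(unnamed)", x$cohort), length(x$snp_ids), x$n,
    x$T_obs, x$B, x$p_emp))
  invisible(x)
}

#' Weighted Stouffer combination of per-cohort p-values
#'
#' One-sided conversion `Z_i = qnorm(1 - p_i)`, combined with square-root
#' sample-size weights:
#' `Z_meta = sum(sqrt(N_i) Z_i) / sqrt(sum(N_i))`, `p_meta = 1 - pnorm(Z)`.
#'
#' @param p_list per-cohort p-values in (0, 1] (the permutation floor keeps
#'   them off 0; a p of exactly 1 maps to `Z_i = -Inf` and hence
#'   `p_meta = 1`, the continuous limit).
#' @param n_list per-cohort sample sizes (weights are their square roots).
#' @param cohorts optional labels.
#' @return an object of class `meta_set_result`: per-cohort table,
#'   `Z_meta`, `p_meta`.
#' @export
stouffer_meta <- function(p_list, n_list, cohorts = NULL) {
  p <- as.numeric(p_list)
  n <- as.numeric(n_list)
  stopifnot(length(p) == length(n), length(p) >= 1L, all(n > 0))
  stop_if_not_prob(p, "p_list", open_right = FALSE)
  z <- stats::qnorm(1 - p)
  w <- sqrt(n)
  Z_meta <- sum(w * z) / sqrt(sum(n))
  structure(list(per_cohort = data.frame(
                   cohort = if (is.null(cohorts)) sprintf("cohort%d", seq_along(p))
                            else as.character(cohorts),
                   p = p, n = n, z = z, weight = w,
                   stringsAsFactors = FALSE),
                 Z_meta = Z_meta,
                 p_meta = stats::pnorm(Z_meta, lower.tail = FALSE)),
            class = "meta_set_result")
}

#' @export
print.meta_set_result <- function(x, ...) {
  cat(sprintf("<meta_set_result> %d cohorts, Z = %.4f, p_meta = %.4g\n",
              nrow(x$per_cohort), x$Z_meta, x$p_meta))
  invisible(x)
}

#' Tabulate set-test results across cohorts and phenotypes
#'
#' Flattens a list of [self_contained_test()] results into the results-TSV
#' layout: cohort, phenotype, n, n_snps, T_obs, B, p_emp, seed.
#'
#' @param results named list (phenotype -> list of `set_test_result`).
#' @return a data.frame.
#' @export
set_test_table <- function(results) {
  rows <- lapply(names(results), function(ph) {
    do.call(rbind, lapply(results[[ph]], function(r) {
      data.frame(cohort = r$cohort, phenotype = ph, n = r$n,
                 n_snps = length(r$snp_ids), T_obs = r$T_obs, B = r$B,
                 p_emp = r$p_emp, seed = r$seed, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
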