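# Per-SNP additive association and fixed-effects inverse-variance
# meta-analysis.
#
# The phenotype entering these scans is already residualised on covariates,
# so each SNP is tested by simple OLS of the standardised score on the 0/1/2
# dosage (mean-imputed where sporadically missing).  Two-sided p-values come
# from the t distribution at n - 2 df.

#' Single-SNP additive regression
#'
#' OLS slope of `y` on the dosage with an intercept; missing dosages are
#' mean-imputed, pairs with missing `y` are dropped.  A constant dosage
#' yields a flagged degenerate result (`beta = 0`, `se = Inf`, `p = 1`)
#' that set statistics exclude.
#'
#' @param dosage per-individual dosages in \{0, 1, 2\} or `NA`.
#' @param y numeric phenotype (same length), or a
#'   `phenotype_vector` whose values are taken in order.
#' @param snp_id identifier carried into the result.
#' @return one-row data.frame: `snp_id`, `beta`, `se`, `z` (= beta/se), `p`,
#'   `n`, `degenerate`.
#' @export
snp_regression <- function(dosage, y, snp_id = NA_character_) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  stopifnot(length(dosage) == length(y))
  ok <- !is.na(y)
  x <- dosage[ok]
  y <- y[ok]
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  n <- length(y)
  if (n < 3L) stop("need at least 3 non-missing pairs", call. = FALSE)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) {
    return(data.frame(snp_id = snp_id, beta = 0, se = Inf, z = 0, p = 1,
                      n = n, degenerate = TRUE, stringsAsFactors = FALSE))
  }
  yc <- y - mean(y)
  beta <- sum(xc * yc) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  s2 <- max(rss, 0) / (n - 2L)
  se <- sqrt(s2 / sxx)
  z <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(abs(z), df = n - 2L, lower.tail = FALSE)
  data.frame(snp_id = snp_id, beta = beta, se = se, z = z,
             p = max(p, .Machine$double.xmin), n = n, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Cohort-wide association scan
#'
#' Vectorised OLS of the phenotype on every SNP, numerically identical to
#' [snp_regression()] per SNP.  Individuals are aligned by id between the
#' genotypes and the phenotype; SNPs with constant dosage are returned
#' flagged.
#'
#' @param g a [genotype_matrix()] or `cohort`.
#' @param y a `phenotype_vector` (aligned by individual id) or a numeric
#'   vector in genotype row order.
#' @param snps optional subset of SNP ids to scan.
#' @return data.frame of per-SNP results (columns as [snp_regression()]).
#' @export
gwas <- function(g, y, snps = NULL) {
  if (inherits(g, "cohort")) g <- g$genotypes
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (!is.null(snps)) {
    miss <- setdiff(snps, colnames(d))
    if (length(miss)) stop("unknown SNP ids: ",
                           paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    d <- d[, snps, drop = FALSE]
  }
  if (inherits(y, "phenotype_vector")) {
    idx <- match(y$individual_ids, rownames(d))
    if (anyNA(idx)) stop("phenotype ids missing from genotypes", call. = FALSE)
    d <- d[idx, , drop = FALSE]
    yv <- unname(y$values)
  } else {
    stopifnot(length(y) == nrow(d))
    yv <- y
    keep <- !is.na(yv)
    d <- d[keep, , drop = FALSE]
    yv <- yv[keep]
  }
  n <- length(yv)
  if (n == 0L) stop("no individuals in common", call. = FALSE)
  x <- mean_impute(d)
  xc <- sweep(x, 2L, colMeans(x))
  yc <- yv - mean(yv)
  sxx <- colSums(xc^2)
  sxy <- as.numeric(crossprod(xc, yc))
  syy <- sum(yc^2)
  degenerate <- sxx == 0
  beta <- ifelse(degenerate, 0, sxy / ifelse(degenerate, 1, sxx))
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- ifelse(degenerate, Inf, sqrt(rss / (n - 2L) / ifelse(degenerate, 1, sxx)))
  z <- ifelse(degenerate, 0, ifelse(se > 0, beta / se, sign(beta) * Inf))
  p <- ifelse(degenerate, 1,
              pmax(2 * stats::pt(abs(z), df = n - 2L, lower.tail = FALSE),
                   .Machine$double.xmin))
  data.frame(snp_id = colnames(d), beta = beta, se = se, z = z, p = p,
             n = n, degenerate = degenerate, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Per SNP across studies: weights `w_i = 1/se_i^2`,
#' `beta_meta = sum(w_i beta_i) / sum(w_i)`, `se_meta = 1/sqrt(sum(w_i))`.
#' Studies with infinite standard error (degenerate fits) are skipped; a SNP
#' with no finite-se study in any cohort is dropped from the output (an
#' error if nothing remains).
#'
#' @param studies list of per-study data.frames as returned by [gwas()].
#' @return data.frame: `snp_id`, `beta_meta`, `se_meta`, `z_meta`, `p_meta`,
#'   `k_studies`.
#' @export
meta_inverse_variance <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1L)
  all <- do.call(rbind, lapply(studies, function(s) {
    s[, c("snp_id", "beta", "se")]
  }))
  all <- all[is.finite(all$se) & all$se > 0, , drop = FALSE]
  if (!nrow(all)) stop("no study with finite standard error", call. = FALSE)
  w <- 1 / all$se^2
  sw <- tapply(w, all$snp_id, sum)
  swb <- tapply(w * all$beta, all$snp_id, sum)
  k <- tapply(w, all$snp_id, length)
  ids <- names(sw)
  beta <- as.numeric(swb / sw)
  se <- 1 / sqrt(as.numeric(sw))
  z <- beta / se
  out <- data.frame(snp_id = ids, beta_meta = beta, se_meta = se, z_meta = z,
                    p_meta = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                    k_studies = as.integer(k), stringsAsFactors = FALSE,
                    row.names = NULL)
  # preserve the SNP order of the first study where possible
  first <- unique(studies[[1]]$snp_id)
  out[order(match(out$snp_id, first)), , drop = FALSE]
}
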