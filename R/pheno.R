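# Construction of analysis-ready phenotypes: ancestry axes by classical
# multidimensional scaling, a general fluid-ability factor (single-factor ML
# fit with Bartlett scoring), covariate residualisation to standardised
# scores, and the age-corrected IQ-type transform.

# Per-SNP mean imputation of missing dosages (used for distance, LD and
# association computations where complete matrices keep the algebra exact).
mean_impute <- function(d) {
  miss <- is.na(d)
  if (any(miss)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

#' Population-structure axes by classical MDS
#'
#' Classical multidimensional scaling on the allele-sharing distance matrix
#' (1 - identity-by-state proportion, computed from per-SNP mean-imputed
#' dosages).  The leading axes separate subpopulations and are used as
#' ancestry covariates.
#'
#' @param g a [genotype_matrix()], typically post-QC.
#' @param k number of axes (default 4); must be < number of individuals.
#' @return an n-by-k matrix of centred axes (`mds1`..`mdsk`), deterministic
#'   up to sign.
#' @export
compute_structure_axes <- function(g, k = 4L) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages)
  if (k >= n) stop("k must be smaller than the number of individuals",
                   call. = FALSE)
  x <- mean_impute(g$dosages)
  m <- ncol(x)
  # mean |dosage difference| / 2 = 1 - IBS proportion
  d <- stats::dist(x, method = "manhattan") / (2 * m)
  ax <- stats::cmdscale(d, k = k)
  colnames(ax) <- sprintf("mds%d", seq_len(k))
  rownames(ax) <- g$individual_ids
  ax
}

#' First-factor scores of a cognitive test battery
#'
#' Fits a single-factor maximum-likelihood model to the complete-case test
#' scores and returns Bartlett factor scores, the standard scoring for a
#' general-ability factor.  Degenerate designs are handled explicitly: one
#' test column returns that column standardised; two columns (too few for an
#' ML factor model) return the first principal component scores.  Scores are
#' oriented to correlate positively with the battery row means.
#'
#' @param battery data.frame of test scores; an `individual_id` column, if
#'   present, is carried through but not analysed.
#' @return a numeric vector aligned to the rows of `battery` (`NA` for rows
#'   with incomplete test scores).
#' @export
derive_fluid_factor <- function(battery) {
  x <- as.data.frame(battery)
  ids <- x$individual_id
  x$individual_id <- NULL
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("battery needs at least one test column", call. = FALSE)
  cc <- stats::complete.cases(x)
  xc <- x[cc, , drop = FALSE]
  sds <- apply(xc, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance test column: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  scores_cc <- if (ncol(x) == 1L) {
    as.numeric(scale(xc[, 1]))
  } else if (ncol(x) == 2L) {
    stats::prcomp(xc, center = TRUE, scale. = TRUE)$x[, 1]
  } else {
    fit <- stats::factanal(xc, factors = 1L, scores = "Bartlett",
                           rotation = "none")
    as.numeric(fit$scores[, 1])
  }
  if (stats::cor(scores_cc, rowMeans(scale(xc))) < 0) scores_cc <- -scores_cc
  out <- rep(NA_real_, nrow(x))
  out[cc] <- scores_cc
  names(out) <- ids
  out
}

#' Residualise a score on covariates and standardise
#'
#' Ordinary least squares of `y` on the covariates (intercept included
#' implicitly), with listwise deletion of missing rows; the residuals are
#' returned standardised to mean 0, SD 1.  Collinear covariates are an
#' error naming the offending columns, as is (numerically) zero residual
#' variance.
#'
#' @param y numeric scores.
#' @param covariates data.frame or matrix of numeric covariates (an
#'   `individual_id` column is used for labelling, not fitted).
#' @param label phenotype label stored on the result.
#' @param individual_ids optional ids; defaults to
#'   `covariates$individual_id` or positional labels.
#' @return an object of class `phenotype_vector`: list with
#'   `individual_ids`, `values` (standardised residuals for the complete
#'   cases), `label` and `covariates_removed`.
#' @export
residualise <- function(y, covariates, label = "phenotype",
                        individual_ids = NULL) {
  cv <- as.data.frame(covariates)
  if (is.null(individual_ids)) {
    individual_ids <- if (!is.null(cv$individual_id)) cv$individual_id
                      else as.character(seq_along(y))
  }
  cv$individual_id <- NULL
  stopifnot(length(y) == nrow(cv), length(individual_ids) == length(y))
  X <- cbind(`(Intercept)` = 1, as.matrix(cv))
  ok <- stats::complete.cases(y, X)
  if (sum(ok) <= ncol(X)) stop("too few complete cases", call. = FALSE)
  Xo <- X[ok, , drop = FALSE]
  qrX <- qr(Xo)
  if (qrX$rank < ncol(Xo)) {
    dropped <- colnames(Xo)[qrX$pivot[(qrX$rank + 1L):ncol(Xo)]]
    stop("collinear covariates: ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  r <- qr.resid(qrX, y[ok])
  s <- stats::sd(r)
  if (!is.finite(s) || s < sqrt(.Machine$double.eps)) {
    stop("zero residual variance: y is an exact linear function of the ",
         "covariates", call. = FALSE)
  }
  values <- as.numeric((r - mean(r)) / s)
  names(values) <- individual_ids[ok]
  structure(list(individual_ids = individual_ids[ok], values = values,
                 label = label, covariates_removed = colnames(Xo)[-1]),
            class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("<phenotype_vector> %s: n = %d, covariates removed: %s\n",
              x$label, length(x$values),
              if (length(x$covariates_removed))
                paste(x$covariates_removed, collapse = ", ") else "none"))
  invisible(x)
}

#' Age-corrected IQ-type score
#'
#' Residualises a raw test score on age at testing and rescales the
#' residuals to the conventional IQ metric, mean 100 and SD 15.  (For
#' association analysis the result is subsequently residualised on sex and
#' ancestry axes and standardised like the other phenotypes.)
#'
#' @param score raw test scores.
#' @param age age in years at testing; a constant age simply centres the
#'   score (slope 0).
#' @return numeric IQ-type scores (sample mean 100, SD 15), `NA` where
#'   `score` or `age` is missing.
#' @export
age11_iq <- function(score, age) {
  stopifnot(length(score) == length(age))
  ok <- !is.na(score) & !is.na(age)
  s <- score[ok]
  a <- age[ok]
  r <- if (stats::sd(a) == 0) s - mean(s) else stats::lsfit(a, s)$residuals
  sdr <- stats::sd(r)
  if (!is.finite(sdr) || sdr < sqrt(.Machine$double.eps)) {
    stop("zero residual variance after age correction", call. = FALSE)
  }
  out <- rep(NA_real_, length(score))
  out[ok] <- 100 + 15 * (r - mean(r)) / sdr
  out
}
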