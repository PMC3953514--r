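# Genotype quality control: individual call rate, SNP call rate, minor
# allele frequency, and an exact Hardy-Weinberg equilibrium test.

#' QC thresholds
#'
#' Defaults follow common GWAS practice for chip data: SNP call rate > 0.98,
#' MAF > 0.01, exact HWE p > 0.001; individuals are dropped below call rate
#' 0.95.
#'
#' @param snp_call_rate,ind_call_rate,maf_min,hwe_p_min fractions in (0, 1).
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate = 0.98, ind_call_rate = 0.95,
                          maf_min = 0.01, hwe_p_min = 0.001) {
  for (v in c(snp_call_rate, ind_call_rate, maf_min, hwe_p_min)) {
    stop_if_not_prob(v, "qc threshold")
  }
  structure(list(snp_call_rate = snp_call_rate, ind_call_rate = ind_call_rate,
                 maf_min = maf_min, hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test conditioning on the allele counts: the p-value is the summed
#' probability of all heterozygote counts whose conditional probability does
#' not exceed that of the observed count.  Stable at low genotype counts,
#' where the chi-square approximation is not.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return the exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) return(1)
  r <- 2L * min(n_hom_ref, n_hom_alt) + n_het  # rare allele count
  h <- seq.int(r %% 2L, min(r, 2L * n - r), by = 2L)  # feasible het counts
  logp <- h * log(2) + lgamma(n + 1) - lgamma((r - h) / 2 + 1) -
    lgamma(h + 1) - lgamma((2 * n - r - h) / 2 + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, h)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

snp_call_rates <- function(d) 1 - colMeans(is.na(d))
ind_call_rates <- function(d) 1 - rowMeans(is.na(d))

empirical_maf <- function(d) {
  f <- colMeans(d, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

hwe_p_per_snp <- function(d) {
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 2, na.rm = TRUE))
  }, numeric(1))
}

#' Quality-control a genotype matrix
#'
#' Filters in a fixed, logged order: (1) individuals by call rate (dropped
#' below `ind_call_rate`), then on the retained individuals (2) SNPs by call
#' rate (kept strictly above `snp_call_rate`), (3) empirical MAF (kept
#' strictly above `maf_min`), (4) exact HWE (kept when p strictly exceeds
#' `hwe_p_min`).  MAF and HWE are recomputed on the retained individuals.
#' Because removing SNPs changes individual call rates (and vice versa), the
#' sweep is repeated until no further removal occurs, which makes the filter
#' idempotent: a second call removes nothing.
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return a list `genotypes` (filtered matrix) and `report` with data
#'   frames `individuals_removed` (id, call_rate) and `snps_removed`
#'   (snp_id, reason, value).
#' @export
qc_genotypes <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  d <- g$dosages
  if (!nrow(d) || !ncol(d)) stop("empty genotype matrix", call. = FALSE)

  removal_log <- function(ids, reason, value) {
    data.frame(snp_id = ids, reason = rep_len(reason, length(ids)),
               value = unname(value), stringsAsFactors = FALSE)
  }
  ind_removed <- data.frame(individual_id = character(0),
                            call_rate = numeric(0), stringsAsFactors = FALSE)
  removed <- list()

  repeat {
    n_before <- nrow(d) + ncol(d)

    icr <- ind_call_rates(d)
    keep_ind <- icr >= thresholds$ind_call_rate
    if (!any(keep_ind)) stop("all individuals removed by QC", call. = FALSE)
    ind_removed <- rbind(ind_removed,
                         data.frame(individual_id = rownames(d)[!keep_ind],
                                    call_rate = unname(icr[!keep_ind]),
                                    stringsAsFactors = FALSE))
    d <- d[keep_ind, , drop = FALSE]

    scr <- snp_call_rates(d)
    fail <- scr <= thresholds$snp_call_rate
    removed[[length(removed) + 1L]] <-
      removal_log(colnames(d)[fail], "call_rate", scr[fail])
    d <- d[, !fail, drop = FALSE]

    if (ncol(d)) {
      maf <- empirical_maf(d)
      fail <- maf <= thresholds$maf_min
      removed[[length(removed) + 1L]] <-
        removal_log(colnames(d)[fail], "maf", maf[fail])
      d <- d[, !fail, drop = FALSE]
    }
    if (ncol(d)) {
      hp <- hwe_p_per_snp(d)
      fail <- hp <= thresholds$hwe_p_min
      removed[[length(removed) + 1L]] <-
        removal_log(colnames(d)[fail], "hwe", hp[fail])
      d <- d[, !fail, drop = FALSE]
    }
    if (!ncol(d)) stop("all SNPs removed by QC", call. = FALSE)

    if (nrow(d) + ncol(d) == n_before) break
  }

  snps_removed <- do.call(rbind, removed)
  rownames(snps_removed) <- NULL
  keep_snp <- g$snps$snp_id %in% colnames(d)
  out <- genotype_matrix(d, g$snps[keep_snp, ],
                         individual_ids = rownames(d))
  list(genotypes = out,
       report = list(individuals_removed = ind_removed,
                     snps_removed = snps_removed,
                     thresholds = thresholds))
}
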