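# Gene-based association p-values by simulation from a multivariate-normal
# null under LD, and competitive gene-set enrichment via a weighted
# running-sum Kolmogorov-Smirnov statistic with set-membership permutation.

# Cholesky factor with an escalating diagonal ridge: SNP correlation
# matrices estimated from finite samples (or containing duplicated SNPs)
# need not be positive definite.
ridge_chol <- function(s, start = 1e-6, max_tries = 12L) {
  s <- (s + t(s)) / 2
  ridge <- 0
  for (i in seq_len(max_tries)) {
    ch <- tryCatch(chol(s + diag(ridge, nrow(s))), error = function(e) NULL)
    if (!is.null(ch)) {
      attr(ch, "ridge") <- ridge
      return(ch)
    }
    ridge <- if (ridge == 0) start else ridge * 10
  }
  stop("LD matrix could not be ridge-adjusted to positive definite",
       call. = FALSE)
}

#' Gene-based p-value by multivariate-normal simulation
#'
#' The gene statistic is the sum of squared per-SNP z scores.  Its null
#' distribution under LD is simulated by drawing `n_sim` vectors from a
#' zero-mean multivariate normal with covariance equal to the SNP
#' correlation matrix and summing their squares; the empirical p-value is
#' `(1 + #\{sum >= T\}) / (1 + n_sim)`.  With independent SNPs this
#' converges to the chi-square tail with one df per SNP; with perfectly
#' correlated SNPs to the tail of (number of SNPs) times a single
#' chi-square.
#'
#' @param z_scores per-SNP z scores for one gene (finite).
#' @param ld SNP correlation matrix (symmetrised and ridge-adjusted to
#'   positive definite as needed); defaults to the identity.
#' @param n_sim number of simulations (default 10000).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param gene label carried into the result.
#' @return an object of class `gene_stat`: `gene`, `n_snps`, `T_gene`,
#'   `n_sim`, `p_gene`.
#' @export
vegas_gene_p <- function(z_scores, ld = NULL, n_sim = 10000L, seed = NULL,
                         gene = NA_character_) {
  z <- as.numeric(z_scores)
  if (!length(z) || !all(is.finite(z))) {
    stop("z_scores must be finite and non-empty", call. = FALSE)
  }
  k <- length(z)
  if (is.null(ld)) ld <- diag(k)
  ld <- as.matrix(ld)
  if (!all(dim(ld) == k)) {
    stop("ld must be square with dimension length(z_scores)", call. = FALSE)
  }
  T_gene <- sum(z^2)
  ch <- ridge_chol(ld)
  exceed <- with_seed(seed, {
    # chunked so that n_sim up to 1e6 stays within modest memory
    chunk <- max(1L, min(n_sim, as.integer(2e6 / k)))
    done <- 0L
    cnt <- 0L
    while (done < n_sim) {
      b <- min(chunk, n_sim - done)
      draws <- matrix(stats::rnorm(b * k), b, k) %*% ch
      cnt <- cnt + sum(rowSums(draws^2) >= T_gene)
      done <- done + b
    }
    cnt
  })
  structure(list(gene = gene, n_snps = k, T_gene = T_gene,
                 n_sim = as.integer(n_sim),
                 p_gene = (1 + exceed) / (1 + n_sim)),
            class = "gene_stat")
}

#' Gene-based statistics for every mapped gene
#'
#' For each gene with at least one mapped SNP, collects the meta-analysis z
#' scores of its SNPs, estimates the LD matrix as the dosage correlation
#' matrix from the pooled genotypes, and computes the simulation p-value via
#' [vegas_gene_p()].  The simulation count is adaptive: it starts at
#' `n_sim_start` and escalates tenfold (up to `n_sim_max`) while the
#' p-value estimate rests on fewer than 10 exceedances.  Genes with no
#' mapped SNP are skipped with a message.
#'
#' @param meta data.frame from [meta_inverse_variance()] (needs `snp_id`,
#'   `z_meta`).
#' @param map a [map_snps_to_genes()] result (gene windows of the
#'   gene-based mode).
#' @param g pooled [genotype_matrix()] for LD estimation.
#' @param n_sim_start,n_sim_max adaptive simulation bounds.
#' @param seed master seed; each gene gets a deterministic sub-stream.
#' @return data.frame: `gene`, `n_snps`, `T_gene`, `n_sim`, `p_gene`.
#' @export
gene_table <- function(meta, map, g, n_sim_start = 1000L, n_sim_max = 1e6,
                       seed = 1L) {
  stopifnot(inherits(map, "snp_gene_map"))
  if (inherits(g, "cohort")) g <- g$genotypes
  x <- mean_impute(g$dosages)
  genes <- names(map$gene_to_snps)
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    gn <- genes[i]
    ids <- intersect(map$gene_to_snps[[gn]], meta$snp_id)
    ids <- intersect(ids, colnames(x))
    if (!length(ids)) {
      message("gene with zero mapped SNPs skipped: ", gn)
      next
    }
    z <- meta$z_meta[match(ids, meta$snp_id)]
    keep <- is.finite(z)
    ids <- ids[keep]
    z <- z[keep]
    if (!length(ids)) {
      message("gene with zero usable SNPs skipped: ", gn)
      next
    }
    ld <- if (length(ids) == 1L) matrix(1, 1, 1)
          else stats::cor(x[, ids, drop = FALSE])
    n_sim <- as.integer(n_sim_start)
    repeat {
      gs <- vegas_gene_p(z, ld, n_sim = n_sim, seed = stream_seed(seed, gn),
                         gene = gn)
      if (gs$p_gene >= 10 / n_sim || n_sim >= n_sim_max) break
      n_sim <- as.integer(min(n_sim * 10, n_sim_max))
    }
    rows[[i]] <- data.frame(gene = gn, n_snps = gs$n_snps,
                            T_gene = gs$T_gene, n_sim = gs$n_sim,
                            p_gene = gs$p_gene, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene with mapped SNPs", call. = FALSE)
  rownames(out) <- NULL
  out
}

# Running-sum enrichment score for one membership assignment over the
# ranked list: candidate genes add w/sum(w_set), others subtract
# 1/(N_g - m); ES is the maximum-magnitude deviation, signed.
running_es <- function(member, w) {
  n <- length(member)
  m <- sum(member)
  step <- numeric(n)
  step[member] <- w[member] / sum(w[member])
  step[!member] <- -1 / (n - m)
  cs <- cumsum(step)
  cs[which.max(abs(cs))]
}

#' Competitive gene-set enrichment by weighted running-sum K-S statistic
#'
#' Genes are ranked by increasing gene-based p-value (ties broken by gene
#' name, so the ranking is deterministic).  Walking the ranking, candidate
#' genes add `w_g / sum(w over the set)` and non-candidates subtract
#' `1/(N_g - m)`; the enrichment score is the signed maximum-magnitude
#' deviation of this running sum.  The null is formed by redrawing the
#' candidate set uniformly at random (`n_perm` times) over the fixed ranked
#' list; `p_enrich = (1 + #\{ES_perm >= ES_obs\}) / (1 + n_perm)`.
#'
#' @param gene_p data.frame with columns `gene` and `p_gene` (one row per
#'   genome gene).
#' @param candidate character vector of candidate gene names (subset of
#'   `gene_p$gene`, non-empty, smaller than the genome list).
#' @param n_perm number of membership permutations (default 15000).
#' @param seed integer seed.
#' @param weight_scheme `"neglog10"` (w_g = -log10 p_gene, the p-value
#'   weighted statistic) or `"unit"` (classic unweighted K-S walk, kept for
#'   oracle testing).
#' @return an object of class `enrichment_result`: `ES_obs`, `n_perm`,
#'   `p_enrich`, `set_size`, `genome_size`, `weight_scheme`, `ES_perm`.
#' @export
gsea_enrichment <- function(gene_p, candidate, n_perm = 15000L, seed = 1L,
                            weight_scheme = c("neglog10", "unit")) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(all(c("gene", "p_gene") %in% names(gene_p)))
  genes <- gene_p$gene
  if (anyDuplicated(genes)) stop("duplicate genes in gene_p", call. = FALSE)
  miss <- setdiff(candidate, genes)
  if (length(miss)) stop("candidate genes absent from gene_p: ",
                         paste(utils::head(miss, 5), collapse = ", "),
                         call. = FALSE)
  N <- length(genes)
  m <- length(candidate)
  if (m < 1L || m >= N) stop("need 0 < set size < genome size", call. = FALSE)
  ord <- order(gene_p$p_gene, genes)
  ranked <- genes[ord]
  p_ranked <- gene_p$p_gene[ord]
  w <- if (weight_scheme == "neglog10") {
    pmax(-log10(pmax(p_ranked, .Machine$double.xmin)), 1e-12)
  } else {
    rep(1, N)
  }
  member <- ranked %in% candidate
  ES_obs <- running_es(member, w)
  ES_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      mb <- logical(N)
      mb[sample.int(N, m)] <- TRUE
      running_es(mb, w)
    }, numeric(1))
  })
  structure(list(ES_obs = ES_obs, n_perm = as.integer(n_perm),
                 p_enrich = (1 + sum(ES_perm >= ES_obs)) / (1 + n_perm),
                 set_size = m, genome_size = N,
                 weight_scheme = weight_scheme, ES_perm = ES_perm,
                 seed = as.integer(seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> ES = %.4f (%s weights), m = %d of %d genes, p = %.4g (%d perms)\n",
    x$ES_obs, x$weight_scheme, x$set_size, x$genome_size, x$p_enrich,
    x$n_perm))
  invisible(x)
}
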