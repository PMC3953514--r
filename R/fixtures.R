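# Candidate-gene fixture: the 27-gene heterotrimeric G-protein set.
#
# The template records, per gene, the published hg18 start/stop coordinates
# and the number of imputed SNPs mapped to the gene under a +-50 kb window.
# Chromosome assignments follow standard genome annotation for these genes;
# strands are assigned deterministically (the published table lists neither)
# and the fixture is a synthetic stand-in, not a re-distribution of any
# genotype resource.

#' Heterotrimeric G-protein gene template
#'
#' The 27 genes coding for the alpha, beta and gamma subunits of
#' heterotrimeric G proteins, with hg18 gene body coordinates and the number
#' of SNPs mapped to each gene (+-50 kb window, imputed data) in the
#' published multi-cohort replication study this package's pipeline
#' re-implements.
#'
#' @return a data.frame with columns `gene`, `chrom`, `start`, `stop`,
#'   `strand`, `n_snps`.
#' @export
gprotein_gene_table <- function() {
  tab <- data.frame(
    gene = c("GNA11", "GNA12", "GNA13", "GNA14", "GNA15", "GNAI1", "GNAI2",
             "GNAI3", "GNAL", "GNAO1", "GNAQ", "GNAS", "GNAT1", "GNAZ",
             "GNB1", "GNB2", "GNB3", "GNB4", "GNB5", "GNG10", "GNG11",
             "GNG12", "GNG2", "GNG3", "GNG4", "GNG5", "GNG7"),
    chrom = c("19", "7", "17", "9", "19", "7", "3", "1", "18", "16", "9",
              "20", "3", "22", "1", "7", "12", "3", "15", "9", "7", "1",
              "14", "11", "1", "1", "19"),
    start = c(3045407L, 2734266L, 60437294L, 79228367L, 3087190L, 79602075L,
              50248650L, 109892708L, 11679264L, 54782751L, 79525010L,
              56848189L, 50204046L, 21742668L, 1706588L, 100109310L,
              6819635L, 180596569L, 50200414L, 113463681L, 93388951L,
              67939736L, 51396799L, 62231708L, 233777607L, 84736593L,
              2462217L),
    stop = c(3072454L, 2850485L, 60483216L, 79453043L, 3114766L, 79686661L,
             50271790L, 109939975L, 11871919L, 54948857L, 79836012L,
             56919645L, 50208953L, 21797221L, 1812355L, 100114728L,
             6826818L, 180652065L, 50270857L, 113472347L, 93393762L,
             68071730L, 51506268L, 62233246L, 233880677L, 84744850L,
             2653746L),
    n_snps = c(69L, 228L, 54L, 311L, 88L, 186L, 32L, 102L, 258L, 241L,
               271L, 127L, 34L, 138L, 52L, 35L, 72L, 94L, 137L, 130L,
               121L, 239L, 392L, 38L, 148L, 136L, 143L),
    stringsAsFactors = FALSE)
  tab$strand <- c("+", "-")[(seq_len(nrow(tab)) %% 2L) + 1L]
  tab
}

#' Published per-cohort set-test results
#'
#' Sample sizes, candidate-set SNP counts and empirical p-values of the
#' self-contained permutation test in the five cohorts of the published
#' replication study, for fluid ability, crystallised ability and (two
#' cohorts) age-11 IQ.  These printed values are the inputs to the Stouffer
#' meta-analysis step and are bundled so the combination can be reproduced
#' without any external data.
#'
#' @return a data.frame with columns `cohort`, `phenotype`, `n`, `n_snps`,
#'   `p_emp` (`n_snps` is `NA` for the age-11 rows where it equals 468).
#' @export
gprotein_replication_results <- function() {
  rbind(
    data.frame(cohort = c("LBC1921", "LBC1936", "ABC1936", "Newcastle",
                          "Manchester"),
               phenotype = "fluid",
               n = c(505L, 989L, 350L, 754L, 805L),
               n_snps = c(468L, 468L, 470L, 469L, 469L),
               p_emp = c(0.68, 0.76, 0.62, 0.18, 0.20),
               stringsAsFactors = FALSE),
    data.frame(cohort = c("LBC1921", "LBC1936", "ABC1936", "Newcastle",
                          "Manchester"),
               phenotype = "crystallised",
               n = c(515L, 1003L, 420L, 750L, 770L),
               n_snps = c(468L, 468L, 470L, 469L, 469L),
               p_emp = c(0.66, 0.97, 0.63, 0.90, 0.57),
               stringsAsFactors = FALSE),
    data.frame(cohort = c("LBC1921", "LBC1936"),
               phenotype = "age11_iq",
               n = c(464L, 947L),
               n_snps = c(468L, 468L),
               p_emp = c(0.90, 0.70),
               stringsAsFactors = FALSE))
}

# Largest-remainder allocation of `total` SNPs proportional to `weights`.
proportional_counts <- function(weights, total) {
  raw <- total * weights / sum(weights)
  k <- floor(raw)
  rem <- total - sum(k)
  if (rem > 0) {
    bump <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[bump] <- k[bump] + 1
  }
  as.integer(k)
}

# Place `n` SNPs uniformly (distinct positions) inside [lo, hi].
place_snps <- function(gene, n, lo, hi, prefix) {
  lo <- max(1L, lo)
  pos <- sort(sample(seq.int(lo, hi), n))
  data.frame(snp_id = sprintf("%s_%s_%04d", prefix, gene, seq_len(n)),
             pos = pos, gene = gene, stringsAsFactors = FALSE)
}

#' Build the candidate-gene annotation fixture and its SNP panels
#'
#' Produces the 27-gene candidate annotation (plus `n_background`
#' non-overlapping background genes), the candidate gene set, and two SNP
#' panels mirroring the two datasets of the replication design:
#'
#' * `genotyped_panel`: ~`n_candidate_snps` chip-style SNPs over the 24
#'   candidate genes with genotyped coverage (GNB2 and the two smallest
#'   genes are dropped, as in the published set test), placed inside the
#'   2 kb upstream / 500 bp downstream windows, with per-gene counts
#'   proportional to the published template counts.
#' * `imputed_panel`: imputation-style coverage with the template per-gene
#'   SNP counts (scaled by `imputed_scale`) inside +-50 kb windows, for all
#'   27 candidate genes and every background gene.
#'
#' @param n_background number of background genes (>= 0) added for the
#'   competitive enrichment analysis.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param n_candidate_snps total genotyped-panel size (default 470, the
#'   published per-cohort candidate-set size of 468-470).
#' @param imputed_scale multiplier on the template per-gene counts for the
#'   imputed panel (1 reproduces the template; use < 1 for desk-scale runs).
#' @param background_snp_mean mean SNP count per background gene (Poisson,
#'   floored at 2).
#' @return a list with `annotation`, `candidate_set`, `genotyped_panel`,
#'   `imputed_panel`.
#' @export
make_annotation_fixture <- function(n_background = 0L, seed = NULL,
                                    n_candidate_snps = 470L,
                                    imputed_scale = 1,
                                    background_snp_mean = 8) {
  if (n_background < 0) stop("n_background must be >= 0", call. = FALSE)
  tmpl <- gprotein_gene_table()
  with_seed(seed, {
    ann <- tmpl[, c("gene", "chrom", "start", "stop", "strand")]
    if (n_background > 0) {
      chrom <- as.character(rep_len(1:22, n_background))
      slot <- stats::ave(seq_len(n_background), chrom, FUN = seq_along)
      start <- 250000000L + (slot - 1L) * 400000L
      len <- as.integer(round(stats::runif(n_background, 2000, 120000)))
      bg <- data.frame(gene = sprintf("BG%04d", seq_len(n_background)),
                       chrom = chrom, start = start, stop = start + len,
                       strand = sample(c("+", "-"), n_background, replace = TRUE),
                       stringsAsFactors = FALSE)
      ann <- rbind(ann, bg)
    }
    rownames(ann) <- NULL

    # genotyped chip-style panel: 24 covered genes, narrow promoter windows
    dropped <- c("GNB2", "GNAT1", "GNG3")
    cov <- tmpl[!tmpl$gene %in% dropped, ]
    counts <- proportional_counts(cov$n_snps, n_candidate_snps)
    gwin <- gene_window(cov, boundary_up = 2000, boundary_down = 500,
                        strand_aware = TRUE)
    geno_list <- lapply(seq_len(nrow(cov)), function(i) {
      d <- place_snps(cov$gene[i], counts[i], gwin$win_start[i],
                      gwin$win_stop[i], "gt")
      d$chrom <- cov$chrom[i]
      d
    })
    gp <- do.call(rbind, geno_list)
    gp <- gp[order(gp$chrom, gp$pos, gp$snp_id), ]
    genotyped <- snp_panel(gp$snp_id, gp$chrom, gp$pos,
                           maf = stats::runif(nrow(gp), 0.05, 0.45),
                           gene = gp$gene)

    # imputed-style panel: all genes, +-50 kb windows
    iw <- gene_window(ann, symmetric_flank = 50000)
    n_imp <- integer(nrow(ann))
    cand <- match(ann$gene, tmpl$gene)
    is_cand <- !is.na(cand)
    n_imp[is_cand] <- pmax(2L, as.integer(round(tmpl$n_snps[cand[is_cand]] *
                                                  imputed_scale)))
    if (any(!is_cand)) {
      n_imp[!is_cand] <- pmax(2L, stats::rpois(sum(!is_cand),
                                               background_snp_mean))
    }
    imp_list <- lapply(seq_len(nrow(ann)), function(i) {
      d <- place_snps(ann$gene[i], n_imp[i], iw$win_start[i],
                      iw$win_stop[i], "im")
      d$chrom <- ann$chrom[i]
      d
    })
    ip <- do.call(rbind, imp_list)
    ip <- ip[order(ip$chrom, ip$pos, ip$snp_id), ]
    imputed <- snp_panel(ip$snp_id, ip$chrom, ip$pos,
                         maf = stats::runif(nrow(ip), 0.05, 0.45),
                         gene = ip$gene)

    list(annotation = ann, candidate_set = tmpl$gene,
         genotyped_panel = genotyped, imputed_panel = imputed)
  })
}
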