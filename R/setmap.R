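# Positional SNP-to-gene assignment with configurable boundaries.
#
# Two window modes mirror the two analysis arms: a promoter-logic window
# (default 2 kb upstream / 500 bp downstream, strand-aware) for the
# self-contained set test, and a symmetric +-50 kb flank (strand ignored)
# for the gene-based test.  Window endpoints are inclusive on both ends.

#' Compute gene windows
#'
#' For `+` strand genes the window is `[start - boundary_up,
#' stop + boundary_down]`; for `-` strand genes with `strand_aware = TRUE`
#' it is mirrored to `[start - boundary_down, stop + boundary_up]`.  When
#' `symmetric_flank` is given it overrides both boundaries with
#' `[start - flank, stop + flank]` regardless of strand.  Windows are
#' clamped at position 1.
#'
#' @param annotation data.frame with columns `gene`, `chrom`, `start`,
#'   `stop`, `strand` (1-based inclusive coordinates).
#' @param boundary_up upstream boundary in bp (>= 0), default 2000.
#' @param boundary_down downstream boundary in bp (>= 0), default 500.
#' @param strand_aware mirror the boundaries on `-` strand genes.
#' @param symmetric_flank optional symmetric flank in bp (e.g. 50000 for the
#'   gene-based mode); overrides the asymmetric boundaries.
#' @return a data.frame `gene`, `chrom`, `win_start`, `win_stop`.
#' @export
gene_window <- function(annotation, boundary_up = 2000, boundary_down = 500,
                        strand_aware = TRUE, symmetric_flank = NULL) {
  stopifnot(all(c("gene", "chrom", "start", "stop") %in% names(annotation)))
  if (any(annotation$start > annotation$stop)) {
    stop("annotation start must be <= stop", call. = FALSE)
  }
  if (boundary_up < 0 || boundary_down < 0) {
    stop("boundaries must be non-negative", call. = FALSE)
  }
  if (!is.null(symmetric_flank)) {
    if (symmetric_flank < 0) stop("symmetric_flank must be >= 0", call. = FALSE)
    lo <- annotation$start - symmetric_flank
    hi <- annotation$stop + symmetric_flank
  } else {
    minus <- strand_aware & !is.null(annotation$strand) &
      annotation$strand == "-"
    lo <- ifelse(minus, annotation$start - boundary_down,
                 annotation$start - boundary_up)
    hi <- ifelse(minus, annotation$stop + boundary_up,
                 annotation$stop + boundary_down)
  }
  data.frame(gene = annotation$gene, chrom = as.character(annotation$chrom),
             win_start = pmax(1, lo), win_stop = hi,
             stringsAsFactors = FALSE)
}

#' Map SNPs to genes by position
#'
#' A SNP belongs to a gene iff `win_start <= pos <= win_stop` on the same
#' chromosome (both ends inclusive); a SNP may belong to several genes whose
#' windows overlap.  The overlap scan is done with GenomicRanges.
#'
#' @param panel a [snp_panel()] (or data.frame with `snp_id`, `chrom`, `pos`).
#' @param annotation gene annotation data.frame (see [gene_window()]).
#' @inheritParams gene_window
#' @return an object of class `snp_gene_map` with elements `gene_to_snps`
#'   (named list of SNP id vectors, position-ordered), `snp_to_genes`
#'   (named list of gene name vectors), `windows`, and `panel`.
#' @export
map_snps_to_genes <- function(panel, annotation, boundary_up = 2000,
                              boundary_down = 500, strand_aware = TRUE,
                              symmetric_flank = NULL) {
  windows <- gene_window(annotation, boundary_up, boundary_down,
                         strand_aware, symmetric_flank)
  panel <- as.data.frame(panel)
  gr_win <- GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$win_start,
                              end = windows$win_stop))
  gr_snp <- GenomicRanges::GRanges(
    seqnames = as.character(panel$chrom),
    ranges = IRanges::IRanges(start = panel$pos, width = 1L))
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(gr_snp, gr_win, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ord <- order(panel$pos[qh], panel$snp_id[qh])
  gene_to_snps <- split(panel$snp_id[qh][ord],
                        factor(windows$gene[sh][ord], levels = windows$gene))
  gene_to_snps <- lapply(gene_to_snps, as.character)
  snp_to_genes <- split(windows$gene[sh], panel$snp_id[qh])
  structure(list(gene_to_snps = gene_to_snps,
                 snp_to_genes = snp_to_genes,
                 windows = windows,
                 panel = panel[, c("snp_id", "chrom", "pos")]),
            class = "snp_gene_map")
}

#' @export
print.snp_gene_map <- function(x, ...) {
  nz <- sum(lengths(x$gene_to_snps) > 0)
  cat(sprintf("<snp_gene_map> %d genes (%d with SNPs), %d mapped SNPs\n",
              length(x$gene_to_snps), nz, length(x$snp_to_genes)))
  invisible(x)
}

#' Build the deduplicated SNP list of a gene set
#'
#' Takes the union of the mapped SNPs of the named genes, deduplicated (a
#' SNP contained in several member genes enters once) and ordered by
#' chromosome then position.  Gene names absent from the map and member
#' genes contributing zero SNPs are reported via a message (coverage losses
#' are expected, not fatal); an empty union is an error.
#'
#' @param gene_set character vector of gene names.
#' @param map a [map_snps_to_genes()] result.
#' @return character vector of SNP ids with attributes `missing_genes` and
#'   `empty_genes`.
#' @export
build_set_snplist <- function(gene_set, map) {
  stopifnot(inherits(map, "snp_gene_map"))
  known <- gene_set[gene_set %in% names(map$gene_to_snps)]
  missing <- setdiff(gene_set, known)
  if (length(missing)) {
    message("genes not in annotation, skipped: ",
            paste(missing, collapse = ", "))
  }
  per_gene <- map$gene_to_snps[known]
  empty <- known[lengths(per_gene) == 0L]
  if (length(empty)) {
    message("genes contributing zero SNPs: ", paste(empty, collapse = ", "))
  }
  ids <- unique(unlist(per_gene, use.names = FALSE))
  if (!length(ids)) stop("gene set maps to zero SNPs", call. = FALSE)
  i <- match(ids, map$panel$snp_id)
  ids <- ids[order(map$panel$chrom[i], map$panel$pos[i], ids)]
  attr(ids, "missing_genes") <- missing
  attr(ids, "empty_genes") <- empty
  ids
}
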