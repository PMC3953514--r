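# Readers and writers for the plain-text formats the pipeline touches:
# dosage TSV, VCF v4.2 (GT field), covariate/phenotype TSV, annotation TSV
# and GMT gene sets.  All tables are tab-separated; coordinates are 1-based
# inclusive throughout.

#' Write a genotype matrix as dosage TSV
#'
#' Dialect: a header row `snp_id chrom pos ref alt <id1> <id2> ...`, then
#' one row per SNP carrying its metadata and 0/1/2/NA dosages.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.table::data.table(snp_id = g$snps$snp_id, chrom = g$snps$chrom,
                                pos = g$snps$pos, ref = g$snps$ref,
                                alt = g$snps$alt)
  dos <- data.table::as.data.table(t(g$dosages))
  data.table::setnames(dos, g$individual_ids)
  data.table::fwrite(cbind(tab, dos), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Read a dosage TSV
#'
#' Validates that every genotype value is 0, 1, 2 or NA and reports the
#' offending data line on failure; truncated or ragged files raise a parse
#' error rather than being silently accepted.
#'
#' @param path dosage TSV written by [write_dosage_tsv()].
#' @return a [genotype_matrix()] (design `maf` is not part of the on-disk
#'   dialect and comes back as `NA`).
#' @export
read_dosage_tsv <- function(path) {
  # fread downgrades ragged/truncated rows to warnings; both are parse
  # errors here, raised once the reader has finished cleanly
  warns <- character(0)
  dt <- tryCatch(
    withCallingHandlers(
      data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                        fill = FALSE, colClasses = list(character = "chrom")),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop("malformed dosage file: ",
                             conditionMessage(e), call. = FALSE))
  if (length(warns)) {
    stop("malformed dosage file: ", warns[1], call. = FALSE)
  }
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(dt)) || ncol(dt) <= length(need)) {
    stop("malformed dosage file: header must be snp_id, chrom, pos, ref, ",
         "alt followed by individual ids", call. = FALSE)
  }
  ids <- setdiff(names(dt), need)
  dos <- as.matrix(dt[, ids, with = FALSE])
  storage.mode(dos) <- "double"
  bad <- which(!is.na(dos) & !(dos %in% c(0, 1, 2)))
  if (length(bad)) {
    line <- ((bad[1] - 1L) %% nrow(dos)) + 1L
    stop(sprintf("invalid dosage value at data line %d of %s", line, path),
         call. = FALSE)
  }
  panel <- snp_panel(dt$snp_id, dt$chrom, dt$pos, dt$ref, dt$alt)
  genotype_matrix(t(dos), panel, individual_ids = ids)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Diploid GT-only records: dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`,
#' missing -> `./.` (the ALT allele is counted, so dosage is the ALT allele
#' count).
#'
#' @param g a [genotype_matrix()].
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_file <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt <- matrix("./.", nrow(g$dosages), ncol(g$dosages))
  gt[!is.na(g$dosages) & g$dosages == 0] <- "0/0"
  gt[!is.na(g$dosages) & g$dosages == 1] <- "0/1"
  gt[!is.na(g$dosages) & g$dosages == 2] <- "1/1"
  body <- cbind(g$snps$chrom, g$snps$pos, g$snps$snp_id, g$snps$ref,
                g$snps$alt, ".", "PASS", ".", "GT", t(gt))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$individual_ids), collapse = "\t"),
             apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses with `vcfR`; GT genotypes (phased or unphased) are converted to
#' ALT allele counts, `./.` to missing.
#'
#' @param path a VCF file.
#' @return a [genotype_matrix()].
#' @export
read_vcf_file <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF: ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  counts[clean %in% c("0/0")] <- 0
  counts[clean %in% c("0/1", "1/0")] <- 1
  counts[clean %in% c("1/1")] <- 2
  unknown <- !is.na(gt) & is.na(counts) & clean != "./."
  if (any(unknown)) {
    stop("unsupported GT codes in VCF (diploid biallelic expected)",
         call. = FALSE)
  }
  panel <- snp_panel(fix[, "ID"], fix[, "CHROM"], as.integer(fix[, "POS"]),
                     fix[, "REF"], fix[, "ALT"])
  genotype_matrix(t(counts), panel, individual_ids = colnames(gt))
}

#' Write / read a covariate or phenotype table
#'
#' TSV with an `individual_id` column first, then named numeric columns.
#' @param tab data.frame with `individual_id` first.
#' @param path file path.
#' @return `path` / a data.frame.
#' @export
write_covariates_tsv <- function(tab, path) {
  stopifnot(names(tab)[1] == "individual_id")
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates_tsv
#' @export
read_covariates_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = "individual_id"))
  if (names(dt)[1] != "individual_id") {
    stop("covariate table must start with individual_id", call. = FALSE)
  }
  as.data.frame(dt)
}

#' Write / read a gene annotation table
#'
#' TSV with columns `gene`, `chrom`, `start`, `stop`, `strand`; coordinates
#' 1-based inclusive.  `zero_based = TRUE` converts 0-based half-open (BED
#' convention) starts on read.
#'
#' @param annotation,path the table / file path.
#' @param zero_based input uses 0-based half-open starts.
#' @return `path` / a data.frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  data.table::fwrite(annotation[, c("gene", "chrom", "start", "stop",
                                    "strand")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path, zero_based = FALSE) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character =
                                                            c("gene", "chrom"))))
  need <- c("gene", "chrom", "start", "stop", "strand")
  if (!all(need %in% names(dt))) {
    stop("annotation must have columns gene, chrom, start, stop, strand",
         call. = FALSE)
  }
  if (zero_based) dt$start <- dt$start + 1L
  if (any(dt$start > dt$stop)) stop("annotation start > stop", call. = FALSE)
  if (anyDuplicated(dt$gene)) stop("duplicate gene names", call. = FALSE)
  dt
}

#' Read / write GMT gene sets
#'
#' GMT: one set per line -- name, description, then tab-separated gene
#' names.  Reading is delegated to `fgsea::gmtPathways`.
#'
#' @param path GMT file.
#' @param sets named list of character vectors.
#' @param description description field written for each set.
#' @return a named list of character vectors / `path`.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a cohort directory
#'
#' Serialises a [simulate_cohort()] result as plain-text files:
#' `genotypes.tsv` (or `genotypes.vcf`), `covariates.tsv`, `battery.tsv`
#' and `latent.tsv` (synthetic truth, kept for recovery checks).
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @param genotype_format `"dosage-tsv"` or `"vcf"`.
#' @return `dir` / a `cohort`.
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("dosage-tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (genotype_format == "dosage-tsv") {
    write_dosage_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  } else {
    write_vcf_file(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  }
  write_covariates_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_covariates_tsv(cohort$battery, file.path(dir, "battery.tsv"))
  write_covariates_tsv(data.frame(individual_id = cohort$covariates$individual_id,
                                  latent_g = cohort$latent_g,
                                  stringsAsFactors = FALSE),
                       file.path(dir, "latent.tsv"))
  writeLines(cohort$name, file.path(dir, "name.txt"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  gpath_tsv <- file.path(dir, "genotypes.tsv")
  geno <- if (file.exists(gpath_tsv)) read_dosage_tsv(gpath_tsv)
          else read_vcf_file(file.path(dir, "genotypes.vcf"))
  covar <- read_covariates_tsv(file.path(dir, "covariates.tsv"))
  battery <- read_covariates_tsv(file.path(dir, "battery.tsv"))
  latent <- read_covariates_tsv(file.path(dir, "latent.tsv"))
  stopifnot(identical(covar$individual_id, geno$individual_ids),
            identical(battery$individual_id, geno$individual_ids))
  structure(list(name = readLines(file.path(dir, "name.txt"))[1],
                 genotypes = geno, covariates = covar, battery = battery,
                 latent_g = latent$latent_g),
            class = "cohort")
}
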