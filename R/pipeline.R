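# End-to-end orchestration: from a config (YAML file or list) through
# simulation/ingest, QC, phenotype construction, SNP-to-gene mapping, the
# per-cohort permutation set test with Stouffer combination, the per-SNP
# meta-analysed scan with gene-based statistics and competitive enrichment,
# to result tables plus a machine-readable run manifest.

#' Demo pipeline configuration
#'
#' A self-contained configuration running the whole pipeline on synthetic
#' cohorts at desk scale: a reduced candidate panel, a small background
#' gene panel, and modest permutation counts.
#'
#' @param out_dir output directory for result tables.
#' @param seed master seed.
#' @param n_individuals per-cohort sample sizes.
#' @param B set-test permutations.
#' @param n_perm enrichment permutations.
#' @param n_sim_max gene-simulation cap.
#' @return a config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir, seed = 1L,
                        n_individuals = c(120L, 150L, 100L, 130L, 140L),
                        B = 499L, n_perm = 999L, n_sim_max = 1e4) {
  list(simulate = list(n_individuals = n_individuals,
                       n_background = 60L,
                       n_candidate_snps = 150L,
                       imputed_scale = 0.1,
                       ld_rho = 0.2,
                       loadings = c(0.6, 0.7, 0.7, 0.8),
                       structure_shift = 0.02,
                       missing_rate = 0.005),
       qc = list(snp_call_rate = 0.98, ind_call_rate = 0.95,
                 maf_min = 0.01, hwe_p_min = 0.001),
       boundaries = list(boundary_up = 2000, boundary_down = 500,
                         symmetric_flank = 50000),
       B = as.integer(B), n_perm = as.integer(n_perm),
       n_sim_max = n_sim_max, n_mds = 4L,
       seed = as.integer(seed), out_dir = out_dir)
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  # pre-flight validation of any referenced input files
  for (co in config$cohorts) {
    for (f in c(co$genotypes, co$covariates, co$battery)) {
      if (!is.null(f) && !file.exists(f)) {
        stop("input file not found: ", f, call. = FALSE)
      }
    }
  }
  for (f in c(config$annotation, config$gene_sets)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("input file not found: ", f, call. = FALSE)
    }
  }
  config
}

pipeline_phenotypes <- function(cohort, axes, n_mds) {
  covar <- cbind(cohort$covariates[, c("age", "sex")],
                 as.data.frame(axes[, seq_len(n_mds), drop = FALSE]))
  battery <- cohort$battery
  battery$individual_id <- NULL
  fluid_raw <- derive_fluid_factor(battery)
  fluid <- residualise(fluid_raw, covar, label = "fluid",
                       individual_ids = cohort$covariates$individual_id)
  # single vocabulary-style test: last battery column
  cryst <- residualise(battery[[ncol(battery)]], covar,
                       label = "crystallised",
                       individual_ids = cohort$covariates$individual_id)
  iq_raw <- age11_iq(battery[[1L]], cohort$covariates$age)
  age11 <- residualise(iq_raw,
                       covar[, setdiff(names(covar), "age"), drop = FALSE],
                       label = "age11_iq",
                       individual_ids = cohort$covariates$individual_id)
  list(fluid = fluid, crystallised = cryst, age11_iq = age11)
}

#' Run the full pipeline
#'
#' Sequencing: simulate (or load) cohorts; genotype QC; ancestry axes;
#' phenotype construction (fluid factor, crystallised score, age-11 IQ
#' analogue), each residualised on age, sex and the leading MDS axes;
#' SNP-to-gene mapping; per-cohort self-contained set tests with Stouffer
#' combination per phenotype; per-SNP scans meta-analysed across cohorts;
#' gene-based simulation p-values; competitive enrichment of the candidate
#' set.  All outputs are written as TSV plus a JSON manifest recording
#' seeds and thresholds; rerunning an identical config reproduces the
#' tables byte for byte.
#'
#' @param config a config list (see [demo_config()]) or path to a YAML file.
#' @return invisibly, a list with the result tables and the output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  fixture <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    fixture <- make_annotation_fixture(
      n_background = sim$n_background %||% 0L,
      seed = stream_seed(seed, "fixture"),
      n_candidate_snps = sim$n_candidate_snps %||% 470L,
      imputed_scale = sim$imputed_scale %||% 1)
    annotation <- fixture$annotation
    candidate <- fixture$candidate_set
    panel <- validate_snp_panel(rbind(as.data.frame(fixture$genotyped_panel),
                                      as.data.frame(fixture$imputed_panel)))
    ns <- sim$n_individuals
    cohorts <- lapply(seq_along(ns), function(i) {
      nm <- sprintf("cohort%d", i)
      simulate_cohort(cohort_config(
        name = nm, n_individuals = ns[i], panel = panel,
        ld_rho = sim$ld_rho %||% 0.2,
        n_test_battery = length(sim$loadings %||% rep(0.7, 4)),
        loadings = sim$loadings %||% rep(0.7, 4),
        structure_shift = sim$structure_shift %||% 0,
        missing_rate = sim$missing_rate %||% 0,
        seed = stream_seed(seed, nm)))
    })
  } else {
    annotation <- read_annotation_tsv(cfg$annotation)
    candidate <- read_gmt(cfg$gene_sets)[[1L]]
    cohorts <- lapply(cfg$cohorts, function(co) {
      geno <- if (grepl("\\.vcf$", co$genotypes)) read_vcf_file(co$genotypes)
              else read_dosage_tsv(co$genotypes)
      structure(list(name = co$name, genotypes = geno,
                     covariates = read_covariates_tsv(co$covariates),
                     battery = read_covariates_tsv(co$battery),
                     latent_g = NULL),
                class = "cohort")
    })
  }

  n_mds <- cfg$n_mds %||% 4L
  thresholds <- do.call(qc_thresholds, cfg$qc %||% list())

  qc_out <- lapply(cohorts, function(co) qc_genotypes(co$genotypes, thresholds))
  for (i in seq_along(cohorts)) {
    keep <- match(qc_out[[i]]$genotypes$individual_ids,
                  cohorts[[i]]$covariates$individual_id)
    cohorts[[i]]$genotypes <- qc_out[[i]]$genotypes
    cohorts[[i]]$covariates <- cohorts[[i]]$covariates[keep, , drop = FALSE]
    cohorts[[i]]$battery <- cohorts[[i]]$battery[keep, , drop = FALSE]
    cohorts[[i]]$latent_g <- cohorts[[i]]$latent_g[keep]
  }
  phenos <- lapply(cohorts, function(co) {
    axes <- compute_structure_axes(co$genotypes, k = n_mds)
    pipeline_phenotypes(co, axes, n_mds)
  })

  bnd <- cfg$boundaries %||% list()
  # maps built on the union panel retained after QC
  union_panel <- unique(do.call(rbind, lapply(cohorts, function(co)
    as.data.frame(co$genotypes$snps)[, c("snp_id", "chrom", "pos")])))
  map_narrow <- map_snps_to_genes(union_panel, annotation,
                                  boundary_up = bnd$boundary_up %||% 2000,
                                  boundary_down = bnd$boundary_down %||% 500,
                                  strand_aware = TRUE)
  map_wide <- map_snps_to_genes(union_panel, annotation,
                                symmetric_flank = bnd$symmetric_flank %||% 50000)
  set_snps <- build_set_snplist(candidate, map_narrow)

  # self-contained set test per cohort and phenotype, Stouffer per phenotype
  B <- cfg$B %||% 10000L
  phenotype_names <- names(phenos[[1L]])
  settest_results <- lapply(stats::setNames(phenotype_names, phenotype_names),
                            function(ph) {
    lapply(cohorts, function(co) {
      y <- phenos[[match(co$name, vapply(cohorts, `[[`, "", "name"))]][[ph]]
      snps_here <- intersect(set_snps, colnames(co$genotypes$dosages))
      self_contained_test(co$genotypes, y, snps_here, B = B,
                          seed = stream_seed(seed, paste0("settest_", co$name,
                                                          "_", ph)),
                          cohort = co$name)
    })
  })
  settest_tab <- set_test_table(settest_results)
  meta_tab <- do.call(rbind, lapply(phenotype_names, function(ph) {
    res <- settest_results[[ph]]
    ms <- stouffer_meta(vapply(res, `[[`, numeric(1), "p_emp"),
                        vapply(res, `[[`, numeric(1), "n"),
                        cohorts = vapply(res, `[[`, "", "cohort"))
    data.frame(phenotype = ph, k_cohorts = length(res), Z_meta = ms$Z_meta,
               p_meta = ms$p_meta, stringsAsFactors = FALSE)
  }))

  # per-SNP scans (fluid phenotype) -> inverse-variance meta -> gene table
  scans <- lapply(cohorts, function(co) {
    ph <- phenos[[match(co$name, vapply(cohorts, `[[`, "", "name"))]]$fluid
    gwas(co$genotypes, ph)
  })
  meta_assoc <- meta_inverse_variance(scans)
  pooled <- pool_genotypes(cohorts)
  gene_tab <- gene_table(meta_assoc, map_wide, pooled,
                         n_sim_start = 1000L,
                         n_sim_max = cfg$n_sim_max %||% 1e6,
                         seed = stream_seed(seed, "genetest"))
  enrich <- gsea_enrichment(gene_tab[, c("gene", "p_gene")],
                            intersect(candidate, gene_tab$gene),
                            n_perm = cfg$n_perm %||% 15000L,
                            seed = stream_seed(seed, "gsea"))
  enrich_tab <- data.frame(ES_obs = enrich$ES_obs, n_perm = enrich$n_perm,
                           p_enrich = enrich$p_enrich,
                           set_size = enrich$set_size,
                           genome_size = enrich$genome_size,
                           weight_scheme = enrich$weight_scheme)

  paths <- c(settest = file.path(cfg$out_dir, "settest.tsv"),
             meta_settest = file.path(cfg$out_dir, "meta_settest.tsv"),
             meta_assoc = file.path(cfg$out_dir, "meta_assoc.tsv"),
             genes = file.path(cfg$out_dir, "genestats.tsv"),
             gsea = file.path(cfg$out_dir, "gsea.tsv"))
  data.table::fwrite(settest_tab, paths["settest"], sep = "\t", quote = FALSE)
  data.table::fwrite(meta_tab, paths["meta_settest"], sep = "\t", quote = FALSE)
  data.table::fwrite(meta_assoc, paths["meta_assoc"], sep = "\t", quote = FALSE)
  data.table::fwrite(gene_tab, paths["genes"], sep = "\t", quote = FALSE)
  data.table::fwrite(enrich_tab, paths["gsea"], sep = "\t", quote = FALSE)
  manifest <- list(package = "snpsetmeta",
                   version = as.character(utils::packageVersion("snpsetmeta")),
                   seed = seed, B = B, n_perm = cfg$n_perm %||% 15000L,
                   thresholds = unclass(thresholds),
                   n_cohorts = length(cohorts),
                   n_set_snps = length(set_snps))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(settest = settest_tab, meta_settest = meta_tab,
                 meta_assoc = meta_assoc, genes = gene_tab,
                 gsea = enrich_tab, paths = paths,
                 set_snps = set_snps, cohorts = cohorts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stack cohorts into one pooled genotype matrix (shared SNPs only), used
# for LD estimation in the gene-based test.
pool_genotypes <- function(cohorts) {
  gs <- lapply(cohorts, function(co) {
    if (inherits(co, "cohort")) co$genotypes else co
  })
  shared <- Reduce(intersect, lapply(gs, function(g) colnames(g$dosages)))
  if (!length(shared)) stop("no shared SNPs across cohorts", call. = FALSE)
  d <- do.call(rbind, lapply(gs, function(g) g$dosages[, shared, drop = FALSE]))
  snps <- as.data.frame(gs[[1L]]$snps)
  snps <- snps[match(shared, snps$snp_id), , drop = FALSE]
  genotype_matrix(d, snps, individual_ids = rownames(d))
}
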