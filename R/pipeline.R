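#' Pipeline configuration
#'
#' One structured configuration object for the end-to-end run. Every
#' threshold defaults to the cohort-analysis value it implements (variant QC
#' MAF 0.01 and HWE 1e-5; pseudobulk >= 50 cells, >= 1000 counts, >= 30
#' donors; ASCA >= 5 het donors and >= 50 reads in 500 bp windows; caQTL
#' indel margin 200 bp; eQTL +/- 1 Mb; meQTL 10 kb; conjunction FDR 0.1).
#' Unknown keys are rejected.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort.
#' @param ... overrides for the named defaults (see
#'   `names(pipeline_config(cohort))`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), ...) {
  cfg <- list(
    cohort = cohort,
    maf_min = 0.01, hwe_p_min = 1e-5,
    min_cells = 50L, min_counts = 1000L, min_donors = 30L,
    n_geno_pcs = 5L, n_pheno_pcs = 30L,
    asca_window = 500L, min_het_donors = 5L, min_total_reads = 50L,
    meth_min_cpgs = 5L, meth_window = 500L,
    fdr = 0.1, meqtl_p_nominal = 1e-3,
    stages = c("simulate", "genotype_qc", "caqtl", "eqtl", "meqtl", "asca",
               "integrate", "gwas_screen"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full discovery pipeline on a synthetic cohort
#'
#' Chains simulate -> genotype QC -> pseudobulk caQTL/eQTL/meQTL -> ASCA ->
#' integration -> GWAS screen, skipping toggled-off stages. Stage outputs
#' accumulate in the returned list together with a summary of record counts
#' per stage. Integration requires both the caQTL and ASCA stages;
#' disabling either makes integration fail with a dependency error.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-simulated cohort (from [simulate_cohort()]);
#'   when supplied the simulate stage is considered done.
#' @return list of stage outputs plus `summary` (a `data.table` of per-stage
#'   record counts) — see the vignette for a walk-through.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  out <- list()
  counts <- list()
  note <- function(stage, n) {
    counts[[length(counts) + 1L]] <<- data.table(stage = stage, records = n)
  }

  if ("simulate" %in% stages || is.null(cohort)) {
    cohort <- cohort %||% simulate_cohort(config$cohort)
  }
  out$cohort <- cohort
  note("simulate", nrow(cohort$fragments))

  G <- cohort$genotypes
  if ("genotype_qc" %in% stages) {
    G <- filter_variants(G, maf_min = config$maf_min,
                         hwe_p_min = config$hwe_p_min)
    note("genotype_qc", nrow(G$variants))
  }
  out$genotypes <- G
  gpcs <- genotype_pcs(G, k = min(config$n_geno_pcs, length(G$donors) - 2L))

  pb <- NULL
  if (any(c("caqtl", "asca", "integrate") %in% stages)) {
    frag_pk <- merge(cohort$fragments[, .(frag_id, barcode, count, peak_id)],
                     cohort$cell_meta[, .(barcode)], by = "barcode")
    pb <- build_pseudobulk(frag_pk, cohort$cell_meta, cohort$peaks,
                           min_cells = config$min_cells,
                           min_counts = config$min_counts,
                           min_donors = config$min_donors)
  }

  if ("caqtl" %in% stages) {
    ca_list <- lapply(pb, function(M) {
      Mn <- normalize_cpm_log1p(M)
      X <- build_covariates(cohort$covariates, Mn$donors, gpcs,
                            phenotype_pcs(Mn, k = config$n_pheno_pcs,
                                          reserve = 5L + config$n_geno_pcs))
      map_cis_qtl(Mn, G, X)
    })
    out$caqtl <- fdr_correct(rbindlist(ca_list))
    note("caqtl", nrow(out$caqtl))
  }

  if ("eqtl" %in% stages) {
    genes <- cohort$genes
    feats <- data.table(feature_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, end = genes$end, kind = "gene")
    E <- pseudobulk_matrix(cohort$expression$counts, feats, "RNA_all")
    En <- normalize_cpm_log1p(E)
    Xe <- build_covariates(cohort$covariates, En$donors, gpcs,
                           phenotype_pcs(En, k = config$n_pheno_pcs,
                                         reserve = 5L + config$n_geno_pcs))
    out$eqtl <- fdr_correct(map_cis_qtl(En, G, Xe))
    note("eqtl", nrow(out$eqtl))
  }

  if ("meqtl" %in% stages) {
    Mm <- build_methylation_phenotypes(cohort$methylation, cohort$peaks,
                                       min_cpgs = config$meth_min_cpgs,
                                       window = config$meth_window)
    Xm <- build_covariates(cohort$covariates, Mm$donors, gpcs)
    out$meqtl <- fdr_correct(map_cis_qtl(Mm, G, Xm))
    note("meqtl", nrow(out$meqtl))
  }

  if ("asca" %in% stages) {
    vc <- count_alleles_per_variant(cohort$fragments, cohort$alleles, G,
                                    cohort$peaks,
                                    window = config$asca_window)
    # restrict to donor/cell-type combinations that survived pseudobulking
    keep <- rbindlist(c(list(data.table(donor = character(),
                                        cell_type = character())),
                        lapply(pb, function(M) {
                          data.table(donor = M$donors, cell_type = M$cell_type)
                        })))
    vc <- merge(vc, keep, by = c("donor", "cell_type"))
    agg <- aggregate_allelic_counts(vc, G)
    out$asca <- fdr_correct(asca_map(agg,
                                     min_het_donors = config$min_het_donors,
                                     min_total_reads = config$min_total_reads))
    note("asca", nrow(out$asca))
  }

  if ("integrate" %in% stages) {
    if (is.null(out$caqtl) || is.null(out$asca)) {
      stop("integration requires both the caqtl and asca stages to be enabled")
    }
    out$callset <- combined_callset(out$caqtl, out$asca, fdr = config$fdr)
    note("integrate", nrow(out$callset))
    detail <- attr(out$callset, "detail")
    if (nrow(detail) >= 3L) {
      out$concordance <- concordance_stats(detail)
    }
    if (!is.null(out$meqtl) && nrow(out$callset)) {
      out$meqtl_concordance <- meqtl_concordance(
        out$callset, out$meqtl, p_nominal = config$meqtl_p_nominal)
    }
  }

  if ("gwas_screen" %in% stages) {
    leads <- cohort$gwas[is_lead == TRUE & variant_id %in% G$variants$variant_id,
                         variant_id]
    blocks <- rbindlist(lapply(leads, function(l) build_ld_block(l, G)))
    out$ld_blocks <- blocks
    if (!is.null(out$callset)) {
      out$screen <- screen_regions(blocks, G, out$callset,
                                   effects = data.table(),
                                   eqtl = out$eqtl, gwas = cohort$gwas)
      note("gwas_screen", nrow(out$screen$rows))
    }
  }

  out$summary <- rbindlist(counts)
  out
}
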