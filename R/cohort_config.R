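#' Configuration for the synthetic single-cell ATAC cohort
#'
#' Bundles every knob of the synthetic cohort generator: cohort size, genome
#' geometry, linkage-disequilibrium structure (founder haplotypes copied in
#' recombination blocks), peak layout, causal-variant effect sizes on the
#' log-accessibility scale, the coupling of CpG methylation (anti-correlated
#' with accessibility when `methylation_coupling < 0`) and of gene expression
#' to the planted enhancer effects.
#'
#' A causal variant with effect `b` multiplies the fragment rate of the
#' haplotype carrying its ALT allele by `exp(b)`, so the expected ALT-haplotype
#' read proportion in heterozygous donors is `pi = exp(b) / (1 + exp(b))`.
#'
#' @param n_donors number of diploid donors.
#' @param cell_types character vector of cell-type names.
#' @param cells_per_donor mean cells per donor per cell type (negative
#'   binomial across donors, dispersion `cells_dispersion`).
#' @param cells_dispersion negative-binomial size parameter for cell counts.
#' @param genome named integer vector of chromosome lengths in bp.
#' @param n_founder_haplotypes number of founder haplotypes copied (with
#'   block-wise recombination) into the cohort; must be at least 2.
#' @param recombination_block_bp mean length of a founder-copying block;
#'   smaller blocks mean faster LD decay.
#' @param mutation_density variants per kb.
#' @param frac_indel fraction of variants that are short (1-10 bp) indels.
#' @param peak_density consensus peaks per 100 kb.
#' @param peak_width consensus peak width in bp.
#' @param frac_causal_peaks fraction of peaks carrying a causal variant.
#' @param effect_size mean absolute effect `|b|` on the log fragment-rate scale.
#' @param effect_sd standard deviation of `|b|`.
#' @param celltype_sharing probability that a causal effect is shared by all
#'   cell types (otherwise a random proper subset is affected).
#' @param methylation_coupling coupling `kappa <= 0` of CpG methylation to the
#'   donor's mean accessibility effect; negative values reproduce the
#'   accessibility-up / methylation-down relationship.
#' @param expression_coupling coupling `gamma` of a linked gene's
#'   log-expression to the causal dosage effect.
#' @param baseline_rate mean fragments per cell per peak (before effects).
#' @param donor_lognorm_sd log-normal SD of donor-level depth factors.
#' @param fragment_length_mean,fragment_length_sd fragment length distribution
#'   (bp), clipped to `[40, peak_width - 10]`.
#' @param mean_cpg_per_window mean number of CpG sites per 500 bp peak window.
#' @param methylation_baseline baseline methylation fraction at peak CpGs.
#' @param methylation_noise_sd SD of per-window per-donor methylation noise.
#' @param n_genes number of genes in the annotation.
#' @param n_gwas_leads number of designated GWAS lead variants.
#' @param seed integer seed; identical `(config, seed)` pairs reproduce every
#'   output exactly.
#' @return an object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_donors = 20, genome = c(chr1 = 5e5), seed = 1)
#' cfg$n_donors
cohort_config <- function(n_donors = 80L,
                          cell_types = c("Astrocyte", "Microglia", "Oligodendrocyte"),
                          cells_per_donor = 70,
                          cells_dispersion = 15,
                          genome = c(chr1 = 5e6, chr2 = 5e6),
                          n_founder_haplotypes = 12L,
                          recombination_block_bp = 2e4,
                          mutation_density = 5,
                          frac_indel = 0.07,
                          peak_density = 5,
                          peak_width = 500L,
                          frac_causal_peaks = 0.2,
                          effect_size = 1.2,
                          effect_sd = 0.25,
                          celltype_sharing = 0.7,
                          methylation_coupling = -2,
                          expression_coupling = 0.5,
                          baseline_rate = 0.35,
                          donor_lognorm_sd = 0.2,
                          fragment_length_mean = 120,
                          fragment_length_sd = 25,
                          mean_cpg_per_window = 8,
                          methylation_baseline = 0.7,
                          methylation_noise_sd = 0.04,
                          n_genes = NULL,
                          n_gwas_leads = 10L,
                          seed = 1L) {
  cfg <- list(
    n_donors = as.integer(n_donors), cell_types = as.character(cell_types),
    cells_per_donor = cells_per_donor, cells_dispersion = cells_dispersion,
    genome = genome, n_founder_haplotypes = as.integer(n_founder_haplotypes),
    recombination_block_bp = recombination_block_bp,
    mutation_density = mutation_density, frac_indel = frac_indel,
    peak_density = peak_density, peak_width = as.integer(peak_width),
    frac_causal_peaks = frac_causal_peaks,
    effect_size = effect_size, effect_sd = effect_sd,
    celltype_sharing = celltype_sharing,
    methylation_coupling = methylation_coupling,
    expression_coupling = expression_coupling,
    baseline_rate = baseline_rate, donor_lognorm_sd = donor_lognorm_sd,
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    mean_cpg_per_window = mean_cpg_per_window,
    methylation_baseline = methylation_baseline,
    methylation_noise_sd = methylation_noise_sd,
    n_genes = if (is.null(n_genes)) max(10L, as.integer(sum(genome) / 5e4)) else as.integer(n_genes),
    n_gwas_leads = as.integer(n_gwas_leads),
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_donors < 2L) stop("n_donors must be at least 2")
  if (length(cfg$genome) == 0L || any(cfg$genome <= 0)) {
    stop("genome must list at least one chromosome of positive length")
  }
  if (anyDuplicated(names(cfg$genome))) stop("genome chromosome names must be unique")
  if (is.null(names(cfg$genome))) stop("genome chromosomes must be named")
  if (cfg$n_founder_haplotypes < 2L) stop("n_founder_haplotypes must be at least 2")
  if (cfg$frac_causal_peaks < 0 || cfg$frac_causal_peaks > 1) {
    stop("frac_causal_peaks must lie in [0, 1]")
  }
  if (cfg$methylation_coupling > 0) stop("methylation_coupling must be <= 0")
  if (length(cfg$cell_types) < 1L) stop("at least one cell type is required")
  for (f in c("cells_per_donor", "cells_dispersion", "recombination_block_bp",
              "mutation_density", "peak_density", "peak_width", "baseline_rate")) {
    if (cfg[[f]] <= 0) stop(sprintf("%s must be positive", f))
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  donors: %d, cell types: %s\n", x$n_donors,
              paste(x$cell_types, collapse = ", ")))
  cat(sprintf("  genome: %s (%.2f Mb total)\n",
              paste(names(x$genome), collapse = ", "), sum(x$genome) / 1e6))
  cat(sprintf("  variants/kb: %.2f, peaks/100kb: %.1f, causal fraction: %.2f\n",
              x$mutation_density, x$peak_density, x$frac_causal_peaks))
  cat(sprintf("  |b| ~ %.2f (sd %.2f), kappa = %.2f, gamma = %.2f, seed = %d\n",
              x$effect_size, x$effect_sd, x$methylation_coupling,
              x$expression_coupling, x$seed))
  invisible(x)
}
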