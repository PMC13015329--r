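#' Simulate per-donor covariates
#'
#' @param G a `phased_genotypes` object (for donor IDs).
#' @param config a [cohort_config()].
#' @return `data.table` with `donor`, `age`, `sex`, `batch`, `modality`.
#' @export
simulate_covariates <- function(G, config) {
  set.seed(child_seed(config$seed, "covariates"))
  nd <- length(G$donors)
  data.table(donor = G$donors,
             age = round(rnorm(nd, 65, 10)),
             sex = sample(c("F", "M"), nd, replace = TRUE),
             batch = sample(c("biobankA", "biobankB"), nd, replace = TRUE),
             modality = sample(c("snATAC", "multiome"), nd, replace = TRUE,
                               prob = c(0.7, 0.3)))
}

#' Simulate per-donor CpG methylation pileups over peak windows
#'
#' CpG sites are scattered in each peak's summit window; each donor's
#' methylated fraction at causal peaks follows
#' `logistic(logit(m0) + kappa * b * g / 2)` plus noise, so with
#' `kappa < 0` methylation falls as the dosage of the
#' accessibility-increasing allele rises (the haplotype-mean accessibility
#' effect for dosage `g` is `b * g / 2`).
#'
#' @param G a `phased_genotypes` object.
#' @param peaks peak table.
#' @param truth ground-truth table.
#' @param config a [cohort_config()].
#' @return named list (by donor) of pileup `data.table`s (`chrom`, `start`,
#'   `end`, `coverage`, `frac`).
#' @export
simulate_methylation <- function(G, peaks, truth, config) {
  validate_cohort_config(config)
  set.seed(child_seed(config$seed, "methylation"))
  peaks <- as.data.table(peaks)
  w <- 500L
  cpg <- peaks[, {
    n <- max(2L, rpois(1L, config$mean_cpg_per_window))
    off <- sort(sample.int(w - 2L, min(n, w - 2L))) - w %/% 2L
    .(pos0 = summit + off)
  }, by = .(peak_id, chrom)]
  m0 <- qlogis(config$methylation_baseline)
  eff <- setNames(rep(0, nrow(peaks)), peaks$peak_id)
  vi <- match(truth$variant_id, G$variants$variant_id)
  nd <- length(G$donors)
  out <- vector("list", nd)
  names(out) <- G$donors
  # per-peak random baseline shift shared by donors
  peak_shift <- setNames(rnorm(nrow(peaks), 0, 0.3), peaks$peak_id)
  for (d in seq_len(nd)) {
    g <- if (nrow(truth)) G$dosage[d, vi] else numeric()
    shift <- setNames(rep(0, nrow(peaks)), peaks$peak_id)
    if (nrow(truth)) {
      shift[truth$peak_id] <- config$methylation_coupling * truth$b * g / 2
    }
    frac_peak <- plogis(m0 + peak_shift + shift +
                          rnorm(nrow(peaks), 0, config$methylation_noise_sd))
    names(frac_peak) <- peaks$peak_id
    frac <- pmin(1, pmax(0, frac_peak[cpg$peak_id] +
                           rnorm(nrow(cpg), 0, 0.02)))
    out[[d]] <- data.table(chrom = cpg$chrom, start = cpg$pos0,
                           end = cpg$pos0 + 1L,
                           coverage = 1L + rpois(nrow(cpg), 20),
                           frac = round(frac, 4))
  }
  out
}

#' Simulate donor x gene expression counts coupled to enhancer effects
#'
#' Negative-binomial counts whose log-mean shifts by `gamma * b * g` for
#' genes linked to a causal variant (see [plant_causal_variants()]).
#'
#' @param G a `phased_genotypes` object.
#' @param genes gene table from [simulate_genes()].
#' @param truth ground-truth table.
#' @param config a [cohort_config()].
#' @return list with `counts` (donors x genes integer matrix) and `genes`.
#' @export
simulate_expression <- function(G, genes, truth, config) {
  set.seed(child_seed(config$seed, "expression"))
  nd <- length(G$donors)
  ng <- nrow(genes)
  base <- rlnorm(ng, log(200), 0.8)
  shift <- matrix(0, nrow = nd, ncol = ng)
  linked <- truth[!is.na(gene_id)]
  if (nrow(linked)) {
    vi <- match(linked$variant_id, G$variants$variant_id)
    gi <- match(linked$gene_id, genes$gene_id)
    for (i in seq_len(nrow(linked))) {
      shift[, gi[i]] <- shift[, gi[i]] +
        linked$gamma[i] * linked$b[i] * G$dosage[, vi[i]]
    }
  }
  depth <- rlnorm(nd, 0, 0.25)
  mu <- depth * t(t(exp(shift)) * base)
  counts <- matrix(rnbinom(nd * ng, mu = mu, size = 10), nrow = nd,
                   dimnames = list(G$donors, genes$gene_id))
  list(counts = counts, genes = as.data.table(genes))
}

#' Simulate a GWAS summary table with designated lead variants
#'
#' Leads are drawn from the causal variants (falling back to common variants
#' when the cohort is null) and given genome-wide-significant p-values;
#' background variants get uniform p-values.
#'
#' @param G a `phased_genotypes` object.
#' @param truth ground-truth table.
#' @param config a [cohort_config()].
#' @return `data.table` (`variant_id`, `chrom`, `pos` 1-based, `p`,
#'   `is_lead`).
#' @export
simulate_gwas_summary <- function(G, truth, config) {
  set.seed(child_seed(config$seed, "gwas"))
  maf <- pmin(colMeans(G$dosage) / 2, 1 - colMeans(G$dosage) / 2)
  pool <- if (nrow(truth)) truth$variant_id else
    G$variants$variant_id[maf >= 0.1]
  n_lead <- min(config$n_gwas_leads, length(pool))
  leads <- sort(sample(pool, n_lead))
  bg <- sample(setdiff(G$variants$variant_id[maf >= 0.01], leads),
               min(200L, sum(maf >= 0.01) - n_lead))
  ids <- c(leads, bg)
  vi <- match(ids, G$variants$variant_id)
  data.table(variant_id = ids,
             chrom = G$variants$chrom[vi],
             pos = G$variants$pos0[vi] + 1L,
             p = c(10^-runif(n_lead, 8.5, 15), runif(length(bg), 1e-6, 1)),
             is_lead = c(rep(TRUE, n_lead), rep(FALSE, length(bg))))
}

#' Simulate the full cohort in memory
#'
#' Runs every component generator in a fixed order and returns all pieces;
#' [generate_cohort()] serialises them to disk.
#'
#' @param config a [cohort_config()].
#' @param null_cohort when `TRUE`, no causal variants are planted (all
#'   `b = 0`), giving a negative-control cohort.
#' @return list with `config`, `genotypes`, `peaks`, `truth`, `fragments`,
#'   `alleles`, `cell_meta`, `genes`, `expression`, `methylation`, `gwas`,
#'   `covariates`.
#' @export
simulate_cohort <- function(config, null_cohort = FALSE) {
  validate_cohort_config(config)
  sim <- simulate_haplotypes(config)
  peaks <- simulate_peaks(config)
  genes <- simulate_genes(config)
  truth <- plant_causal_variants(sim, peaks, genes, config)
  if (null_cohort) truth <- truth[0]
  G <- genotypes_from_simulation(sim, config)
  fr <- simulate_allelic_fragments(G, peaks, truth, config)
  expr <- simulate_expression(G, genes, truth, config)
  meth <- simulate_methylation(G, peaks, truth, config)
  gwas <- simulate_gwas_summary(G, truth, config)
  cov <- simulate_covariates(G, config)
  list(config = config, genotypes = G, peaks = peaks, truth = truth,
       fragments = fr$fragments, alleles = fr$alleles,
       cell_meta = fr$cell_meta, genes = genes, expression = expr,
       methylation = meth, gwas = gwas, covariates = cov)
}

#' Write the synthetic cohort to disk
#'
#' Serialises a simulated cohort as the standard plain-text formats: phased
#' VCF 4.2 (GT with `|`, PS), narrowPeak (column 10 = summit offset),
#' fragment TSV (chrom, start, end, barcode, count) with an allele
#' annotation sidecar, cell metadata, per-donor bedMethyl-like pileups,
#' donor x gene expression TSV, gene annotation, GWAS summary, covariates,
#' genome FASTA, the ground-truth table, and a YAML manifest listing every
#' file with its record count. On any write failure no manifest is emitted.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @param cohort optional pre-simulated cohort from [simulate_cohort()].
#' @param write_genome write the genome FASTA (needed for model scoring).
#' @return invisible manifest `data.table` (`file`, `records`).
#' @export
generate_cohort <- function(config, out_dir, cohort = NULL,
                            write_genome = TRUE) {
  validate_cohort_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  co <- cohort %||% simulate_cohort(config)
  G <- co$genotypes
  manifest <- list()
  put <- function(file, records) {
    manifest[[length(manifest) + 1L]] <<- data.table(file = file,
                                                     records = records)
  }

  write_phased_vcf(G, file.path(out_dir, "genotypes.vcf"),
                   contigs = config$genome)
  put("genotypes.vcf", nrow(G$variants))

  pk <- co$peaks
  np <- data.table(chrom = pk$chrom, start = pk$start, end = pk$end,
                   name = pk$peak_id, score = 0L, strand = ".",
                   signalValue = 0, pValue = -1, qValue = -1,
                   peak = pk$summit - pk$start)
  fwrite(np, file.path(out_dir, "peaks.narrowPeak"), sep = "\t",
         col.names = FALSE)
  put("peaks.narrowPeak", nrow(np))

  fr <- co$fragments[, .(chrom, start, end, barcode, count)]
  fwrite(fr, file.path(out_dir, "fragments.tsv"), sep = "\t")
  put("fragments.tsv", nrow(fr))

  al <- merge(co$alleles,
              co$fragments[, .(frag_id, chrom, start, end, barcode)],
              by = "frag_id")[, .(chrom, start, end, barcode, variant_id,
                                  allele)]
  fwrite(al, file.path(out_dir, "fragment_alleles.tsv"), sep = "\t")
  put("fragment_alleles.tsv", nrow(al))

  truth_frags <- merge(co$fragments[, .(frag_id, chrom, start, end, barcode,
                                        hap, peak_id)],
                       co$alleles[, .(n_sites = .N), by = frag_id],
                       by = "frag_id", all.x = TRUE)
  fwrite(truth_frags, file.path(out_dir, "truth_fragment_haplotypes.tsv"),
         sep = "\t")
  put("truth_fragment_haplotypes.tsv", nrow(truth_frags))

  fwrite(co$cell_meta, file.path(out_dir, "cell_metadata.tsv"), sep = "\t")
  put("cell_metadata.tsv", nrow(co$cell_meta))

  meth_dir <- file.path(out_dir, "methylation")
  dir.create(meth_dir, showWarnings = FALSE)
  for (d in names(co$methylation)) {
    fwrite(co$methylation[[d]], file.path(meth_dir, paste0(d, ".bedmethyl.tsv")),
           sep = "\t")
  }
  put("methylation/", sum(vapply(co$methylation, nrow, 0L)))

  expr <- data.table(donor = rownames(co$expression$counts),
                     as.data.table(co$expression$counts))
  fwrite(expr, file.path(out_dir, "expression_counts.tsv"), sep = "\t")
  put("expression_counts.tsv", nrow(expr))

  fwrite(co$genes, file.path(out_dir, "genes.tsv"), sep = "\t")
  put("genes.tsv", nrow(co$genes))

  fwrite(co$gwas, file.path(out_dir, "gwas_summary.tsv"), sep = "\t")
  put("gwas_summary.tsv", nrow(co$gwas))

  fwrite(co$covariates, file.path(out_dir, "covariates.tsv"), sep = "\t")
  put("covariates.tsv", nrow(co$covariates))

  fwrite(co$truth, file.path(out_dir, "ground_truth.tsv"), sep = "\t")
  put("ground_truth.tsv", nrow(co$truth))

  if (write_genome) {
    genome <- simulate_genome_sequence(G$variants, co$truth, config)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                                file.path(out_dir, "genome.fa"))
    put("genome.fa", length(genome))
  }

  man <- rbindlist(manifest)
  missing <- man$file[!file.exists(file.path(out_dir, sub("/$", "", man$file)))]
  if (length(missing)) {
    stop("partial write failure, no manifest emitted: ",
         paste(missing, collapse = ", "))
  }
  yaml::write_yaml(list(seed = config$seed,
                        files = lapply(seq_len(nrow(man)), function(i) {
                          list(file = man$file[i], records = man$records[i])
                        })),
                   file.path(out_dir, "manifest.yaml"))
  invisible(man)
}
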