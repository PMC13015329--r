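#' Phased genotype container
#'
#' Internal container tying together donor IDs, the variant table, the two
#' haplotype allele matrices, per-donor phase-set IDs and ALT dosages.
#' Positions are stored 0-based (`pos0`); VCF 1-based coordinates exist only
#' at I/O boundaries.
#'
#' @param donors character vector of donor IDs.
#' @param variants `data.table` with `variant_id`, `chrom`, `pos0`, `ref`,
#'   `alt`, `is_indel`.
#' @param hap1,hap2 donor x variant integer allele matrices (0 = REF, 1 = ALT;
#'   `NA` only for multiallelic placeholders).
#' @param phase_set donor x variant integer matrix of phase-set IDs (`NA` =
#'   unphased).
#' @return object of class `phased_genotypes`.
#' @export
phased_genotypes <- function(donors, variants, hap1, hap2, phase_set) {
  stopifnot(nrow(hap1) == length(donors), ncol(hap1) == nrow(variants),
            all(dim(hap1) == dim(hap2)), all(dim(hap1) == dim(phase_set)))
  variants <- as.data.table(variants)
  if (anyDuplicated(variants[, .(chrom, pos0, ref, alt)])) {
    stop("duplicate (chrom, pos, ref, alt) records in variant table")
  }
  ord <- variants[, order(chrom, pos0)]
  variants <- variants[ord]
  hap1 <- hap1[, ord, drop = FALSE]
  hap2 <- hap2[, ord, drop = FALSE]
  phase_set <- phase_set[, ord, drop = FALSE]
  dimnames(hap1) <- dimnames(hap2) <- dimnames(phase_set) <-
    list(donors, variants$variant_id)
  obj <- list(donors = donors, variants = variants, hap1 = hap1, hap2 = hap2,
              phase_set = phase_set, dosage = hap1 + hap2)
  class(obj) <- "phased_genotypes"
  obj
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf("phased_genotypes: %d donors x %d variants (%d indels)\n",
              length(x$donors), nrow(x$variants), sum(x$variants$is_indel)))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.phased_genotypes <- function(x) c(length(x$donors), nrow(x$variants))

#' Subset a phased genotype matrix
#'
#' @param G a `phased_genotypes` object.
#' @param donors,variants donor IDs / variant IDs (or logical/integer index)
#'   to retain; `NULL` keeps all.
#' @return a `phased_genotypes` object.
#' @export
subset_genotypes <- function(G, donors = NULL, variants = NULL) {
  di <- if (is.null(donors)) seq_along(G$donors) else {
    if (is.character(donors)) match(donors, G$donors)
    else seq_along(G$donors)[donors]
  }
  if (anyNA(di)) stop("unknown donor IDs in subset")
  vi <- if (is.null(variants)) seq_len(nrow(G$variants)) else {
    if (is.character(variants)) match(variants, G$variants$variant_id)
    else seq_len(nrow(G$variants))[variants]
  }
  if (anyNA(vi)) stop("unknown variant IDs in subset")
  phased_genotypes(G$donors[di], G$variants[vi],
                   G$hap1[di, vi, drop = FALSE], G$hap2[di, vi, drop = FALSE],
                   G$phase_set[di, vi, drop = FALSE])
}

#' Convert a haplotype simulation into a phased genotype matrix
#'
#' Donor `i` receives haplotype rows `2i - 1` and `2i`. All variants on a
#' chromosome share one phase set per donor (fully phased cohort); use
#' `frac_unphased` to knock a random subset of heterozygous genotypes back to
#' unphased for testing.
#'
#' @param sim output of [simulate_haplotypes()].
#' @param config the generating [cohort_config()].
#' @param frac_unphased fraction of het genotypes left unphased.
#' @return a `phased_genotypes` object.
#' @export
genotypes_from_simulation <- function(sim, config, frac_unphased = 0) {
  nd <- nrow(sim$haplotypes) / 2L
  donors <- sprintf("D%03d", seq_len(nd))
  hap1 <- sim$haplotypes[2L * seq_len(nd) - 1L, , drop = FALSE]
  hap2 <- sim$haplotypes[2L * seq_len(nd), , drop = FALSE]
  chrom_idx <- as.integer(factor(sim$variants$chrom,
                                 levels = unique(sim$variants$chrom)))
  ps <- matrix(rep(chrom_idx * 1000L, each = nd), nrow = nd)
  if (frac_unphased > 0) {
    set.seed(child_seed(config$seed, "unphase"))
    het <- hap1 != hap2
    knock <- het & matrix(runif(length(ps)) < frac_unphased, nrow = nd)
    ps[knock] <- NA_integer_
  }
  phased_genotypes(donors, sim$variants, hap1, hap2, ps)
}

#' Read a phased multi-sample VCF
#'
#' Decodes GT (phased `a|b` fills both haplotypes; unphased heterozygotes get
#' a missing phase set) and the PS phase-set field. Missing genotypes `./.`
#' are set to homozygous reference, following the cohort-merge convention in
#' which unseen alleles default to REF — note this biases allele frequencies
#' downwards at poorly covered sites. Multiallelic records are kept (alleles
#' `NA`) so that [filter_variants()] can drop them explicitly.
#'
#' @param path VCF file (plain text or gzip).
#' @return a `phased_genotypes` object; multiallelic records carry `NA`
#'   alleles and `n_alleles > 2` in the variant table.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF
  fix <- as.data.table(fixm)
  gt <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  ps <- tryCatch(vcfR::extract.gt(v, element = "PS", as.numeric = TRUE),
                 error = function(e) NULL)
  donors <- colnames(gt)
  nvar <- nrow(fix)
  variants <- data.table(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos0 = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT)
  variants[, n_alleles := 1L + vapply(strsplit(alt, ","), length, 1L)]
  variants[, is_indel := nchar(ref) != nchar(sub(",.*", "", alt)) &
             n_alleles == 2L]
  if (anyDuplicated(variants[, .(chrom, pos0, ref, alt)])) {
    d <- variants[duplicated(variants[, .(chrom, pos0, ref, alt)])][1]
    stop(sprintf("duplicate VCF record at %s:%d %s>%s",
                 d$chrom, d$pos0 + 1L, d$ref, d$alt))
  }
  h1 <- h2 <- matrix(0L, nrow = length(donors), ncol = nvar)
  psm <- matrix(NA_integer_, nrow = length(donors), ncol = nvar)
  gt_t <- t(gt)  # donors x variants
  phased <- !is.na(gt_t) & grepl("|", gt_t, fixed = TRUE)
  # vcfR reports fully missing genotypes as NA regardless of convertNA
  missing <- is.na(gt_t) | gt_t %in% c("./.", ".|.", ".")
  al <- strsplit(ifelse(missing, "0|0", gt_t), "[|/]")
  bad <- !missing & lengths(al) != 2L
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("malformed GT '%s' for donor %s at record %d",
                 gt_t[i], donors[(i - 1L) %% length(donors) + 1L],
                 (i - 1L) %/% length(donors) + 1L))
  }
  a1 <- suppressWarnings(as.integer(vapply(al, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(al, function(x) x[2] %||% NA_character_, "")))
  a1[missing] <- 0L; a2[missing] <- 0L
  if (any(is.na(a1) & !missing) || any(is.na(a2) & !missing)) {
    i <- which((is.na(a1) | is.na(a2)) & !missing)[1]
    stop(sprintf("malformed GT '%s' at record %d", gt_t[i],
                 (i - 1L) %/% length(donors) + 1L))
  }
  h1[] <- a1; h2[] <- a2
  if (!is.null(ps)) psm[] <- as.integer(t(ps))
  # unphased hets have no phase set even if PS was (wrongly) present
  het <- h1 != h2
  psm[het & !phased] <- NA_integer_
  # phased genotypes without an explicit PS get a per-chromosome default
  chrom_idx <- as.integer(factor(variants$chrom, levels = unique(variants$chrom)))
  default_ps <- matrix(rep(chrom_idx * 1000L, each = length(donors)),
                       nrow = length(donors))
  fill <- phased & is.na(psm)
  psm[fill] <- default_ps[fill]
  phased_genotypes(donors, variants, h1, h2, psm)
}

#' Write a phased genotype matrix as VCF 4.2
#'
#' @param G a `phased_genotypes` object.
#' @param path output path.
#' @param contigs optional named vector of chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(G, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ascaqtl synthetic cohort",
           if (!is.null(contigs)) {
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs))
           },
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", G$donors), collapse = "\t"))
  nd <- length(G$donors)
  # GT:PS strings, vectorised over the full donor x variant matrix
  gt <- matrix(paste0(G$hap1, ifelse(is.na(G$phase_set), "/", "|"), G$hap2,
                      ifelse(is.na(G$phase_set), "",
                             paste0(":", G$phase_set))),
               nrow = nd)
  body <- vapply(seq_len(nrow(G$variants)), function(j) {
    v <- G$variants[j]
    paste(c(v$chrom, v$pos0 + 1L, v$variant_id, v$ref, v$alt, ".", "PASS",
            ".", "GT:PS", gt[, j]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Exact conditional Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose probability does not exceed that of the observed
#' configuration (two-sided exact test, plain p, no mid-p correction).
#' Monomorphic sites return `p = 1` by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # modal configuration: p = 1
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(het = h | n, allele counts), up to a shared constant
  lp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Variant quality control
#'
#' Retains biallelic variants with minor allele frequency at least `maf_min`
#' and Hardy-Weinberg exact-test p-value at least `hwe_p_min`; multiallelic
#' records are dropped (not split). MAF and HWE are both computed on the
#' donors present in `G`, so subsetting donors before filtering recomputes
#' both on the analysis subset.
#'
#' @param G a `phased_genotypes` object.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum HWE exact p-value.
#' @param max_alleles maximum allele count (biallelic = 2).
#' @return filtered `phased_genotypes`; empty (with a warning) if nothing
#'   survives.
#' @export
filter_variants <- function(G, maf_min = 0.01, hwe_p_min = 1e-5,
                            max_alleles = 2L) {
  stopifnot(inherits(G, "phased_genotypes"))
  if (nrow(G$variants) == 0L) {
    warning("empty genotype matrix; nothing to filter")
    return(G)
  }
  n_alleles <- G$variants$n_alleles %||% rep(2L, nrow(G$variants))
  biallelic <- n_alleles <= max_alleles & !is.na(colSums(G$dosage))
  af <- colMeans(G$dosage) / 2
  maf <- pmin(af, 1 - af)
  nd <- length(G$donors)
  hwe <- vapply(seq_len(nrow(G$variants)), function(j) {
    if (!biallelic[j]) return(0)
    g <- G$dosage[, j]
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, 0)
  keep <- biallelic & maf >= maf_min & hwe >= hwe_p_min
  if (!any(keep)) {
    warning("no variants survive filtering; returning empty matrix")
  }
  subset_genotypes(G, variants = which(keep))
}

#' Genotype principal components
#'
#' PCA on the column-standardised dosage matrix; scores are centred and each
#' component's sign is fixed by making its largest-magnitude loading positive.
#'
#' @param G a filtered `phased_genotypes` object.
#' @param k number of components (default 5, the usual population-structure
#'   adjustment).
#' @return donors x k score matrix.
#' @export
genotype_pcs <- function(G, k = 5L) {
  stopifnot(inherits(G, "phased_genotypes"))
  if (k >= length(G$donors)) stop("k must be smaller than the number of donors")
  pca_scores(G$dosage, k)
}
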