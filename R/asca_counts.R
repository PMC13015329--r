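#' Count REF/ALT reads per heterozygous variant in peak windows
#'
#' Restricts counting to variants inside the `window`-bp summit-centred peak
#' windows, and to donors heterozygous at the variant (homozygous donors are
#' not allele-informative). Each fragment contributes at most one count to
#' each variant it overlaps; no UMI deduplication is applied (ATAC fragments
#' are the counting unit).
#'
#' @param fragments fragment table with `frag_id`, `chrom`, `start`, `end`,
#'   `barcode`, `donor`, `cell_type`.
#' @param alleles long annotation table (`frag_id`, `variant_id`, `allele`)
#'   recording the allele each fragment carries at each overlapped site.
#' @param G a `phased_genotypes` object.
#' @param peaks peak table with `summit`.
#' @param window summit-centred window width (bp).
#' @return `data.table` with `donor`, `cell_type`, `peak_id`, `variant_id`,
#'   `ref_count`, `alt_count`.
#' @export
count_alleles_per_variant <- function(fragments, alleles, G, peaks,
                                      window = 500L) {
  fragments <- as.data.table(fragments)
  alleles <- as.data.table(alleles)
  vw <- variants_in_peak_windows(G$variants, peaks, window = window)
  ann <- merge(alleles, fragments[, .(frag_id, chrom, start, end, donor,
                                      cell_type)], by = "frag_id")
  # annotations for variants absent from G (e.g. removed by QC) are simply
  # not countable; a variant present in G but outside its fragment's span
  # means corrupt input
  pos <- G$variants$pos0[match(ann$variant_id, G$variants$variant_id)]
  known <- !is.na(pos)
  bad <- which(known & (pos < ann$start | pos >= ann$end))
  if (length(bad)) {
    stop(sprintf("fragment %d annotates variant %s it does not overlap",
                 ann$frag_id[bad[1]], ann$variant_id[bad[1]]))
  }
  ann <- ann[known]
  ann <- merge(ann, vw[, .(variant_id, peak_id)], by = "variant_id",
               allow.cartesian = TRUE)
  if (!nrow(ann)) {
    return(data.table(donor = character(), cell_type = character(),
                      peak_id = character(), variant_id = character(),
                      ref_count = integer(), alt_count = integer()))
  }
  # keep only donor-heterozygous sites
  di <- match(ann$donor, G$donors)
  vi <- match(ann$variant_id, G$variants$variant_id)
  ann <- ann[G$hap1[cbind(di, vi)] != G$hap2[cbind(di, vi)]]
  out <- ann[, .(ref_count = sum(allele == 0L),
                 alt_count = sum(allele == 1L)),
             by = .(donor, cell_type, peak_id, variant_id)]
  setorder(out, peak_id, variant_id, cell_type, donor)
  out[]
}

#' Aggregate allelic counts per peak, oriented on a test variant's haplotypes
#'
#' For one (peak, test variant) pair: every heterozygous helper variant in
#' the peak window that shares the test variant's phase set contributes its
#' counts, oriented onto the test variant's haplotypes — if the helper's ALT
#' allele lies on the same haplotype as the test variant's ALT, helper ALT
#' reads count toward `y`, otherwise helper REF reads do. Helpers in a
#' different or missing phase set are skipped; donors unphased at the test
#' variant are excluded.
#'
#' @param variant_counts output of [count_alleles_per_variant()].
#' @param G a `phased_genotypes` object.
#' @param peak peak ID.
#' @param test_variant variant ID (must lie in the peak window).
#' @return `data.table` with `donor`, `cell_type`, `peak_id`, `variant_id`
#'   (the test variant), `y` (ALT-haplotype reads), `n` (total reads).
#' @export
aggregate_counts_per_peak <- function(variant_counts, G, peak, test_variant) {
  aggregate_allelic_counts(variant_counts[peak_id == peak], G,
                           test_variants = test_variant)
}

#' Vectorised phase-aware aggregation over all (peak, test variant) pairs
#'
#' @param variant_counts output of [count_alleles_per_variant()].
#' @param G a `phased_genotypes` object.
#' @param test_variants optional restriction of test-variant IDs.
#' @return `AllelicCountTable`-style `data.table` (`donor`, `cell_type`,
#'   `peak_id`, `variant_id`, `y`, `n`), one row per heterozygous, phased
#'   donor per (peak, test variant, cell type).
#' @export
aggregate_allelic_counts <- function(variant_counts, G, test_variants = NULL) {
  vc <- as.data.table(variant_counts)
  if (!nrow(vc)) {
    return(data.table(donor = character(), cell_type = character(),
                      peak_id = character(), variant_id = character(),
                      y = integer(), n = integer()))
  }
  tests <- unique(vc[, .(peak_id, test_variant = variant_id)])
  if (!is.null(test_variants)) tests <- tests[test_variant %in% test_variants]
  # all (test variant, helper variant) pairs within a peak window
  pairs <- merge(tests, vc[, .(peak_id, helper = variant_id, donor,
                               cell_type, ref_count, alt_count)],
                 by = "peak_id", allow.cartesian = TRUE)
  di <- match(pairs$donor, G$donors)
  ti <- match(pairs$test_variant, G$variants$variant_id)
  hi <- match(pairs$helper, G$variants$variant_id)
  het_test <- G$hap1[cbind(di, ti)] != G$hap2[cbind(di, ti)]
  ps_test <- G$phase_set[cbind(di, ti)]
  ps_help <- G$phase_set[cbind(di, hi)]
  same_ps <- !is.na(ps_test) & !is.na(ps_help) & ps_test == ps_help
  keep <- het_test & same_ps
  pairs <- pairs[keep]
  if (!nrow(pairs)) {
    return(data.table(donor = character(), cell_type = character(),
                      peak_id = character(), variant_id = character(),
                      y = integer(), n = integer()))
  }
  di <- di[keep]; ti <- ti[keep]; hi <- hi[keep]
  # helper ALT on the same haplotype as the test variant's ALT?
  test_alt_on_h1 <- G$hap1[cbind(di, ti)] == 1L
  helper_alt_on_h1 <- G$hap1[cbind(di, hi)] == 1L
  aligned <- test_alt_on_h1 == helper_alt_on_h1
  pairs[, y_part := ifelse(aligned, alt_count, ref_count)]
  out <- pairs[, .(y = sum(y_part), n = sum(ref_count + alt_count)),
               by = .(donor, cell_type, peak_id, variant_id = test_variant)]
  setorder(out, peak_id, variant_id, cell_type, donor)
  out[]
}
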