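#' Haplotype r-squared between two variants
#'
#' Squared Pearson correlation of the 0/1 allele vectors over the `2N`
#' phased haplotypes — the exact phased LD measure; symmetric and invariant
#' to swapping allele labels at either site.
#'
#' @param hap_a,hap_b 0/1 allele vectors of equal length (>= 4).
#' @return r-squared in `[0, 1]`, or `NA` (with attribute
#'   `monomorphic = TRUE`) when either vector is monomorphic.
#' @export
ld_r2 <- function(hap_a, hap_b) {
  stopifnot(length(hap_a) == length(hap_b), length(hap_a) >= 4L)
  if (var(hap_a) == 0 || var(hap_b) == 0) {
    return(structure(NA_real_, monomorphic = TRUE))
  }
  cor(hap_a, hap_b)^2
}

#' Build an LD proximity region around a GWAS lead variant
#'
#' Candidate partners are the biallelic variants within a 2 Mb window
#' centred on the lead (interpreted as +/- 1 Mb) with minor allele
#' frequency at least `maf_min` and `r2(lead, v) >= r2_pair_min`. The region
#' extends to the furthest partner with `r2 >= r2_edge` on each side of the
#' lead; each side is floored at `min_side` bp, so the smallest region is
#' `2 * min_side = 3000` bp, which is also what a lead with no qualifying
#' partner receives.
#'
#' @param lead lead variant ID (must be present and polymorphic in `G`).
#' @param G a `phased_genotypes` object.
#' @param window total window width in bp (2 Mb).
#' @param r2_pair_min minimum r2 for a variant to count as a partner.
#' @param maf_min partner minor-allele-frequency threshold.
#' @param r2_edge r2 threshold defining the region edges.
#' @param min_side minimum distance from the lead on each side.
#' @return `data.table` row (`lead`, `chrom`, `start`, `end` 0-based
#'   half-open, `left_dist`, `right_dist`, `n_partners`, `max_r2_left`,
#'   `max_r2_right`).
#' @export
build_ld_block <- function(lead, G, window = 2e6, r2_pair_min = 0.05,
                           maf_min = 0.001, r2_edge = 0.6,
                           min_side = 1500L) {
  li <- match(lead, G$variants$variant_id)
  if (is.na(li)) stop("lead variant not found in genotypes")
  lead_hap <- c(G$hap1[, li], G$hap2[, li])
  if (var(lead_hap) == 0) stop("lead variant is monomorphic")
  lv <- G$variants[li]
  n_alleles <- G$variants$n_alleles %||% rep(2L, nrow(G$variants))
  af <- colMeans(G$dosage) / 2
  maf <- pmin(af, 1 - af)
  cand <- which(G$variants$chrom == lv$chrom &
                  abs(G$variants$pos0 - lv$pos0) <= window / 2 &
                  maf >= maf_min & n_alleles <= 2L &
                  seq_len(nrow(G$variants)) != li)
  r2 <- vapply(cand, function(j) {
    v <- ld_r2(lead_hap, c(G$hap1[, j], G$hap2[, j]))
    if (is.na(v)) 0 else v
  }, 0)
  partners <- cand[r2 >= r2_pair_min]
  r2p <- r2[r2 >= r2_pair_min]
  pos <- G$variants$pos0[partners]
  left <- pos < lv$pos0 & r2p >= r2_edge
  right <- pos > lv$pos0 & r2p >= r2_edge
  left_dist <- if (any(left)) lv$pos0 - min(pos[left]) else 0L
  right_dist <- if (any(right)) max(pos[right]) - lv$pos0 else 0L
  left_dist <- max(left_dist, min_side)
  right_dist <- max(right_dist, min_side)
  data.table(lead = lead, chrom = lv$chrom,
             start = lv$pos0 - left_dist,
             end = lv$pos0 + right_dist,
             left_dist = left_dist, right_dist = right_dist,
             n_partners = length(partners),
             max_r2_left = if (any(pos < lv$pos0)) max(r2p[pos < lv$pos0]) else NA_real_,
             max_r2_right = if (any(pos > lv$pos0)) max(r2p[pos > lv$pos0]) else NA_real_)
}

#' Screen LD blocks for regulatory-variant evidence
#'
#' Overlaps the cohort's variants with each block and annotates every hit
#' with callset membership, sequence-model effect, eQTL significance and
#' direct GWAS evidence, then assigns evidence tiers per block:
#' \describe{
#'   \item{callset}{block contains a caQTL-ASCA callset variant}
#'   \item{callset_predicted}{callset variant with |model logFC| > 0.2}
#'   \item{callset_predicted_eqtl}{additionally eQTL q < 0.05}
#'   \item{model_only_0.2 / model_only_0.5}{no callset support but a variant
#'     with |logFC| above the threshold, sub-flagged when its GWAS p-value
#'     is below 5e-8}
#' }
#'
#' @param blocks `data.table` of [build_ld_block()] rows.
#' @param G `phased_genotypes` with the cohort variants.
#' @param callset output of [combined_callset()].
#' @param effects model-effect table (`variant_id`, `cell_type`, `logfc`).
#' @param eqtl eQTL table with `q` (may be empty).
#' @param gwas GWAS summary `data.table` (`variant_id`, `p`), may be empty.
#' @param logfc_mid,logfc_strong model-effect thresholds.
#' @param eqtl_q eQTL significance threshold.
#' @param gwas_p genome-wide significance threshold.
#' @return list with `rows` (one per variant-block hit) and `summary` (one
#'   per block with tier flags).
#' @export
screen_regions <- function(blocks, G, callset, effects, eqtl = NULL,
                           gwas = NULL, logfc_mid = 0.2, logfc_strong = 0.5,
                           eqtl_q = 0.05, gwas_p = 5e-8) {
  blocks <- as.data.table(blocks)
  if (!nrow(blocks)) {
    return(list(rows = data.table(), summary = data.table()))
  }
  if (any(blocks$end <= blocks$start)) stop("malformed block region")
  vv <- G$variants[, .(variant_id, chrom, pos0)]
  setkey(blocks, chrom, start, end)
  rows <- blocks[, .(lead, chrom, start, end)][
    vv, on = .(chrom, start <= pos0, end > pos0), nomatch = NULL,
    .(lead, variant_id, pos0 = i.pos0)]
  if (!nrow(rows)) {
    return(list(rows = rows,
                summary = blocks[, .(lead, n_variants = 0L,
                                     tier_callset = FALSE,
                                     tier_callset_predicted = FALSE,
                                     tier_callset_predicted_eqtl = FALSE,
                                     tier_model_0.2 = FALSE,
                                     tier_model_0.5 = FALSE,
                                     gwas_support = FALSE)]))
  }
  rows[, in_callset := variant_id %in% callset$variant_id]
  eff <- as.data.table(effects)
  best_eff <- if (nrow(eff)) {
    eff[!is.na(logfc), .(model_logfc = logfc[which.max(abs(logfc))]),
        by = variant_id]
  } else data.table(variant_id = character(), model_logfc = numeric())
  rows <- merge(rows, best_eff, by = "variant_id", all.x = TRUE)
  if (!is.null(eqtl) && nrow(eqtl)) {
    eq <- as.data.table(eqtl)[!is.na(q), .(eqtl_q = min(q)), by = variant_id]
    rows <- merge(rows, eq, by = "variant_id", all.x = TRUE)
  } else rows[, eqtl_q := NA_real_]
  if (!is.null(gwas) && nrow(gwas)) {
    gw <- as.data.table(gwas)[, .(variant_id, gwas_p = p)]
    rows <- merge(rows, gw, by = "variant_id", all.x = TRUE)
  } else rows[, gwas_p := NA_real_]
  rows[, `:=`(
    tier_callset = in_callset,
    tier_callset_predicted = in_callset & !is.na(model_logfc) &
      abs(model_logfc) > logfc_mid,
    tier_model_mid = !in_callset & !is.na(model_logfc) &
      abs(model_logfc) > logfc_mid,
    tier_model_strong = !in_callset & !is.na(model_logfc) &
      abs(model_logfc) > logfc_strong)]
  rows[, gwas_sig := !is.na(gwas_p) & gwas_p < ..gwas_p]
  rows[, tier_callset_predicted_eqtl := tier_callset_predicted &
         !is.na(eqtl_q) & eqtl_q < ..eqtl_q]
  summary <- rows[, .(
    n_variants = .N,
    tier_callset = any(tier_callset),
    tier_callset_predicted = any(tier_callset_predicted),
    tier_callset_predicted_eqtl = any(tier_callset_predicted_eqtl),
    tier_model_0.2 = any(tier_model_mid),
    tier_model_0.5 = any(tier_model_strong),
    gwas_support = any(gwas_sig & (tier_model_mid | tier_model_strong))),
    by = lead]
  missing_leads <- setdiff(blocks$lead, summary$lead)
  if (length(missing_leads)) {
    summary <- rbind(summary,
                     data.table(lead = missing_leads, n_variants = 0L,
                                tier_callset = FALSE,
                                tier_callset_predicted = FALSE,
                                tier_callset_predicted_eqtl = FALSE,
                                tier_model_0.2 = FALSE,
                                tier_model_0.5 = FALSE,
                                gwas_support = FALSE))
  }
  list(rows = rows[], summary = summary[order(lead)])
}
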