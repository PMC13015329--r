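#' Combine caQTL and ASCA into the high-confidence callset
#'
#' A (variant, peak) pair enters the callset when it passes `q < fdr` in
#' *both* the caQTL and the ASCA analysis in at least one shared cell type
#' (the strict same-cell-type conjunction). With `any_cell_type = TRUE`,
#' significance may come from different cell types.
#'
#' @param caqtl caQTL table from [map_cis_qtl()] with `q` added by
#'   [fdr_correct()]; peak feature IDs in `feature_id`.
#' @param asca ASCA table from [asca_map()] with `q` added.
#' @param fdr conjunction FDR threshold.
#' @param any_cell_type relax the same-cell-type requirement.
#' @return `data.table` with one row per (variant, peak): `cell_types`
#'   (comma-joined significant cell types), `slope` and `imbalance` from the
#'   most significant shared cell type, and per-cell-type detail in
#'   list-free long form via the `detail` attribute.
#' @export
combined_callset <- function(caqtl, asca, fdr = 0.1, any_cell_type = FALSE) {
  caqtl <- as.data.table(caqtl); asca <- as.data.table(asca)
  if (nrow(caqtl) && !"q" %in% names(caqtl) ||
      nrow(asca) && !"q" %in% names(asca)) {
    stop("inputs must be FDR-corrected over their full combined test sets (missing q)")
  }
  if (!nrow(caqtl) || !nrow(asca)) {
    out <- data.table(variant_id = character(), peak_id = character(),
                      cell_types = character(), slope = numeric(),
                      imbalance = numeric(), q_ca = numeric(),
                      q_as = numeric())
    setattr(out, "detail",
            data.table(variant_id = character(), peak_id = character(),
                       cell_type = character(), slope = numeric(),
                       imbalance = numeric()))
    return(out)
  }
  ca <- caqtl[!is.na(q) & q < fdr,
              .(variant_id, peak_id = feature_id, cell_type, slope,
                p_ca = p, q_ca = q)]
  as_ <- asca[!is.na(q) & q < fdr,
              .(variant_id, peak_id, cell_type, imbalance, p_as = p,
                q_as = q)]
  joined <- if (any_cell_type) {
    j <- merge(unique(ca[, .(variant_id, peak_id)]),
               unique(as_[, .(variant_id, peak_id)]),
               by = c("variant_id", "peak_id"))
    ca_j <- merge(ca, j, by = c("variant_id", "peak_id"))
    as_j <- merge(as_, j, by = c("variant_id", "peak_id"))
    merge(ca_j, as_j, by = c("variant_id", "peak_id"),
          allow.cartesian = TRUE, suffixes = c("", ".as"))
  } else {
    merge(ca, as_, by = c("variant_id", "peak_id", "cell_type"))
  }
  if (!nrow(joined)) {
    out <- data.table(variant_id = character(), peak_id = character(),
                      cell_types = character(), slope = numeric(),
                      imbalance = numeric(), q_ca = numeric(),
                      q_as = numeric())
    setattr(out, "detail", joined)
    return(out)
  }
  ct_col <- if (any_cell_type) "cell_type" else "cell_type"
  out <- joined[order(q_ca)][, .(
    cell_types = paste(sort(unique(get(ct_col))), collapse = ","),
    slope = slope[1], imbalance = imbalance[1],
    q_ca = q_ca[1], q_as = q_as[1]),
    by = .(variant_id, peak_id)]
  setorder(out, peak_id, variant_id)
  setattr(out, "detail", joined)
  out[]
}

#' Cross-assay concordance between caQTL slopes and allelic imbalance
#'
#' Directions are `sign(slope)` for caQTL and `sign(imbalance - 0.5)` for
#' ASCA (both oriented ALT-up); correlations are computed on
#' `(slope, imbalance - 0.5)` pairs. A variant significant in several cell
#' types contributes one pair per cell type.
#'
#' @param pairs `data.table` with `slope` and `imbalance` columns (e.g. the
#'   `detail` attribute of [combined_callset()]).
#' @return list with `pearson`, `spearman`, `frac_same_direction`, `n`.
#' @export
concordance_stats <- function(pairs) {
  pairs <- as.data.table(pairs)
  pairs <- pairs[!is.na(slope) & !is.na(imbalance)]
  if (nrow(pairs) < 3L) stop("need at least 3 (slope, imbalance) pairs")
  x <- pairs$slope
  y <- pairs$imbalance - 0.5
  list(pearson = cor(x, y, method = "pearson"),
       spearman = cor(x, y, method = "spearman"),
       frac_same_direction = mean(sign(x) == sign(y)),
       n = nrow(pairs))
}

#' Distances of top caQTL variants to peak summits
#'
#' For every peak, picks the variant with the smallest caQTL p-value and
#' reports its signed distance to the peak summit, separately for callset
#' peaks and for the background of all tested peaks, plus a rank-sum
#' comparison of the absolute distances.
#'
#' @param callset output of [combined_callset()].
#' @param peaks peak table with `summit`.
#' @param all_tested full caQTL table (`variant_id`, `feature_id`, `p`).
#' @param G `phased_genotypes` (for variant positions).
#' @return list with `callset_dist`, `background_dist` (signed bp) and
#'   `ranksum_p` (one-sided: callset |distance| smaller).
#' @export
summit_distances <- function(callset, peaks, all_tested, G) {
  peaks <- as.data.table(peaks)
  if (!"summit" %in% names(peaks) || anyNA(peaks$summit)) {
    stop("peaks must carry summit positions")
  }
  tested <- as.data.table(all_tested)[!is.na(p)]
  top <- tested[order(p), .SD[1], by = feature_id]
  top[, pos0 := G$variants$pos0[match(variant_id, G$variants$variant_id)]]
  top[, summit := peaks$summit[match(feature_id, peaks$peak_id)]]
  top[, dist := pos0 - summit]
  in_call <- top$feature_id %in% callset$peak_id
  callset_dist <- top$dist[in_call]
  background_dist <- top$dist
  rp <- if (length(callset_dist) >= 3L) {
    suppressWarnings(wilcox.test(abs(callset_dist),
                                 abs(top$dist[!in_call]),
                                 alternative = "less")$p.value)
  } else NA_real_
  list(callset_dist = callset_dist, background_dist = background_dist,
       ranksum_p = rp)
}

#' Cross-cell-type correlation of allelic imbalance
#'
#' Pearson correlation of `imbalance - 0.5` between cell types over the
#' variants quantified (not necessarily significant) in both.
#'
#' @param asca full ASCA table with `variant_id`, `peak_id`, `cell_type`,
#'   `imbalance`.
#' @param min_shared minimum shared quantified variants per pair.
#' @return symmetric correlation matrix with unit diagonal; `NA` where the
#'   overlap is insufficient.
#' @export
crosscelltype_correlation <- function(asca, min_shared = 3L) {
  asca <- as.data.table(asca)[!is.na(imbalance)]
  cts <- sort(unique(asca$cell_type))
  if (length(cts) < 2L) stop("need at least 2 cell types")
  m <- matrix(NA_real_, length(cts), length(cts), dimnames = list(cts, cts))
  diag(m) <- 1
  wide <- dcast(asca, variant_id + peak_id ~ cell_type,
                value.var = "imbalance")
  for (i in seq_along(cts)) for (j in seq_along(cts)) {
    if (j <= i) next
    ok <- complete.cases(wide[[cts[i]]], wide[[cts[j]]])
    if (sum(ok) >= min_shared) {
      r <- cor(wide[[cts[i]]][ok] - 0.5, wide[[cts[j]]][ok] - 0.5)
      m[i, j] <- m[j, i] <- r
    }
  }
  m
}

#' Concordance between meQTL and caQTL slopes
#'
#' Joins callset variants with methylation-QTL rows passing a nominal
#' p-value filter and reports the correlation between the meQTL and caQTL
#' slopes plus the fraction with opposite signs (methylation is expected to
#' move against accessibility).
#'
#' @param callset output of [combined_callset()].
#' @param meqtl meQTL table from [map_cis_qtl()] (features are peak
#'   methylation bins named `<peak_id>_meth`).
#' @param p_nominal nominal meQTL p-value threshold for inclusion.
#' @return list with `joined` (the merged table), `pearson`,
#'   `frac_discordant`, `n`; empty join gives `n = 0` with a warning.
#' @export
meqtl_concordance <- function(callset, meqtl, p_nominal = 1e-3) {
  meqtl <- as.data.table(meqtl)[!is.na(p) & p < p_nominal]
  meqtl[, peak_id := sub("_meth$", "", feature_id)]
  joined <- merge(as.data.table(callset)[, .(variant_id, peak_id, slope)],
                  meqtl[, .(variant_id, peak_id, me_slope = slope,
                            me_p = p)],
                  by = c("variant_id", "peak_id"))
  if (!nrow(joined)) {
    warning("no callset variant passes the meQTL nominal filter")
    return(list(joined = joined, pearson = NA_real_,
                frac_discordant = NA_real_, n = 0L))
  }
  list(joined = joined,
       pearson = if (nrow(joined) >= 3L) cor(joined$slope, joined$me_slope)
                 else NA_real_,
       frac_discordant = mean(sign(joined$slope) != sign(joined$me_slope)),
       n = nrow(joined))
}
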