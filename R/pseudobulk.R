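#' Pseudobulk phenotype container
#'
#' @param values donors x features numeric matrix.
#' @param features `data.table` with `feature_id`, `chrom`, `start`, `end`
#'   and `kind` (one of `"peak"`, `"gene"`, `"methylation"`). Peak features
#'   may also carry `summit`.
#' @param cell_type label of the cell population the matrix was aggregated
#'   over.
#' @param cell_totals optional named vector of cells per donor.
#' @param lib_sizes optional named vector of per-donor count totals.
#' @return object of class `pseudobulk_matrix`.
#' @export
pseudobulk_matrix <- function(values, features, cell_type,
                              cell_totals = NULL, lib_sizes = NULL) {
  features <- as.data.table(features)
  stopifnot(ncol(values) == nrow(features), !is.null(rownames(values)))
  if (anyNA(values)) stop("pseudobulk values must not contain missing entries")
  colnames(values) <- features$feature_id
  obj <- list(values = values, features = features, cell_type = cell_type,
              donors = rownames(values), cell_totals = cell_totals,
              lib_sizes = lib_sizes)
  class(obj) <- "pseudobulk_matrix"
  obj
}

#' @export
print.pseudobulk_matrix <- function(x, ...) {
  cat(sprintf("pseudobulk_matrix [%s]: %d donors x %d %s features\n",
              x$cell_type, nrow(x$values), ncol(x$values),
              x$features$kind[1] %||% "?"))
  invisible(x)
}

#' Build raw pseudobulk count matrices per cell type
#'
#' Sums raw counts over all cells of each donor x cell type combination,
#' then applies the cohort inclusion rules: a donor enters a cell type's
#' matrix only with at least `min_cells` cells and at least `min_counts`
#' summed counts, and a cell type is kept only if at least `min_donors`
#' donors survive.
#'
#' @param fragments fragment table (`barcode`, `peak_id`, `count`) or any
#'   per-cell count table with those columns (`peak_id` is the feature).
#' @param cell_meta `data.table` mapping `barcode` to `donor` and
#'   `cell_type`.
#' @param peaks feature table (`peak_id`, `chrom`, `start`, `end`, optionally
#'   `summit`).
#' @param min_cells minimum cells per donor.
#' @param min_counts minimum summed counts per donor.
#' @param min_donors minimum donors per cell type.
#' @return named list of raw-count `pseudobulk_matrix` objects, one per
#'   surviving cell type (empty list, with a warning, if none survives).
#' @export
build_pseudobulk <- function(fragments, cell_meta, peaks,
                             min_cells = 50L, min_counts = 1000L,
                             min_donors = 30L) {
  fragments <- as.data.table(fragments)
  cell_meta <- as.data.table(cell_meta)
  if (length(setdiff(fragments$barcode, cell_meta$barcode))) {
    stop("fragment barcodes missing from cell metadata")
  }
  peaks <- as.data.table(peaks)
  fr <- merge(fragments[, .(barcode, peak_id, count)],
              cell_meta, by = "barcode")
  n_cells <- cell_meta[, .(cells = .N), by = .(donor, cell_type)]
  totals <- fr[, .(total = sum(count)), by = .(donor, cell_type)]
  qc <- merge(n_cells, totals, by = c("donor", "cell_type"), all.x = TRUE)
  qc[is.na(total), total := 0L]
  qc <- qc[cells >= min_cells & total >= min_counts]
  surviving <- qc[, .N, by = cell_type][N >= min_donors, cell_type]
  if (!length(surviving)) {
    warning("no cell type retains enough donors; returning empty list")
    return(list())
  }
  feats <- data.table(feature_id = peaks$peak_id, chrom = peaks$chrom,
                      start = peaks$start, end = peaks$end, kind = "peak")
  if ("summit" %in% names(peaks)) feats[, summit := peaks$summit]
  out <- list()
  for (ct in surviving) {
    keep <- qc[cell_type == ct]
    sub <- fr[cell_type == ct & donor %in% keep$donor,
              .(count = sum(count)), by = .(donor, peak_id)]
    m <- matrix(0, nrow = nrow(keep), ncol = nrow(peaks),
                dimnames = list(sort(keep$donor), peaks$peak_id))
    sub <- sub[peak_id %in% peaks$peak_id]
    m[cbind(match(sub$donor, rownames(m)),
            match(sub$peak_id, colnames(m)))] <- sub$count
    out[[ct]] <- pseudobulk_matrix(
      m, feats, ct,
      cell_totals = setNames(keep$cells, keep$donor)[rownames(m)],
      lib_sizes = rowSums(m))
  }
  out
}

#' Counts-per-million, log1p normalisation
#'
#' `value = ln(1 + count * 1e6 / library_size)` with the library size taken as
#' the donor's total count over all features. Donors with a zero library are
#' dropped with a warning.
#'
#' @param M a raw-count `pseudobulk_matrix`.
#' @return a normalised `pseudobulk_matrix`.
#' @export
normalize_cpm_log1p <- function(M) {
  stopifnot(inherits(M, "pseudobulk_matrix"))
  if (any(M$values < 0) || any(M$values != round(M$values))) {
    stop("normalisation expects raw non-negative integer counts")
  }
  lib <- rowSums(M$values)
  if (any(lib == 0)) {
    warning(sprintf("dropping %d donor(s) with zero library size",
                    sum(lib == 0)))
  }
  v <- M$values[lib > 0, , drop = FALSE]
  lib <- lib[lib > 0]
  pseudobulk_matrix(log1p(v * 1e6 / lib), M$features, M$cell_type,
                    cell_totals = M$cell_totals[rownames(v)],
                    lib_sizes = lib)
}

#' Phenotype principal components
#'
#' PCA on the donor x feature normalised matrix with the same sign convention
#' as [genotype_pcs()]. The requested component count is capped so that the
#' downstream regression keeps residual degrees of freedom: `k` may not
#' exceed `n_donors - reserve - 3`, where `reserve` counts the other
#' covariate columns. A cap below the request is reported via a message.
#'
#' @param M a normalised `pseudobulk_matrix`.
#' @param k requested number of components (default 30).
#' @param reserve number of non-PC covariate columns to protect.
#' @return donors x k' score matrix (k' <= k after capping).
#' @export
phenotype_pcs <- function(M, k = 30L, reserve = 0L) {
  stopifnot(inherits(M, "pseudobulk_matrix"))
  nd <- nrow(M$values)
  cap <- nd - reserve - 3L
  if (cap < 1L) stop("too few donors to fit any phenotype PC after reserving covariates")
  if (k > cap) {
    message(sprintf("phenotype PCs capped at %d (requested %d) to preserve residual dof",
                    cap, k))
    k <- cap
  }
  k <- min(k, ncol(M$values) - 1L)
  pca_scores(M$values, k)
}

#' Build methylation phenotypes over peak summit windows
#'
#' For each donor, the mean methylation fraction over the CpGs falling in the
#' `window`-bp summit-centred bin of each peak. A bin is kept only if every
#' donor has at least `min_cpgs` informative CpGs in it — bins missing in any
#' donor are dropped entirely.
#'
#' @param pileups named list (by donor) of CpG pileup tables with columns
#'   `chrom`, `start`, `end`, `coverage`, `frac` (methylated fraction).
#' @param peaks peak table with `summit`.
#' @param min_cpgs minimum informative CpGs per bin per donor.
#' @param window bin width centred on the summit.
#' @return a `pseudobulk_matrix` with `kind = "methylation"` and cell type
#'   `"bulk"`; zero features (with a warning) if nothing survives.
#' @export
build_methylation_phenotypes <- function(pileups, peaks, min_cpgs = 5L,
                                         window = 500L) {
  peaks <- as.data.table(peaks)
  bins <- peaks[, .(feature_id = paste0(peak_id, "_meth"), peak_id, chrom,
                    start = summit - window %/% 2L,
                    end = summit + window %/% 2L)]
  donors <- names(pileups)
  stats_list <- lapply(donors, function(d) {
    p <- as.data.table(pileups[[d]])
    setkey(bins, chrom, start, end)
    hits <- bins[p, on = .(chrom, start <= start, end > start),
                 nomatch = NULL,
                 .(feature_id, frac = i.frac)]
    hits[, .(n_cpg = .N, mean_frac = mean(frac)), by = feature_id]
  })
  names(stats_list) <- donors
  counts <- rbindlist(stats_list, idcol = "donor")
  if (!nrow(counts)) {
    warning("no CpGs overlap any peak window")
    return(pseudobulk_matrix(matrix(0, length(donors), 0,
                                    dimnames = list(donors, NULL)),
                             bins[0][, kind := character()], "bulk"))
  }
  ok <- counts[, .(min_n = min(n_cpg), n_donors = .N), by = feature_id][
    min_n >= min_cpgs & n_donors == length(donors), feature_id]
  keep_bins <- bins[feature_id %in% ok]
  if (!nrow(keep_bins)) {
    warning("no methylation bin is informative in all donors")
  }
  m <- matrix(NA_real_, nrow = length(donors), ncol = nrow(keep_bins),
              dimnames = list(donors, keep_bins$feature_id))
  sub <- counts[feature_id %in% ok]
  m[cbind(match(sub$donor, donors),
          match(sub$feature_id, keep_bins$feature_id))] <- sub$mean_frac
  feats <- keep_bins[, .(feature_id, chrom, start, end, kind = "methylation")]
  pseudobulk_matrix(m, feats, "bulk")
}
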