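#' Simulate per-cell ATAC fragments with haplotype-resolved allelic signal
#'
#' For every donor, cell type and peak, fragment counts are drawn per
#' haplotype as Poisson with rate `0.5 * baseline * depth_d * exp(b * a_h)`,
#' where `a_h` is the ALT count of the peak's causal variant on haplotype `h`
#' (cell-type-specific `b`; `b = 0` for non-causal peaks, so both haplotypes
#' are symmetric). Fragments are emitted as intervals inside the peak; each
#' fragment is annotated with the alleles it overlaps at the donor's variant
#' sites, which is the only public trace of its haplotype of origin — the
#' haplotype label itself lives in the returned table as ground truth and is
#' written only to a truth sidecar.
#'
#' @param G a `phased_genotypes` object for the cohort.
#' @param peaks peak table from [simulate_peaks()].
#' @param truth ground truth from [plant_causal_variants()] (may have zero
#'   rows for a null cohort).
#' @param config the generating [cohort_config()].
#' @return list with `fragments` (`frag_id`, `chrom`, `start`, `end`,
#'   `barcode`, `count`, `donor`, `cell_type`, `peak_id`, `hap` — the last
#'   four are ground-truth/bookkeeping columns not written to the public
#'   fragment file), `alleles` (`frag_id`, `variant_id`, `allele`, plus
#'   fragment coordinates for file export) and `cell_meta` (`barcode`,
#'   `donor`, `cell_type`).
#' @export
simulate_allelic_fragments <- function(G, peaks, truth, config) {
  validate_cohort_config(config)
  set.seed(child_seed(config$seed, "fragments"))
  nd <- length(G$donors)
  cts <- config$cell_types
  peaks <- as.data.table(peaks)
  np <- nrow(peaks)

  if (nrow(truth)) {
    miss <- setdiff(truth$variant_id, G$variants$variant_id)
    if (length(miss)) {
      stop("causal variants absent from genotypes: ",
           paste(head(miss, 3), collapse = ", "))
    }
    # causal variants must be observable through overlapping reads
    vw <- variants_in_peak_windows(G$variants, peaks, window = config$peak_width)
    bad <- truth[!paste(variant_id, peak_id) %in%
                   paste(vw$variant_id, vw$peak_id)]
    if (nrow(bad)) {
      stop("causal variant outside its peak window (imbalance unobservable): ",
           bad$variant_id[1])
    }
  }

  # cells per donor x cell type
  n_cells <- matrix(
    pmax(5L, rnbinom(nd * length(cts), mu = config$cells_per_donor,
                     size = config$cells_dispersion)),
    nrow = nd, dimnames = list(G$donors, cts))
  cell_meta <- rbindlist(lapply(cts, function(ct) {
    data.table(donor = rep(G$donors, n_cells[, ct]), cell_type = ct)
  }))
  cell_meta[, barcode := sprintf("%s_%s_c%04d", donor, cell_type,
                                 seq_len(.N)), by = .(donor, cell_type)]

  # donor depth factors with a mild age trend (absorbed by covariates later)
  depth <- rlnorm(nd, 0, config$donor_lognorm_sd)
  base_peak <- rlnorm(np, log(config$baseline_rate), 0.4)
  ct_mult <- matrix(rlnorm(np * length(cts), 0, 0.3), nrow = np,
                    dimnames = list(peaks$peak_id, cts))

  # per-haplotype ALT counts of the causal variant, donors x causal peaks
  b_mat <- matrix(0, nrow = np, ncol = length(cts),
                  dimnames = list(peaks$peak_id, cts))
  a1 <- a2 <- matrix(0L, nrow = nd, ncol = np)
  if (nrow(truth)) {
    pi_idx <- match(truth$peak_id, peaks$peak_id)
    vi_idx <- match(truth$variant_id, G$variants$variant_id)
    for (i in seq_len(nrow(truth))) {
      for (ct in strsplit(truth$cell_types[i], ",")[[1]]) {
        b_mat[pi_idx[i], ct] <- truth$b[i]
      }
      a1[, pi_idx[i]] <- G$hap1[, vi_idx[i]]
      a2[, pi_idx[i]] <- G$hap2[, vi_idx[i]]
    }
  }

  frag_chunks <- vector("list", length(cts) * 2L)
  k <- 0L
  for (ct in cts) {
    lam_base <- outer(depth * n_cells[, ct], base_peak * ct_mult[, ct])
    bct <- matrix(rep(b_mat[, ct], each = nd), nrow = nd)
    for (h in 1:2) {
      ah <- if (h == 1L) a1 else a2
      counts <- matrix(rpois(nd * np, 0.5 * lam_base * exp(bct * ah)),
                       nrow = nd)
      nz <- which(counts > 0L, arr.ind = TRUE)
      if (!nrow(nz)) next
      k <- k + 1L
      frag_chunks[[k]] <- data.table(
        donor_i = nz[, 1L], peak_i = nz[, 2L], hap = h,
        cell_type = ct, nfrag = counts[nz])
    }
  }
  grp <- rbindlist(frag_chunks[seq_len(k)])
  frags <- grp[rep(seq_len(.N), nfrag)]
  frags[, nfrag := NULL]

  # fragment geometry inside the peak
  w <- config$peak_width
  n <- nrow(frags)
  len <- pmin(w - 10L, pmax(40L, as.integer(round(
    rnorm(n, config$fragment_length_mean, config$fragment_length_sd)))))
  off <- as.integer(floor(runif(n) * (w - len + 1L)))
  frags[, `:=`(
    chrom = peaks$chrom[peak_i],
    start = peaks$start[peak_i] + off,
    end = peaks$start[peak_i] + off + len,
    peak_id = peaks$peak_id[peak_i],
    donor = G$donors[donor_i])]
  # assign each fragment to a random cell of its donor/cell type
  nc <- n_cells[cbind(frags$donor_i, match(frags$cell_type, cts))]
  frags[, barcode := sprintf("%s_%s_c%04d", donor, cell_type,
                             as.integer(floor(runif(.N) * nc) + 1L))]
  frags[, `:=`(donor_i = NULL, peak_i = NULL, count = 1L)]
  frags[, frag_id := .I]
  setcolorder(frags, c("frag_id", "chrom", "start", "end", "barcode", "count",
                       "donor", "cell_type", "peak_id", "hap"))

  # allele annotations: which variant sites each fragment overlaps, and the
  # allele carried by its haplotype of origin
  vv <- G$variants[, .(variant_id, chrom, pos0)]
  setkey(vv, chrom, pos0)
  ann <- frags[, .(frag_id, chrom, start, end, donor, hap)]
  ann <- vv[ann, on = .(chrom, pos0 >= start, pos0 < end), nomatch = NULL,
            .(frag_id, variant_id, donor, hap, pos = x.pos0)]
  if (nrow(ann)) {
    di <- match(ann$donor, G$donors)
    vi <- match(ann$variant_id, G$variants$variant_id)
    ann[, allele := ifelse(hap == 1L, G$hap1[cbind(di, vi)],
                           G$hap2[cbind(di, vi)])]
  } else {
    ann[, allele := integer()]
  }
  alleles <- ann[, .(frag_id, variant_id, allele)]

  list(fragments = frags[],
       alleles = alleles[],
       cell_meta = cell_meta[, .(barcode, donor, cell_type)])
}

#' Map variants to summit-centred peak windows
#'
#' @param variants variant table with `chrom`, `pos0`.
#' @param peaks peak table with `summit`.
#' @param window window width in bp, centred on the summit.
#' @return `data.table` of (variant_id, peak_id, pos0, win_start, win_end).
#' @export
variants_in_peak_windows <- function(variants, peaks, window = 500L) {
  pk <- as.data.table(peaks)[, .(peak_id, chrom,
                                 win_start = summit - window %/% 2L,
                                 win_end = summit + window %/% 2L)]
  vv <- as.data.table(variants)[, .(variant_id, chrom, pos0)]
  setkey(pk, chrom, win_start, win_end)
  hits <- pk[vv, on = .(chrom, win_start <= pos0, win_end > pos0),
             nomatch = NULL,
             .(variant_id, peak_id, pos0 = i.pos0)]
  win <- as.data.table(peaks)[, .(peak_id,
                                  win_start = summit - window %/% 2L,
                                  win_end = summit + window %/% 2L)]
  merge(hits, win, by = "peak_id")
}
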