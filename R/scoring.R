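#' Build fixed-length REF and ALT sequences around a peak summit
#'
#' Both sequences are exactly `L` bp, centred on the peak summit, uppercase
#' A/C/G/T/N. SNPs substitute a single base. For a deletion of `k` bp the
#' ALT window recruits `k` extra reference bases split as evenly as possible
#' between the flanks (odd `k`: the extra base downstream); an insertion of
#' `k` bp trims the ALT window symmetrically the same way, so the variant
#' site stays inside both windows.
#'
#' @param peak one peak row (with `chrom` and `summit`).
#' @param variant one variant row (`chrom`, `pos0`, `ref`, `alt`).
#' @param genome named character vector (or `DNAStringSet`-coercible) of
#'   chromosome sequences.
#' @param L model input length (default 2114).
#' @return list with `ref_seq`, `alt_seq` (length-L strings) and
#'   `var_offset_ref` (0-based offset of the variant in the REF window).
#' @export
build_ref_alt_inputs <- function(peak, variant, genome, L = 2114L) {
  chrom <- variant$chrom
  if (!identical(chrom, peak$chrom)) stop("variant and peak on different chromosomes")
  seq_chr <- toupper(as.character(genome[[chrom]]))
  clen <- nchar(seq_chr)
  center <- as.integer(peak$summit)
  s0 <- center - L %/% 2L  # 0-based window start
  if (s0 < 0L || s0 + L > clen) stop("peak window exceeds chromosome bounds")
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  pos <- as.integer(variant$pos0)
  if (pos < s0 || pos + nchar(ref) > s0 + L) {
    stop(sprintf("variant %s at %s:%d lies outside the %d bp summit window",
                 variant$variant_id %||% "?", chrom, pos + 1L, L))
  }
  obs <- substr(seq_chr, pos + 1L, pos + nchar(ref))
  if (obs != ref) {
    stop(sprintf("reference mismatch at %s:%d: FASTA has '%s', variant REF is '%s'",
                 chrom, pos + 1L, obs, ref))
  }
  ref_seq <- substr(seq_chr, s0 + 1L, s0 + L)
  k <- nchar(alt) - nchar(ref)  # >0 insertion, <0 deletion, 0 SNP/MNP
  if (k == 0L) {
    alt_seq <- ref_seq
    off <- pos - s0
    substr(alt_seq, off + 1L, off + nchar(alt)) <- alt
  } else {
    # edit within a buffered context, then re-window with split flanks
    buf <- abs(k) + 4L
    c0 <- max(0L, s0 - buf)
    c1 <- min(clen, s0 + L + buf)
    ctx <- substr(seq_chr, c0 + 1L, c1)
    rel <- pos - c0  # 0-based within ctx
    edited <- paste0(substr(ctx, 1L, rel), alt,
                     substr(ctx, rel + nchar(ref) + 1L, nchar(ctx)))
    if (k < 0L) {       # deletion: recruit |k| extra bases, extra downstream
      left_extra <- abs(k) %/% 2L
    } else {            # insertion: trim k bases, extra trim downstream
      left_extra <- -(k %/% 2L)
    }
    a0 <- (s0 - c0) - left_extra  # 0-based start within edited context
    if (a0 < 0L || a0 + L > nchar(edited)) {
      stop("variant window not achievable near chromosome edge")
    }
    alt_seq <- substr(edited, a0 + 1L, a0 + L)
    var_rel <- rel - a0
    if (var_rel < 0L || var_rel >= L) {
      stop("variant fell outside the adjusted ALT window")
    }
  }
  list(ref_seq = ref_seq, alt_seq = alt_seq, var_offset_ref = pos - s0)
}

#' Toy position-weight-matrix sequence model
#'
#' A deterministic, analytically evaluable stand-in for a trained
#' accessibility model, implementing the sequence-model interface (a pure
#' function of sequence returning one positive scalar per cell type). Each
#' cell type scores the best-window log-odds match of each of its motifs,
#' sums them, and maps the sum through a softplus link scaled per cell type,
#' so outputs are positive and smooth in the match score. `N` bases
#' contribute a zero one-hot column.
#'
#' @param motifs named list (by cell type) of character vectors of consensus
#'   motifs; each is converted to a PWM with `match_prob` on the consensus
#'   base.
#' @param weight,intercept link parameters: output =
#'   `softplus(weight * score + intercept)`.
#' @param match_prob PWM probability of the consensus base.
#' @return object of class `toy_pwm_model`; call [predict_accessibility()]
#'   on sequences.
#' @export
toy_pwm_model <- function(motifs, weight = 1, intercept = 0,
                          match_prob = 0.97) {
  stopifnot(is.list(motifs), length(names(motifs)) == length(motifs))
  pwms <- lapply(motifs, function(ms) lapply(ms, function(m) {
    ch <- strsplit(m, "")[[1]]
    p <- matrix((1 - match_prob) / 3, nrow = 4, ncol = length(ch),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    p[cbind(match(ch, rownames(p)), seq_along(ch))] <- match_prob
    log(p / 0.25)  # log-odds vs uniform background
  }))
  structure(list(pwms = pwms, cell_types = names(motifs), weight = weight,
                 intercept = intercept),
            class = c("toy_pwm_model", "sequence_model"))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# best-window log-odds score of one PWM on a one-hot matrix (4 x L)
best_pwm_score <- function(onehot, pwm) {
  w <- ncol(pwm); L <- ncol(onehot)
  if (L < w) return(-Inf)
  scores <- vapply(seq_len(L - w + 1L), function(s) {
    sum(onehot[, s:(s + w - 1L)] * pwm)
  }, 0)
  max(scores)
}

one_hot <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  m <- matrix(0, nrow = 4, ncol = length(ch),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  hit <- match(ch, rownames(m))
  ok <- !is.na(hit)
  m[cbind(hit[ok], which(ok))] <- 1
  m
}

#' Predict accessibility per cell type with a sequence model
#'
#' @param model a `sequence_model` (e.g. [toy_pwm_model()]).
#' @param seq a single sequence string.
#' @return named numeric vector, one positive scalar per cell type.
#' @export
predict_accessibility <- function(model, seq) {
  UseMethod("predict_accessibility")
}

#' @export
predict_accessibility.toy_pwm_model <- function(model, seq) {
  oh <- one_hot(seq)
  vapply(model$cell_types, function(ct) {
    s <- sum(vapply(model$pwms[[ct]], function(p) best_pwm_score(oh, p), 0))
    softplus(model$weight * s + model$intercept)
  }, 0)
}

#' In-silico mutagenesis effect of one variant
#'
#' Scores the REF and ALT sequences with the model and reports, per cell
#' type, `delta = pred_alt - pred_ref` and
#' `logfc = log2(pred_alt / pred_ref)`. If either prediction is
#' non-positive the log fold-change is `NA` (delta is still reported).
#'
#' @param model a `sequence_model`.
#' @param ref_seq,alt_seq equal-role sequences from
#'   [build_ref_alt_inputs()].
#' @param background optional matrix (peaks x cell types) of background peak
#'   predictions for percentile scores.
#' @return `data.table` with `cell_type`, `delta`, `logfc` and optionally
#'   `percentile` (fraction of background |delta| below this variant's).
#' @export
ism_variant_effect <- function(model, ref_seq, alt_seq, background = NULL) {
  pr <- predict_accessibility(model, ref_seq)
  pa <- predict_accessibility(model, alt_seq)
  lfc <- ifelse(pr > 0 & pa > 0, log2(pa / pr), NA_real_)
  out <- data.table(cell_type = names(pr), pred_ref = unname(pr),
                    pred_alt = unname(pa), delta = unname(pa - pr),
                    logfc = unname(lfc))
  if (!is.null(background)) {
    out[, percentile := vapply(seq_len(.N), function(i) {
      bg <- abs(background[, cell_type[i]])
      mean(bg <= abs(delta[i]))
    }, 0)]
  }
  out[]
}

#' Gene-level variant effect from base-resolution expression predictions
#'
#' Sums predicted coverage over the bins overlapping a gene's exons (a bin
#' counts when its start coordinate lies inside an exon), aggregates cells
#' by cell type, applies `log2(x + 1)`, and reports ALT minus REF per cell
#' type.
#'
#' @param base_pred_ref,base_pred_alt cells x bins matrices of predicted
#'   coverage.
#' @param bin_starts 0-based genomic start of each bin (columns).
#' @param exons `data.table` with `start`, `end` (0-based half-open).
#' @param cell_groups factor/character of length `nrow(base_pred_ref)`
#'   assigning cells to cell types.
#' @return named numeric vector of per-cell-type log2 effects.
#' @export
gene_level_effect <- function(base_pred_ref, base_pred_alt, bin_starts,
                              exons, cell_groups) {
  stopifnot(all(dim(base_pred_ref) == dim(base_pred_alt)),
            length(bin_starts) == ncol(base_pred_ref),
            length(cell_groups) == nrow(base_pred_ref))
  exons <- as.data.table(exons)
  bw <- if (length(bin_starts) > 1L) min(diff(sort(bin_starts))) else 1L
  if (any(exons$start < min(bin_starts)) ||
      any(exons$end > max(bin_starts) + bw)) {
    stop("exon outside the prediction window")
  }
  in_exon <- vapply(bin_starts, function(s) {
    any(s >= exons$start & s < exons$end)
  }, TRUE)
  if (!any(in_exon)) stop("no bin start falls inside an exon")
  groups <- sort(unique(as.character(cell_groups)))
  vapply(groups, function(g) {
    rows <- cell_groups == g
    x_ref <- sum(base_pred_ref[rows, in_exon, drop = FALSE])
    x_alt <- sum(base_pred_alt[rows, in_exon, drop = FALSE])
    log2(x_alt + 1) - log2(x_ref + 1)
  }, 0)
}

#' Score every cohort variant against its overlapping peaks
#'
#' One row per (variant, overlapping peak, cell type); variants overlapping
#' no peak are skipped and tallied. Peak overlap uses the summit-centred
#' window that defines the model input.
#'
#' @param model a `sequence_model`.
#' @param peaks peak table with `summit`.
#' @param variants variant table (`variant_id`, `chrom`, `pos0`, `ref`,
#'   `alt`).
#' @param genome named character vector of chromosome sequences.
#' @param window overlap window width (defaults to the peak width stored in
#'   the table, else 500).
#' @param L model input length.
#' @param background optional background prediction matrix for percentiles.
#' @return list with `effects` (`data.table`: `variant_id`, `peak_id`,
#'   `cell_type`, `delta`, `logfc`) and `tally` (named counts of skipped
#'   variants).
#' @export
score_cohort_variants <- function(model, peaks, variants, genome,
                                  window = 500L, L = 2114L,
                                  background = NULL) {
  peaks <- as.data.table(peaks)
  variants <- as.data.table(variants)
  hits <- variants_in_peak_windows(variants, peaks, window = window)
  tally <- c(no_peak = nrow(variants) - length(unique(hits$variant_id)),
             window_error = 0L)
  if (!nrow(hits)) {
    return(list(effects = data.table(variant_id = character(),
                                     peak_id = character(),
                                     cell_type = character(),
                                     delta = numeric(), logfc = numeric()),
                tally = tally))
  }
  setorder(hits, peak_id, variant_id)
  res <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    pk <- peaks[peak_id == hits$peak_id[i]]
    vv <- variants[variant_id == hits$variant_id[i]]
    eff <- tryCatch({
      io <- build_ref_alt_inputs(pk, vv, genome, L = L)
      e <- ism_variant_effect(model, io$ref_seq, io$alt_seq,
                              background = background)
      e[, `:=`(variant_id = vv$variant_id, peak_id = pk$peak_id)]
      e
    }, error = function(e) NULL)
    if (is.null(eff)) {
      tally["window_error"] <- tally["window_error"] + 1L
    } else {
      res[[i]] <- eff
    }
  }
  effects <- rbindlist(res[!vapply(res, is.null, TRUE)])
  if (nrow(effects)) {
    setcolorder(effects, c("variant_id", "peak_id", "cell_type"))
    setorder(effects, peak_id, variant_id, cell_type)
  }
  list(effects = effects, tally = tally)
}
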