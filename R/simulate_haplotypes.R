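#' Simulate phased haplotypes with block-wise linkage disequilibrium
#'
#' Haplotypes are built by copying from a small pool of founder haplotypes in
#' blocks whose lengths are exponentially distributed around
#' `recombination_block_bp`. Because nearby variants tend to be copied from the
#' same founder, squared allelic correlation (r^2) decays with distance, giving
#' the cohort tunable LD without a coalescent simulator.
#'
#' @param config a [cohort_config()].
#' @return a list with `haplotypes` (a `2 * n_donors` x `n_variants` 0/1
#'   integer matrix, rows ordered donor1-hap1, donor1-hap2, donor2-hap1, ...)
#'   and `variants` (a `data.table` with `variant_id`, `chrom`, `pos0`
#'   (0-based), `ref`, `alt`, `is_indel`).
#' @export
simulate_haplotypes <- function(config) {
  validate_cohort_config(config)
  set.seed(child_seed(config$seed, "haplotypes"))
  variants <- sample_variant_sites(config)
  nv <- nrow(variants)
  nf <- config$n_founder_haplotypes
  # U-shaped founder allele-frequency spectrum
  p <- rbeta(nv, 0.6, 0.6)
  founders <- matrix(rbinom(nf * nv, 1L, rep(p, each = nf)), nrow = nf)
  nh <- 2L * config$n_donors
  haps <- matrix(0L, nrow = nh, ncol = nv)
  for (ch in names(config$genome)) {
    idx <- which(variants$chrom == ch)
    if (!length(idx)) next
    pos <- variants$pos0[idx]
    len <- config$genome[[ch]]
    for (h in seq_len(nh)) {
      # breakpoints of founder-copying blocks along this chromosome
      n_br <- rpois(1L, len / config$recombination_block_bp)
      brk <- sort(runif(n_br, 0, len))
      fid <- sample.int(nf, n_br + 1L, replace = TRUE)
      haps[h, idx] <- founders[cbind(fid[findInterval(pos, brk) + 1L],
                                     idx)]
    }
  }
  list(haplotypes = haps, variants = variants, founder_freq = p)
}

# Variant sites with a minimum gap so indel REF spans and embedded motifs
# never collide with a neighbouring site.
sample_variant_sites <- function(config, min_gap = 16L) {
  bases <- c("A", "C", "G", "T")
  out <- vector("list", length(config$genome))
  for (i in seq_along(config$genome)) {
    ch <- names(config$genome)[i]
    len <- config$genome[[i]]
    n <- max(2L, round(config$mutation_density * len / 1000))
    # rejection-free spacing: sample gaps, rescale to chromosome length
    gaps <- rexp(n, 1)
    pos <- round(cumsum(gaps) / sum(gaps) * (len - 4000L)) + 2000L
    pos <- pos[!duplicated(pos)]
    keep <- c(TRUE, diff(pos) >= min_gap)
    pos <- pos[keep]
    n <- length(pos)
    is_indel <- runif(n) < config$frac_indel
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    k <- pmin(10L, 1L + rpois(sum(is_indel), 2L))
    if (sum(is_indel)) {
      del <- runif(sum(is_indel)) < 0.5
      ins_seq <- vapply(k, function(m) {
        paste(sample(bases, m, replace = TRUE), collapse = "")
      }, "")
      ref_i <- ref[is_indel]
      alt_i <- ifelse(del, ref_i, paste0(ref_i, ins_seq))
      ref_i <- ifelse(del, paste0(ref_i, ins_seq), ref_i)
      ref[is_indel] <- ref_i
      alt[is_indel] <- alt_i
    }
    out[[i]] <- data.table(chrom = ch, pos0 = as.integer(pos),
                           ref = ref, alt = alt, is_indel = is_indel)
  }
  v <- rbindlist(out)
  setorder(v, chrom, pos0)
  v[, variant_id := sprintf("v%06d", .I)]
  setcolorder(v, "variant_id")
  v[]
}

#' Lay out consensus peaks along the synthetic genome
#'
#' Fixed-width peaks (narrowPeak-like) spaced according to `peak_density`,
#' each with a summit offset drawn away from the peak edges.
#'
#' @param config a [cohort_config()].
#' @return `data.table` with `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `summit` (absolute 0-based position).
#' @export
simulate_peaks <- function(config) {
  validate_cohort_config(config)
  set.seed(child_seed(config$seed, "peaks"))
  w <- config$peak_width
  out <- vector("list", length(config$genome))
  for (i in seq_along(config$genome)) {
    ch <- names(config$genome)[i]
    len <- config$genome[[i]]
    n <- max(1L, round(config$peak_density * len / 1e5))
    centers <- round(seq(len / (n + 1), len * n / (n + 1), length.out = n) +
                       runif(n, -0.15, 0.15) * len / (n + 1))
    start <- pmax(2000L, pmin(as.integer(centers - w %/% 2L),
                              as.integer(len - w - 2000L)))
    summit_off <- as.integer(round(runif(n, 0.3, 0.7) * w))
    out[[i]] <- data.table(chrom = ch, start = start, end = start + w,
                           summit = start + summit_off)
  }
  pk <- rbindlist(out)
  setorder(pk, chrom, start)
  pk[, peak_id := sprintf("peak_%05d", .I)]
  setcolorder(pk, "peak_id")
  pk[]
}

#' Plant causal regulatory variants and build the ground-truth table
#'
#' Selects a fraction of peaks to carry one causal SNP near the summit. The
#' effect `b` multiplies the fragment rate of the ALT-carrying haplotype by
#' `exp(b)`; its sign is random. For each causal variant the REF/ALT alleles
#' are rewritten so that the accessibility-increasing allele completes a
#' consensus motif occurrence later embedded in the genome sequence (the
#' decreasing allele breaks it), which lets sequence-model scoring recover the
#' planted direction.
#'
#' @param sim output of [simulate_haplotypes()] (alleles may be modified in
#'   place for causal variants).
#' @param peaks output of [simulate_peaks()].
#' @param genes optional gene table from [simulate_genes()] for expression
#'   links.
#' @param config a [cohort_config()].
#' @param motif consensus motif completed by the accessibility-up allele.
#' @return `data.table` ground truth: `variant_id`, `peak_id`, `cell_types`
#'   (comma-joined), `b`, `pi`, `gene_id`, `gamma`, `meth_shift`,
#'   `motif_offset`.
#' @export
plant_causal_variants <- function(sim, peaks, genes = NULL, config,
                                  motif = "TGACGTCA") {
  validate_cohort_config(config)
  set.seed(child_seed(config$seed, "causal"))
  v <- sim$variants
  maf <- pmin(colMeans(sim$haplotypes), 1 - colMeans(sim$haplotypes))
  # candidate causal variants: common SNPs close to a summit
  cand <- v[, .(variant_id, chrom, pos0, is_indel)]
  cand[, maf := maf]
  hits <- merge(cand[is_indel == FALSE & maf >= 0.12],
                peaks, by = "chrom", allow.cartesian = TRUE)
  hits <- hits[abs(pos0 - summit) <= 150L]
  eligible <- unique(hits$peak_id)
  n_causal <- min(length(eligible), round(config$frac_causal_peaks * nrow(peaks)))
  causal_peaks <- sort(sample(eligible, n_causal))
  picks <- hits[peak_id %in% causal_peaks][
    , .SD[which.min(abs(pos0 - summit))], by = peak_id]

  n <- nrow(picks)
  b <- (2L * rbinom(n, 1L, 0.5) - 1L) *
    pmax(0.3, rnorm(n, config$effect_size, config$effect_sd))
  kct <- length(config$cell_types)
  cell_types <- vapply(seq_len(n), function(i) {
    if (kct == 1L || runif(1) < config$celltype_sharing) {
      paste(config$cell_types, collapse = ",")
    } else {
      m <- sample.int(kct - 1L, 1L)
      paste(sort(sample(config$cell_types, m)), collapse = ",")
    }
  }, "")

  # rewrite alleles so ALT completes the motif when b > 0, breaks it when b < 0
  mlen <- nchar(motif)
  offset <- sample.int(mlen, n, replace = TRUE)
  cons <- substring(motif, offset, offset)
  other <- vapply(cons, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
  ref <- ifelse(b < 0, cons, other)
  alt <- ifelse(b < 0, other, cons)
  vi <- match(picks$variant_id, v$variant_id)
  v[vi, `:=`(ref = ..ref, alt = ..alt, is_indel = FALSE)]

  gene_id <- rep(NA_character_, n)
  gamma <- rep(NA_real_, n)
  if (!is.null(genes) && nrow(genes)) {
    for (i in seq_len(n)) {
      g <- genes[chrom == picks$chrom[i]]
      if (!nrow(g)) next
      d <- interval_distance(picks$pos0[i], g$start, g$end)
      j <- which.min(d)
      if (d[j] <= 2e5) {
        gene_id[i] <- g$gene_id[j]
        gamma[i] <- config$expression_coupling * sign(b[i]) *
          runif(1, 0.8, 1.2)
      }
    }
  }
  data.table(variant_id = picks$variant_id, peak_id = picks$peak_id,
             cell_types = cell_types, b = b, pi = exp(b) / (1 + exp(b)),
             gene_id = gene_id, gamma = gamma,
             meth_shift = config$methylation_coupling * b,
             motif_offset = offset)
}

#' Simulate a gene annotation with exon structure
#'
#' @param config a [cohort_config()].
#' @return `data.table` with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `exon_starts`, `exon_ends` (comma-joined 0-based half-open intervals).
#' @export
simulate_genes <- function(config) {
  validate_cohort_config(config)
  set.seed(child_seed(config$seed, "genes"))
  per_chrom <- pmax(1L, round(config$n_genes * config$genome / sum(config$genome)))
  out <- vector("list", length(config$genome))
  for (i in seq_along(config$genome)) {
    ch <- names(config$genome)[i]
    len <- config$genome[[i]]
    n <- per_chrom[i]
    body_len <- as.integer(round(runif(n, 5e3, 3e4)))
    start <- as.integer(round(seq(len * 0.05, len * 0.9, length.out = n)))
    start <- pmin(start, len - body_len - 1000L)
    n_ex <- pmax(2L, rpois(n, 4L))
    ex_s <- character(n); ex_e <- character(n)
    for (j in seq_len(n)) {
      # 2*(n_ex - 1) interior cuts alternate exon/intron boundaries
      n_cut <- 2L * (n_ex[j] - 1L)
      cuts <- sort(sample(seq(50L, body_len[j] - 50L, by = 25L), n_cut))
      es <- start[j] + c(0L, cuts[seq(2L, n_cut, by = 2L)])
      ee <- start[j] + c(cuts[seq(1L, n_cut, by = 2L)], body_len[j])
      ex_s[j] <- paste(es, collapse = ",")
      ex_e[j] <- paste(ee, collapse = ",")
    }
    out[[i]] <- data.table(chrom = ch, start = start,
                           end = start + body_len,
                           strand = sample(c("+", "-"), n, replace = TRUE),
                           exon_starts = ex_s, exon_ends = ex_e)
  }
  g <- rbindlist(out)
  setorder(g, chrom, start)
  g[, gene_id := sprintf("gene_%04d", .I)]
  setcolorder(g, "gene_id")
  g[]
}

#' Build the synthetic genome sequence consistent with the variant table
#'
#' Random background sequence with every variant's REF allele written at its
#' position; around each causal variant the planting motif is embedded so
#' that the accessibility-up allele restores the consensus (see
#' [plant_causal_variants()]).
#'
#' @param variants variant table (possibly rewritten by
#'   [plant_causal_variants()]).
#' @param truth ground-truth table (may be `NULL` for no motifs).
#' @param config a [cohort_config()].
#' @param motif consensus motif, must match the one used when planting.
#' @return named character vector of chromosome sequences.
#' @export
simulate_genome_sequence <- function(variants, truth = NULL, config,
                                     motif = "TGACGTCA") {
  validate_cohort_config(config)
  set.seed(child_seed(config$seed, "genome"))
  bases <- c("A", "C", "G", "T")
  genome <- vapply(names(config$genome), function(ch) {
    paste(sample(bases, config$genome[[ch]], replace = TRUE), collapse = "")
  }, "")
  mchars <- strsplit(motif, "")[[1]]
  for (ch in names(genome)) {
    sq <- strsplit(genome[[ch]], "")[[1]]
    vv <- variants[chrom == ch]
    # write REF alleles into the background (1-based string index = pos0 + 1)
    for (i in seq_len(nrow(vv))) {
      r <- strsplit(vv$ref[i], "")[[1]]
      sq[vv$pos0[i] + seq_along(r)] <- r
    }
    if (!is.null(truth) && nrow(truth)) {
      tv <- merge(truth, vv[, .(variant_id, pos0, ref)], by = "variant_id")
      for (i in seq_len(nrow(tv))) {
        s0 <- tv$pos0[i] - tv$motif_offset[i] + 1L  # motif start, 0-based
        sq[s0 + seq_along(mchars)] <- mchars
        # the genome carries the REF allele at the variant site, which only
        # matches the consensus when b < 0 (ALT breaks the motif)
        sq[tv$pos0[i] + 1L] <- substr(tv$ref[i], 1L, 1L)
      }
    }
    genome[[ch]] <- paste(sq, collapse = "")
  }
  genome
}
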