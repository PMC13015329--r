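#' Construct a synthetic read for mappability filtering
#'
#' Reads are represented by their locus and by the (variant, allele) pairs
#' they carry at overlapped heterozygous sites — a sequence-free stand-in
#' that exercises allele-swap remapping without a full read simulator.
#'
#' @param chrom,start,length read locus (0-based start) and length.
#' @param variants `data.table` with `variant_id`, `offset` (0-based within
#'   the read), `allele` (0/1) and optionally `ref`/`alt` strings for
#'   indel-aware coordinate shifts; may have zero rows.
#' @param mapq mapping quality of the original alignment.
#' @return object of class `synthetic_read`.
#' @export
synthetic_read <- function(chrom, start, length, variants = NULL, mapq = 60L) {
  variants <- if (is.null(variants)) {
    data.table(variant_id = character(), offset = integer(),
               allele = integer(), ref = character(), alt = character())
  } else as.data.table(variants)
  if (nrow(variants)) {
    if (!"ref" %in% names(variants)) variants[, ref := "N"]
    if (!"alt" %in% names(variants)) variants[, alt := "N"]
    stopifnot(all(variants$allele %in% 0:1),
              all(variants$offset >= 0), all(variants$offset < length))
    setorder(variants, offset)
  }
  structure(list(chrom = chrom, start = start, length = length,
                 variants = variants, mapq = mapq),
            class = "synthetic_read")
}

#' @export
print.synthetic_read <- function(x, ...) {
  cat(sprintf("synthetic_read %s:%d-%d (mapq %d, %d het site(s))\n",
              x$chrom, x$start, x$start + x$length, x$mapq,
              nrow(x$variants)))
  invisible(x)
}

#' Enumerate allele-substituted versions of a read
#'
#' Builds the Cartesian product of alleles over the read's overlapped
#' heterozygous biallelic sites — up to `2^6 = 64` combinations. Reads
#' overlapping more than `max_sites` het sites are not enumerated but
#' flagged for discard. Indel substitutions shift the offsets of downstream
#' sites and the read length within the read representation.
#'
#' @param read a [synthetic_read()].
#' @param max_sites maximum het sites before the read is flagged (default 6,
#'   the 64-combination cap).
#' @return list with `combinations` (list of `synthetic_read`s, empty when
#'   flagged) and `discard_flag`.
#' @export
enumerate_allele_combinations <- function(read, max_sites = 6L) {
  stopifnot(inherits(read, "synthetic_read"))
  k <- nrow(read$variants)
  if (k > max_sites) {
    return(list(combinations = list(), discard_flag = TRUE))
  }
  if (k == 0L) {
    return(list(combinations = list(read), discard_flag = FALSE))
  }
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  combos <- vector("list", nrow(grid))
  len_diff <- nchar(read$variants$alt) - nchar(read$variants$ref)
  for (i in seq_len(nrow(grid))) {
    al <- grid[i, ]
    v <- copy(read$variants)
    v[, allele := as.integer(al)]
    # downstream offsets shift by the cumulative indel length difference
    shift <- cumsum(c(0L, (len_diff * al)[-k]))
    v[, offset := offset + as.integer(shift)]
    combos[[i]] <- synthetic_read(read$chrom, read$start,
                                  read$length + sum(len_diff * al),
                                  v, read$mapq)
  }
  list(combinations = combos, discard_flag = FALSE)
}

#' Allele-swap mappability filter
#'
#' A read overlapping heterozygous sites is retained only if every
#' allele-substituted version of it maps back to the original locus with
#' mapping quality strictly above `mq_min`; reads overlapping no het site
#' pass unchanged, and reads with more than 6 het sites (over 64
#' combinations) are discarded. A mapper failure on any combination
#' discards the read.
#'
#' @param reads list of [synthetic_read()] objects.
#' @param mapper function taking a `synthetic_read` and returning
#'   `list(chrom, start, mapq)` (deterministic alignment oracle).
#' @param mq_min minimum mapping quality (exclusive).
#' @return list with `retained` (list of reads) and `tally`, a named count
#'   of drop reasons (`too_many_sites`, `moved`, `low_mapq`,
#'   `mapper_failure`).
#' @export
mappability_filter <- function(reads, mapper, mq_min = 10L) {
  tally <- c(too_many_sites = 0L, moved = 0L, low_mapq = 0L,
             mapper_failure = 0L)
  retained <- vector("list", length(reads))
  m <- 0L
  for (r in reads) {
    if (nrow(r$variants) == 0L) {
      m <- m + 1L; retained[[m]] <- r
      next
    }
    en <- enumerate_allele_combinations(r)
    if (en$discard_flag) {
      tally["too_many_sites"] <- tally["too_many_sites"] + 1L
      next
    }
    verdict <- "keep"
    for (cb in en$combinations) {
      hit <- tryCatch(mapper(cb), error = function(e) NULL)
      if (is.null(hit)) { verdict <- "mapper_failure"; break }
      if (!identical(hit$chrom, r$chrom) || hit$start != r$start) {
        verdict <- "moved"; break
      }
      if (hit$mapq <= mq_min) { verdict <- "low_mapq"; break }
    }
    if (verdict == "keep") {
      m <- m + 1L; retained[[m]] <- r
    } else {
      tally[verdict] <- tally[verdict] + 1L
    }
  }
  list(retained = retained[seq_len(m)], tally = tally)
}

#' Trivial alignment oracle mapping every read to its stated locus
#'
#' @param mapq mapping quality reported for every read.
#' @return a mapper function for [mappability_filter()].
#' @export
perfect_mapper <- function(mapq = 60L) {
  force(mapq)
  function(read) list(chrom = read$chrom, start = read$start, mapq = mapq)
}

#' Simulate reads over peak windows for mappability testing
#'
#' Tiny read simulator used only to exercise the mappability filter: draws
#' reads across the given peak windows for one donor and attaches the
#' heterozygous sites each read overlaps.
#'
#' @param G a `phased_genotypes` object.
#' @param donor donor ID.
#' @param peaks peak table.
#' @param n_reads reads to draw.
#' @param read_length read length in bp.
#' @param seed RNG seed.
#' @return list of [synthetic_read()] objects.
#' @export
simulate_reads <- function(G, donor, peaks, n_reads = 100L,
                           read_length = 80L, seed = 1L) {
  set.seed(seed)
  peaks <- as.data.table(peaks)
  di <- match(donor, G$donors)
  if (is.na(di)) stop("unknown donor")
  pk <- peaks[sample.int(nrow(peaks), n_reads, replace = TRUE)]
  start <- pk$start + as.integer(floor(runif(n_reads) *
                                         pmax(1L, pk$end - pk$start - read_length)))
  lapply(seq_len(n_reads), function(i) {
    vv <- G$variants[chrom == pk$chrom[i] & pos0 >= start[i] &
                       pos0 < start[i] + read_length]
    if (nrow(vv)) {
      vi <- match(vv$variant_id, G$variants$variant_id)
      het <- G$hap1[di, vi] != G$hap2[di, vi]
      vv <- vv[het]
      vi <- vi[het]
    }
    v <- if (nrow(vv)) {
      hap <- sample(1:2, 1L)
      data.table(variant_id = vv$variant_id, offset = vv$pos0 - start[i],
                 allele = if (hap == 1L) G$hap1[di, vi] else G$hap2[di, vi],
                 ref = vv$ref, alt = vv$alt)
    } else NULL
    synthetic_read(pk$chrom[i], start[i], read_length, v)
  })
}
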