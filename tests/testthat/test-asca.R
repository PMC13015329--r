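# compact builders for allelic-count fixtures
frag_row <- function(id, start, end, donor, ct = "CT", bc = NULL) {
  data.table::data.table(frag_id = id, chrom = "chr1", start = start,
                         end = end, barcode = bc %||% paste0(donor, "_c1"),
                         donor = donor, cell_type = ct)
}

test_that("allele counting respects windows, het status and fragment granularity", {
  # two variants: v001 at summit, v002 251 bp away (outside the 500 bp window)
  hap1 <- matrix(c(0L, 1L), 2, 2); hap2 <- matrix(c(1L, 0L), 2, 2)
  G <- make_genotypes(hap1, hap2, pos0 = c(1250L, 1501L))
  peaks <- data.table::data.table(peak_id = "pk", chrom = "chr1",
                                  start = 1000L, end = 1500L, summit = 1250L)
  frags <- rbind(frag_row(1L, 1200L, 1320L, "D001"),
                 frag_row(2L, 1210L, 1330L, "D001"),
                 frag_row(3L, 1400L, 1540L, "D001"))
  alleles <- data.table::data.table(frag_id = c(1L, 2L, 3L),
                                    variant_id = c("v001", "v001", "v002"),
                                    allele = c(1L, 1L, 0L))
  vc <- count_alleles_per_variant(frags, alleles, G, peaks)
  # v002 is outside the summit window: never counted
  expect_false("v002" %in% vc$variant_id)
  # two fragments from the same cell still count twice (no UMI dedup)
  expect_equal(vc[variant_id == "v001", alt_count], 2L)
  expect_equal(vc[variant_id == "v001", ref_count], 0L)
  # an annotation that does not overlap its fragment is corrupt input
  bad <- data.table::copy(alleles)[frag_id == 1L, variant_id := "v002"]
  expect_error(count_alleles_per_variant(frags, bad, G, peaks),
               "does not overlap")
})

test_that("phase-aware aggregation orients helper counts onto the test variant", {
  # donor het at test variant v001 (ALT on hap1) and helpers v002 (ALT on
  # hap1, in phase) and v003 (ALT on hap2, in phase)
  hap1 <- matrix(c(1L, 1L, 0L), 1, 3)
  hap2 <- matrix(c(0L, 0L, 1L), 1, 3)
  G <- make_genotypes(hap1, hap2, pos0 = c(1100L, 1200L, 1300L))
  vc <- data.table::data.table(
    donor = "D001", cell_type = "CT", peak_id = "pk",
    variant_id = c("v001", "v002", "v003"),
    ref_count = c(3L, 2L, 5L), alt_count = c(5L, 4L, 3L))
  out <- aggregate_counts_per_peak(vc, G, "pk", "v001")
  # aligned helpers contribute ALT; the opposite-haplotype helper contributes
  # REF reads toward y: y = 5 + 4 + 5 = 14, n = 8 + 6 + 8 = 22
  expect_equal(out$y, 14L)
  expect_equal(out$n, 22L)
  # the in-phase oriented sum of the spec example: (5,3) and (4,2) -> (9,14)
  vc2 <- vc[variant_id != "v003"]
  vc2[variant_id == "v002", `:=`(ref_count = 2L, alt_count = 4L)]
  out2 <- aggregate_counts_per_peak(vc2, G, "pk", "v001")
  expect_equal(out2$y, 9L)
  expect_equal(out2$n, 14L)
})

test_that("helpers in another phase set and unphased donors are excluded", {
  hap1 <- matrix(c(1L, 1L), 1, 2); hap2 <- matrix(c(0L, 0L), 1, 2)
  ps <- matrix(c(1L, 2L), 1, 2)  # helper in a different phase set
  G <- make_genotypes(hap1, hap2, pos0 = c(1100L, 1200L), phase_set = ps)
  vc <- data.table::data.table(
    donor = "D001", cell_type = "CT", peak_id = "pk",
    variant_id = c("v001", "v002"),
    ref_count = c(3L, 10L), alt_count = c(5L, 10L))
  out <- aggregate_counts_per_peak(vc, G, "pk", "v001")
  expect_equal(out$y, 5L)   # only the test variant itself contributes
  expect_equal(out$n, 8L)
  # unphased test variant: donor dropped entirely
  ps2 <- matrix(c(NA_integer_, 2L), 1, 2)
  G2 <- make_genotypes(hap1, hap2, pos0 = c(1100L, 1200L), phase_set = ps2)
  out2 <- aggregate_counts_per_peak(vc, G2, "pk", "v001")
  expect_equal(nrow(out2), 0L)
})

test_that("orientation agrees with the haplotype-of-origin ground truth", {
  co <- tiny_cohort()
  G <- co$genotypes
  vc <- count_alleles_per_variant(co$fragments, co$alleles, G, co$peaks)
  tr <- co$truth[1]
  agg <- aggregate_counts_per_peak(vc[cell_type == co$config$cell_types[1]],
                                   G, tr$peak_id, tr$variant_id)
  vi <- match(tr$variant_id, G$variants$variant_id)
  # oracle: count fragments by true haplotype of origin restricted to those
  # overlapping at least one het site of the donor
  ann_frag <- unique(co$alleles$frag_id)
  for (d in agg$donor[1:min(3, nrow(agg))]) {
    alt_hap <- if (G$hap1[d, vi] == 1L) 1L else 2L
    fr <- co$fragments[peak_id == tr$peak_id & donor == d &
                         cell_type == co$config$cell_types[1] &
                         frag_id %in% ann_frag]
    # fragments informative for this donor: overlap >= 1 het variant in window
    vw <- variants_in_peak_windows(G$variants, co$peaks[peak_id == tr$peak_id])
    het_ids <- vw$variant_id[G$hap1[d, vw$variant_id] != G$hap2[d, vw$variant_id]]
    inf <- co$alleles[frag_id %in% fr$frag_id & variant_id %in% het_ids]
    contrib <- merge(inf, fr[, .(frag_id, hap)], by = "frag_id")
    expect_equal(agg[donor == d, y],
                 sum(contrib$hap == alt_hap))
    expect_equal(agg[donor == d, n], nrow(contrib))
  }
})

test_that("beta-binomial log-likelihood has its closed-form special cases", {
  # uniform compound: alpha = beta = 1 gives -log(n + 1) for every y
  for (y in c(0, 3, 10)) {
    expect_equal(betabinom_loglik(y, 10, 1, 1), -log(11), tolerance = 1e-12)
  }
  # large concentration approaches the binomial(0.5) likelihood
  expect_equal(betabinom_loglik(50, 100, 1e6, 1e6),
               dbinom(50, 100, 0.5, log = TRUE), tolerance = 1e-3)
  # normalisation over the support
  expect_equal(sum(exp(betabinom_loglik(0:30, 30, 2.3, 0.7))), 1,
               tolerance = 1e-10)
  expect_error(betabinom_loglik(5, 10, -1, 1), "positive")
  expect_error(betabinom_loglik(11, 10, 1, 1), "lie in")
})

test_that("the imbalance test is null-centred, thresholded and oracle-consistent", {
  balanced <- data.table::data.table(y = rep(25L, 8), n = rep(50L, 8))
  fit <- as_cht_test(balanced)
  expect_s3_class(fit, "ascht")
  expect_equal(fit$imbalance, 0.5, tolerance = 1e-3)
  expect_lt(fit$lrt, 1e-4)
  expect_gt(fit$p, 0.99)
  # 4 het donors: below the donor threshold
  expect_true(as_cht_test(balanced[1:4])$untestable)
  # 5 donors but 49 reads: below the read threshold
  few <- data.table::data.table(y = c(5L, 5L, 5L, 5L, 4L), n = c(10L, 10L, 10L, 10L, 9L))
  expect_true(as_cht_test(few)$untestable)
  expect_false(as_cht_test(data.table::data.table(y = rep(5L, 5),
                                                  n = rep(10L, 5)))$untestable)
  # recovery at pi = 0.7 and agreement with the 2-D grid-search ML oracle
  set.seed(31)
  y <- rbetabinom(8, 100, 0.7, 40)
  rows <- data.table::data.table(y = y, n = rep(100L, 8))
  fit2 <- as_cht_test(rows)
  expect_lt(abs(fit2$imbalance - 0.7), 0.05)
  oracle <- betabinom_grid_oracle(rows$y, rows$n)
  expect_lt(abs(fit2$imbalance - oracle$imbalance), 1e-3)
})

test_that("allele swap mirrors the imbalance and preserves the LRT", {
  set.seed(13)
  y <- rbetabinom(9, 80, 0.65, 30)
  rows <- data.table::data.table(y = y, n = rep(80L, 9))
  swapped <- data.table::data.table(y = rows$n - rows$y, n = rows$n)
  a <- as_cht_test(rows); b <- as_cht_test(swapped)
  expect_equal(a$imbalance, 1 - b$imbalance, tolerance = 1e-8)
  expect_equal(a$lrt, b$lrt, tolerance = 1e-8)
  expect_equal(a$alpha, b$beta, tolerance = 1e-6)
})

test_that("the LRT grows with single-donor deviation from balance", {
  n <- 200L
  lrts <- vapply(c(100L, 120L, 140L, 160L, 180L), function(y) {
    as_cht_test(data.table::data.table(y = y, n = n),
                min_het_donors = 1L)$lrt
  }, 0)
  expect_true(all(diff(lrts) > 0))
})

test_that("asca_map returns one corrected row per (variant, peak, cell type)", {
  co <- tiny_cohort()
  res <- tiny_pipeline()
  expect_true(all(c("variant_id", "peak_id", "cell_type", "alpha", "beta",
                    "imbalance", "lrt", "p", "q", "n_het", "n_reads",
                    "untestable") %in% names(res$asca)))
  expect_false(anyDuplicated(res$asca[, .(variant_id, peak_id, cell_type)]) > 0)
  ok <- res$asca[untestable == FALSE]
  expect_true(all(ok$imbalance > 0 & ok$imbalance < 1))
  expect_true(all(ok$lrt >= 0))
  expect_true(all(ok$q >= ok$p - 1e-12, na.rm = TRUE))
  # untestable rows carry no statistics
  expect_true(all(is.na(res$asca[untestable == TRUE, p])))
})
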