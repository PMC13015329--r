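# compact genome fixture: one chromosome with a motif planted at a known spot
scoring_fixture <- function(L = 214L, motif = "TGACGTCA", chrom_len = 6000L,
                            summit = 3000L, motif_at = 2997L) {
  set.seed(61)
  sq <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  mch <- strsplit(motif, "")[[1]]
  sq[motif_at + seq_along(mch)] <- mch  # 0-based motif_at
  genome <- c(chr1 = paste(sq, collapse = ""))
  peak <- data.table::data.table(peak_id = "pk", chrom = "chr1",
                                 start = summit - 250L, end = summit + 250L,
                                 summit = summit)
  list(genome = genome, peak = peak, motif = motif, motif_at = motif_at)
}

test_that("REF/ALT windows are fixed-length and substitute exactly one SNP base", {
  fx <- scoring_fixture()
  g <- fx$genome
  v <- data.table::data.table(variant_id = "v1", chrom = "chr1",
                              pos0 = 3000L,
                              ref = substr(g, 3001L, 3001L), alt = "N")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  io <- build_ref_alt_inputs(fx$peak, v, g, L = 214L)
  expect_equal(nchar(io$ref_seq), 214L)
  expect_equal(nchar(io$alt_seq), 214L)
  d <- which(strsplit(io$ref_seq, "")[[1]] != strsplit(io$alt_seq, "")[[1]])
  expect_length(d, 1)
  expect_equal(d - 1L, io$var_offset_ref)
  # degenerate record with REF == ALT yields identical windows
  v2 <- data.table::copy(v)[, alt := ref]
  io2 <- build_ref_alt_inputs(fx$peak, v2, g, L = 214L)
  expect_identical(io2$ref_seq, io2$alt_seq)
  # REF mismatch against the FASTA names the site
  v3 <- data.table::copy(v)[, ref := setdiff(c("A", "C", "G", "T"),
                                             c(ref, alt))[1]]
  expect_error(build_ref_alt_inputs(fx$peak, v3, g, L = 214L),
               "reference mismatch")
})

test_that("deletion windows recruit flanking bases and reproduce the gap", {
  fx <- scoring_fixture()
  g <- fx$genome
  pos <- 3010L
  ref3 <- substr(g, pos + 1L, pos + 3L)  # anchor + 2 deleted bases
  v <- data.table::data.table(variant_id = "d1", chrom = "chr1", pos0 = pos,
                              ref = ref3, alt = substr(ref3, 1L, 1L))
  io <- build_ref_alt_inputs(fx$peak, v, g, L = 214L)
  expect_equal(nchar(io$alt_seq), 214L)
  # round-trip: deleting 2 bases after the anchor from the reference context
  # (1 extra flank base upstream, 1 downstream) reproduces the ALT window
  s0 <- 3000L - 107L
  ref_ctx <- substr(g, s0 + 1L - 1L, s0 + 214L + 1L)  # widened by the flanks
  rel <- pos - (s0 - 1L)                              # 0-based in context
  manual <- paste0(substr(ref_ctx, 1L, rel + 1L),
                   substr(ref_ctx, rel + 4L, nchar(ref_ctx)))
  expect_identical(io$alt_seq, manual)
})

test_that("indel windows keep length L and contain the variant (property)", {
  fx <- scoring_fixture()
  g <- fx$genome
  set.seed(9)
  for (i in 1:30) {
    k <- sample(1:50, 1)
    pos <- sample(2900:3040, 1)  # inside the 214 bp summit window with room
                                 # for the longest deletion span
    if (runif(1) < 0.5) {  # deletion of k bp
      ref <- substr(g, pos + 1L, pos + 1L + k)
      alt <- substr(ref, 1L, 1L)
    } else {               # insertion of k bp
      ref <- substr(g, pos + 1L, pos + 1L)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), k,
                                      replace = TRUE), collapse = ""))
    }
    v <- data.table::data.table(variant_id = "x", chrom = "chr1",
                                pos0 = pos, ref = ref, alt = alt)
    io <- build_ref_alt_inputs(fx$peak, v, g, L = 214L)
    expect_equal(nchar(io$ref_seq), 214L)
    expect_equal(nchar(io$alt_seq), 214L)
  }
})

test_that("toy-model ISM matches analytic evaluation and is antisymmetric", {
  fx <- scoring_fixture()
  g <- fx$genome
  model <- toy_pwm_model(list(CTa = fx$motif, CTb = "CCCCGGGG"),
                         weight = 0.5, intercept = 1)
  # break the motif's 4th base (0-based offset 3 from motif_at)
  pos <- fx$motif_at + 3L
  ref <- substr(g, pos + 1L, pos + 1L)
  stopifnot(ref == "C")
  v <- data.table::data.table(variant_id = "m1", chrom = "chr1", pos0 = pos,
                              ref = ref, alt = "T")
  io <- build_ref_alt_inputs(fx$peak, v, g, L = 214L)
  eff <- ism_variant_effect(model, io$ref_seq, io$alt_seq)
  # oracle: naive per-position loops over the same sequences
  pr <- toy_model_oracle(model, io$ref_seq)
  pa <- toy_model_oracle(model, io$alt_seq)
  expect_equal(eff$delta, unname(pa - pr), tolerance = 1e-9)
  expect_equal(eff$logfc, unname(log2(pa / pr)), tolerance = 1e-9)
  # the motif cell type loses accessibility; the other is unchanged
  expect_lt(eff[cell_type == "CTa", logfc], 0)
  expect_equal(eff[cell_type == "CTb", logfc], 0, tolerance = 1e-12)
  # identical inputs give zero everywhere
  null_eff <- ism_variant_effect(model, io$ref_seq, io$ref_seq)
  expect_true(all(null_eff$delta == 0) && all(null_eff$logfc == 0))
  # swapping REF and ALT negates both scores
  rev_eff <- ism_variant_effect(model, io$alt_seq, io$ref_seq)
  expect_equal(rev_eff$delta, -eff$delta, tolerance = 1e-12)
  expect_equal(rev_eff$logfc, -eff$logfc, tolerance = 1e-12)
})

test_that("gene-level aggregation uses the bin-start rule and the log2 link", {
  set.seed(3)
  bins <- seq(0L, 900L, by = 100L)
  pred <- matrix(runif(6 * 10, 1, 5), 6, 10)
  groups <- rep(c("CTa", "CTb"), each = 3)
  exons <- data.table::data.table(start = c(150L, 600L), end = c(420L, 750L))
  # identical predictions give zero effect
  expect_equal(unname(gene_level_effect(pred, pred, bins, exons, groups)),
               c(0, 0))
  # bin-start rule: bins 200, 300, 400 (starts in [150,420)) and 600, 700
  in_exon <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  alt <- 2 * pred
  eff <- gene_level_effect(pred, alt, bins, exons, groups)
  for (ct in c("CTa", "CTb")) {
    x <- sum(pred[groups == ct, in_exon])
    expect_equal(unname(eff[ct]), log2(2 * x + 1) - log2(x + 1),
                 tolerance = 1e-12)
  }
  # an exon outside the covered window is an error
  expect_error(gene_level_effect(pred, alt, bins,
                                 data.table::data.table(start = 2000L,
                                                        end = 2100L),
                                 groups),
               "outside")
})

test_that("cohort scoring emits one row per overlapping peak and tallies orphans", {
  fx <- scoring_fixture()
  model <- toy_pwm_model(list(CT = fx$motif))
  peaks2 <- rbind(fx$peak,
                  data.table::data.table(peak_id = "pk2", chrom = "chr1",
                                         start = 2800L, end = 3300L,
                                         summit = 3050L))
  g <- fx$genome
  vv <- data.table::data.table(
    variant_id = c("in_both", "orphan"), chrom = "chr1",
    pos0 = c(3020L, 200L),
    ref = c(substr(g, 3021L, 3021L), substr(g, 201L, 201L)),
    alt = c("A", "A"))
  vv[ref == "A", alt := "G"]
  out <- score_cohort_variants(model, peaks2, vv, g, L = 214L)
  expect_equal(nrow(out$effects), 2L)  # one per overlapped peak window
  expect_setequal(out$effects$peak_id, c("pk", "pk2"))
  expect_equal(unname(out$tally["no_peak"]), 1L)
  empty <- score_cohort_variants(model, peaks2, vv[0], g, L = 214L)
  expect_equal(nrow(empty$effects), 0L)
})

test_that("model scores recover the planted effect direction on the cohort", {
  co <- tiny_cohort()
  cfg <- tiny_cfg()
  genome <- simulate_genome_sequence(co$genotypes$variants, co$truth, cfg)
  model <- toy_pwm_model(list(CT = "TGACGTCA"))
  causal_peaks <- co$peaks[peak_id %in% co$truth$peak_id]
  vv <- co$genotypes$variants[variant_id %in% co$truth$variant_id]
  out <- score_cohort_variants(model, causal_peaks, vv, genome, L = 514L)
  eff <- merge(out$effects, co$truth[, .(variant_id, peak_id, b)],
               by = c("variant_id", "peak_id"))
  scored <- eff[abs(logfc) > 0.05]
  expect_gte(nrow(scored), 0.7 * nrow(co$truth))
  # the accessibility-raising allele completes the motif, so the ISM logFC
  # sign tracks the planted effect sign
  expect_gte(mean(sign(scored$logfc) == sign(scored$b)), 0.9)
  # planted motif-breakers score higher than background variants
  bg_ids <- setdiff(
    variants_in_peak_windows(co$genotypes$variants, causal_peaks)$variant_id,
    co$truth$variant_id)
  bg <- co$genotypes$variants[variant_id %in% bg_ids][is_indel == FALSE][1:20]
  out_bg <- score_cohort_variants(model, causal_peaks, bg, genome, L = 514L)
  expect_gt(median(abs(scored$logfc)),
            median(abs(out_bg$effects$logfc)) + 0.05)
})
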