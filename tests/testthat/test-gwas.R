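# deterministic haplotype vectors with a controlled correlation structure
flip_some <- function(x, k, seed = 1) {
  set.seed(seed)
  y <- x
  i <- sample(length(x), k)
  y[i] <- 1L - y[i]
  y
}

test_that("haplotype r-squared has its exact symmetries and null behaviour", {
  lead <- rep(c(0L, 1L), 100)
  expect_equal(ld_r2(lead, lead), 1)
  expect_equal(ld_r2(lead, 1L - lead), 1)     # complementary vectors
  partner <- flip_some(lead, 20)
  expect_equal(ld_r2(lead, partner), ld_r2(partner, lead))
  expect_equal(ld_r2(lead, partner), ld_r2(1L - lead, partner))
  mono <- ld_r2(lead, rep(0L, 200))
  expect_true(is.na(mono))
  expect_true(attr(mono, "monomorphic"))
  set.seed(19)
  null_r2 <- replicate(50, ld_r2(rbinom(400, 1, 0.5), rbinom(400, 1, 0.5)))
  expect_lt(median(null_r2), 0.05)
  expect_lt(mean(null_r2 > 0.05), 0.2)
})

# build a phased cohort where partner r2 to the lead is controlled by the
# number of flipped haplotypes
ld_fixture <- function(pos, flips, lead_pos = 1e6L, nd = 100L) {
  lead <- rep(c(0L, 1L), nd)
  haps <- cbind(lead, mapply(function(k, s) flip_some(lead, k, s),
                             flips, seq_along(flips) + 100))
  pos0 <- as.integer(c(lead_pos, pos))
  ord <- order(pos0)
  hap1 <- haps[seq(1, 2 * nd, 2), ord, drop = FALSE]
  hap2 <- haps[seq(2, 2 * nd, 2), ord, drop = FALSE]
  G <- make_genotypes(hap1, hap2, pos0 = pos0[ord])
  list(G = G, lead = G$variants$variant_id[which(G$variants$pos0 == lead_pos)])
}

test_that("LD blocks extend to the furthest strong partner with floored sides", {
  # partner at +5 kb with r2 ~ 0.7 and at -800 bp with r2 ~ 0.9:
  # right side extends to 5000, left side floors at 1500
  fx <- ld_fixture(pos = c(1e6 + 5e3, 1e6 - 800), flips = c(17, 5))
  r2s <- vapply(setdiff(fx$G$variants$variant_id, fx$lead), function(v) {
    j <- match(v, fx$G$variants$variant_id)
    ld_r2(c(fx$G$hap1[, match(fx$lead, fx$G$variants$variant_id)],
            fx$G$hap2[, match(fx$lead, fx$G$variants$variant_id)]),
          c(fx$G$hap1[, j], fx$G$hap2[, j]))
  }, 0)
  expect_true(all(r2s > 0.6))
  blk <- build_ld_block(fx$lead, fx$G)
  expect_equal(blk$right_dist, 5000L)
  expect_equal(blk$left_dist, 1500L)
  expect_equal(blk$end - blk$start, 6500L)
  # the lead always lies inside the region
  lead_pos <- fx$G$variants$pos0[match(fx$lead, fx$G$variants$variant_id)]
  expect_true(blk$start <= lead_pos && lead_pos < blk$end)
})

test_that("leads without strong partners get the minimal 3 kb region", {
  # partners exist (r2 >= 0.05) but none reaches the 0.6 edge threshold
  fx <- ld_fixture(pos = c(1e6 + 3e3, 1e6 - 4e3), flips = c(70, 80))
  blk <- build_ld_block(fx$lead, fx$G)
  expect_equal(blk$end - blk$start, 3000L)
  expect_equal(blk$left_dist, 1500L)
  expect_equal(blk$right_dist, 1500L)
})

test_that("partners outside the 2 Mb window are ignored", {
  fx <- ld_fixture(pos = c(1e6 + 1.2e6, 1e6 + 2e3), flips = c(5, 10))
  blk <- build_ld_block(fx$lead, fx$G)
  expect_equal(blk$right_dist, 2000L)  # the 1.2 Mb partner never counts
})

test_that("raising the edge threshold never enlarges a region", {
  fx <- ld_fixture(pos = 1e6 + c(-6e3, -2e3, 3e3, 8e3),
                   flips = c(30, 12, 20, 40))
  sizes <- vapply(c(0.3, 0.6, 0.8, 0.95), function(t) {
    b <- build_ld_block(fx$lead, fx$G, r2_edge = t)
    as.integer(b$end - b$start)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(sizes >= 3000L))
  expect_error(build_ld_block("v999", fx$G), "not found")
})

test_that("region screening assigns the documented evidence tiers", {
  blocks <- data.table::data.table(lead = "L1", chrom = "chr1",
                                   start = 0L, end = 10000L,
                                   left_dist = 5000L, right_dist = 5000L,
                                   n_partners = 2L, max_r2_left = 0.8,
                                   max_r2_right = 0.7)
  hap1 <- matrix(rep(c(0L, 1L), 8), 4, 4); hap2 <- matrix(0L, 4, 4)
  G <- make_genotypes(hap1, hap2, pos0 = c(100L, 200L, 300L, 20000L))
  callset <- data.table::data.table(variant_id = "v001", peak_id = "p")
  effects <- data.table::data.table(
    variant_id = c("v001", "v002"), cell_type = "CT",
    logfc = c(0.25, -0.6))
  gwas <- data.table::data.table(variant_id = "v002", p = 1e-9)
  sc <- screen_regions(blocks, G, callset, effects, gwas = gwas)
  rows <- sc$rows
  # callset variant with |logFC| = 0.25 reaches the predicted-callset tier
  expect_true(rows[variant_id == "v001", tier_callset_predicted])
  # non-callset variant with |logFC| = 0.6 and GWAS p < 5e-8
  expect_true(rows[variant_id == "v002", tier_model_strong])
  expect_true(rows[variant_id == "v002", gwas_sig])
  expect_true(sc$summary$gwas_support)
  # v004 lies outside every block
  expect_false("v004" %in% rows$variant_id)
  empty <- screen_regions(blocks[0], G, callset, effects)
  expect_equal(nrow(empty$rows), 0L)
})

test_that("causal GWAS leads are recovered in the predicted-callset tier", {
  co <- tiny_cohort()
  res <- tiny_pipeline()
  cfg <- tiny_cfg()
  G <- res$genotypes
  leads <- co$gwas[is_lead == TRUE & variant_id %in% G$variants$variant_id,
                   variant_id]
  expect_gte(length(leads), 5)
  blocks <- data.table::rbindlist(lapply(leads, function(l) {
    build_ld_block(l, G)
  }))
  genome <- simulate_genome_sequence(co$genotypes$variants, co$truth, cfg)
  model <- toy_pwm_model(list(CT = "TGACGTCA"))
  causal_peaks <- co$peaks[peak_id %in% co$truth$peak_id]
  vv <- co$genotypes$variants[variant_id %in% co$truth$variant_id]
  effects <- score_cohort_variants(model, causal_peaks, vv, genome,
                                   L = 514L)$effects
  sc <- screen_regions(blocks, G, res$callset, effects, eqtl = res$eqtl,
                       gwas = co$gwas)
  # every lead is itself a strong planted causal variant: blocks should be
  # recovered with callset + model support
  hit <- sc$summary[lead %in% leads]
  strong <- leads[leads %in% res$callset$variant_id &
                    leads %in% effects[abs(logfc) > 0.2, variant_id]]
  recovered <- sc$summary[tier_callset_predicted == TRUE, lead]
  expect_gte(length(strong), 3)
  expect_gte(mean(strong %in% recovered), 0.9)
})
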