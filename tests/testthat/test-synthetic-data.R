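test_that("haplotypes copied from two founders without recombination are perfectly correlated", {
  cfg <- cohort_config(n_donors = 25, genome = c(chr1 = 2e5),
                       n_founder_haplotypes = 2,
                       recombination_block_bp = 1e12, seed = 3)
  sim <- simulate_haplotypes(cfg)
  h <- sim$haplotypes
  poly <- which(apply(h, 2, var) > 0)
  expect_gt(length(poly), 10)
  # every polymorphic column is a copy (or mirror) of the founder indicator
  r2 <- abs(cor(h[, poly]))
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("haplotype simulation is deterministic in (config, seed)", {
  cfg <- cohort_config(n_donors = 10, genome = c(chr1 = 2e5), seed = 42)
  s1 <- simulate_haplotypes(cfg)
  s2 <- simulate_haplotypes(cfg)
  expect_identical(s1$haplotypes, s2$haplotypes)
  expect_identical(s1$variants, s2$variants)
})

test_that("r-squared decays with distance under block-wise founder copying", {
  cfg <- cohort_config(n_donors = 50, genome = c(chr1 = 1e6),
                       recombination_block_bp = 1e4, seed = 5)
  sim <- simulate_haplotypes(cfg)
  h <- sim$haplotypes
  pos <- sim$variants$pos0
  poly <- which(apply(h, 2, var) > 0)
  set.seed(1)
  idx <- sample(poly, 400)
  pr <- t(combn(sort(idx), 2))
  pr <- pr[sample(nrow(pr), 20000), ]
  d <- abs(pos[pr[, 1]] - pos[pr[, 2]])
  r2 <- vapply(seq_len(nrow(pr)), function(i) {
    cor(h[, pr[i, 1]], h[, pr[i, 2]])^2
  }, 0)
  near <- mean(r2[d < 1e3])
  far <- mean(r2[d > 1e5])
  expect_gt(near, far)
  # non-increasing trend over coarse distance bins
  bins <- cut(d, c(0, 2e3, 2e4, 2e5, Inf))
  mm <- tapply(r2, bins, mean)
  expect_true(all(diff(mm) <= 0.02))
})

test_that("generator errors on invalid configurations", {
  expect_error(cohort_config(genome = c(chr1 = 0)), "positive")
  expect_error(cohort_config(n_founder_haplotypes = 1), "at least 2")
  expect_error(cohort_config(frac_causal_peaks = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(methylation_coupling = 0.5), "<= 0")
})

test_that("fragment haplotype rates are symmetric without an effect", {
  co <- tiny_cohort()
  G <- co$genotypes
  # non-causal peaks: pooled hap1 vs hap2 fragment counts are balanced
  bg <- co$fragments[!peak_id %in% co$truth$peak_id]
  tab <- table(bg$hap)
  expect_lt(abs(tab[1] / sum(tab) - 0.5), 0.005)
})

test_that("ALT-haplotype fragment share matches the planted allelic proportion", {
  # one peak, one causal variant with b = ln(4) (pi = 0.8), deep coverage
  nd <- 12
  hap1 <- matrix(rep(c(1L, 0L), each = nd), nd, 2)
  hap2 <- matrix(0L, nd, 2)
  G <- make_genotypes(hap1, hap2, pos0 = c(1250L, 1300L))
  peaks <- data.table::data.table(peak_id = "peak_1", chrom = "chr1",
                                  start = 1000L, end = 1500L, summit = 1250L)
  truth <- data.table::data.table(
    variant_id = "v001", peak_id = "peak_1", cell_types = "CT", b = log(4),
    pi = 0.8, gene_id = NA_character_, gamma = NA_real_,
    meth_shift = 0, motif_offset = 1L)
  cfg <- cohort_config(n_donors = nd, cell_types = "CT",
                       cells_per_donor = 200, genome = c(chr1 = 1e4),
                       baseline_rate = 2, seed = 9)
  fr <- simulate_allelic_fragments(G, peaks, truth, cfg)
  # all donors are het with ALT on haplotype 1
  expect_gt(nrow(fr$fragments), 2000)
  alt_frac <- mean(fr$fragments$hap == 1L)
  expect_lt(abs(alt_frac - 0.8), 0.03)
})

test_that("fragment simulation rejects unobservable causal variants", {
  nd <- 6
  hap1 <- matrix(1L, nd, 1); hap2 <- matrix(0L, nd, 1)
  G <- make_genotypes(hap1, hap2, pos0 = 5000L)
  peaks <- data.table::data.table(peak_id = "peak_1", chrom = "chr1",
                                  start = 1000L, end = 1500L, summit = 1250L)
  truth <- data.table::data.table(
    variant_id = "v001", peak_id = "peak_1", cell_types = "CT", b = 1,
    pi = 0.73, gene_id = NA_character_, gamma = NA_real_,
    meth_shift = 0, motif_offset = 1L)
  cfg <- cohort_config(n_donors = nd, cell_types = "CT",
                       genome = c(chr1 = 1e4), seed = 1)
  expect_error(simulate_allelic_fragments(G, peaks, truth, cfg),
               "unobservable")
  truth$variant_id <- "missing"
  expect_error(simulate_allelic_fragments(G, peaks, truth, cfg), "absent")
})

test_that("written cohort files are consistent and reproducible", {
  cfg <- cohort_config(n_donors = 15, genome = c(chr1 = 4e5),
                       cells_per_donor = 30, seed = 21)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  man1 <- generate_cohort(cfg, d1, write_genome = FALSE)
  man2 <- generate_cohort(cfg, d2, write_genome = FALSE)
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
  # determinism: byte-identical outputs
  for (f in c("genotypes.vcf", "fragments.tsv", "ground_truth.tsv",
              "expression_counts.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # VCF sample count = metadata donor count = covariate rows
  hdr <- grep("^#CHROM", readLines(file.path(d1, "genotypes.vcf")),
              value = TRUE)
  vcf_donors <- length(strsplit(hdr, "\t")[[1]]) - 9L
  cov <- data.table::fread(file.path(d1, "covariates.tsv"))
  meta <- data.table::fread(file.path(d1, "cell_metadata.tsv"))
  expect_equal(vcf_donors, 15)
  expect_equal(nrow(cov), 15)
  expect_equal(length(unique(meta$donor)), 15)
  # every causal variant appears in the VCF at its stated position
  truth <- data.table::fread(file.path(d1, "ground_truth.tsv"))
  G <- read_phased_vcf(file.path(d1, "genotypes.vcf"))
  expect_true(all(truth$variant_id %in% G$variants$variant_id))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("methylation decreases with the dosage of the accessibility-raising allele", {
  co <- tiny_cohort()
  G <- co$genotypes
  truth <- co$truth
  M <- build_methylation_phenotypes(co$methylation, co$peaks)
  slopes <- vapply(seq_len(nrow(truth)), function(i) {
    fid <- paste0(truth$peak_id[i], "_meth")
    if (!fid %in% M$features$feature_id) return(NA_real_)
    # dosage of the accessibility-increasing allele
    g <- G$dosage[, truth$variant_id[i]]
    if (truth$b[i] < 0) g <- 2 - g
    means <- tapply(M$values[, fid], g, mean)
    if (length(means) < 2) return(NA_real_)
    unname(coef(lm(as.numeric(means) ~ as.numeric(names(means))))[2])
  }, 0)
  slopes <- slopes[!is.na(slopes)]
  expect_gt(length(slopes), 5)
  expect_true(mean(slopes < 0) > 0.9)
})

test_that("pooled het-donor ALT fraction converges to the planted proportion", {
  co <- tiny_cohort()
  G <- co$genotypes
  for (i in seq_len(min(5, nrow(co$truth)))) {
    tr <- co$truth[i]
    vi <- match(tr$variant_id, G$variants$variant_id)
    het <- which(G$hap1[, vi] != G$hap2[, vi])
    cts <- strsplit(tr$cell_types, ",")[[1]]
    fr <- co$fragments[peak_id == tr$peak_id & donor %in% G$donors[het] &
                         cell_type %in% cts]
    alt_hap <- ifelse(G$hap1[cbind(match(fr$donor, G$donors), vi)] == 1L,
                      1L, 2L)
    x <- sum(fr$hap == alt_hap); n <- nrow(fr)
    se <- sqrt(tr$pi * (1 - tr$pi) / n)
    expect_lt(abs(x / n - tr$pi), 3 * se + 0.01)
  }
})
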