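# Shared fixtures: cohorts are simulated once per test run and cached in this
# environment so several test files can reuse them.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small cohort for unit tests: 40 donors, 2 Mb, 100 peaks, ~20 causal variants
tiny_cfg <- function(seed = 7) {
  cohort_config(n_donors = 40, genome = c(chr1 = 2e6), cells_per_donor = 80,
                peak_density = 5, seed = seed)
}

tiny_cohort <- function() cached("tiny_cohort", simulate_cohort(tiny_cfg()))

tiny_pipeline <- function() cached("tiny_pipeline", {
  # 10 phenotype PCs: at ~100 features the 30-PC default would absorb the
  # per-peak genotype effects themselves
  suppressMessages(run_pipeline(pipeline_config(cohort = tiny_cfg(),
                                                n_pheno_pcs = 10L),
                                cohort = tiny_cohort()))
})

# minimal hand-built phased genotype objects for boundary fixtures
make_genotypes <- function(hap1, hap2, pos0 = NULL, chrom = "chr1",
                           phase_set = NULL, donors = NULL,
                           ref = NULL, alt = NULL, is_indel = NULL) {
  nd <- nrow(hap1); nv <- ncol(hap1)
  donors <- donors %||% sprintf("D%03d", seq_len(nd))
  pos0 <- pos0 %||% (seq_len(nv) * 100L)
  variants <- data.table::data.table(
    variant_id = sprintf("v%03d", seq_len(nv)), chrom = chrom,
    pos0 = as.integer(pos0),
    ref = ref %||% rep("A", nv), alt = alt %||% rep("G", nv),
    is_indel = is_indel %||% rep(FALSE, nv))
  ps <- phase_set %||% matrix(1L, nd, nv)
  phased_genotypes(donors, variants, hap1, hap2, ps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
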