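---
title: "Discovering cis-regulatory variants from single-cell chromatin accessibility"
author: "ascaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cis-regulatory variants from single-cell chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascaqtl)
library(data.table)
```

## The problem

A genetic variant that alters a transcription-factor binding site can change
how open the surrounding chromatin is — in *cis*, on the same DNA molecule.
Single-cell ATAC-seq cohorts make two complementary measurements of this
possible:

* **caQTL mapping.** Aggregate fragments per donor and cell type
  ("pseudobulk"), and regress normalised peak accessibility on the donor's
  ALT-allele dosage \(g \in \{0,1,2\}\) with covariates. A nonzero slope
  indicates an accessibility QTL, but it is exposed to any confounder that
  co-varies with genotype across donors.
* **Allele-specific chromatin accessibility (ASCA).** Within a donor
  heterozygous at a variant, the two haplotypes share the same nucleus, so
  *trans* and technical effects cancel. If reads overlapping heterozygous
  sites in a peak come disproportionately from the haplotype carrying the
  ALT allele, the variant (or something phased with it) acts in *cis*.

Variants supported by both tests at FDR < 0.1 form the high-confidence
callset. Two further layers cross-check it: CpG methylation QTLs (expected
to move *against* accessibility), and a sequence model scored by in-silico
mutagenesis (ISM), which predicts the variant's effect from sequence alone.
Finally, LD-proximity regions around GWAS lead variants are screened for
callset and model-predicted variants.

`ascaqtl` implements this entire chain, together with a synthetic cohort
generator with known ground truth, so every stage is testable end to end
without any external data.

## The models

### Pseudobulk cis-QTL

For each (variant, feature, cell type) the model is ordinary least squares,

\[ y_d = \mu + \beta_g g_d + X_d \gamma + \varepsilon_d, \]

with \(y\) the log1p-CPM phenotype, computed by the Frisch–Waugh route:
both \(y\) and \(g\) are residualised on \([1, X]\) and the slope is the
simple regression of the residuals, with `dof = n - rank([1, X]) - 1` so it
is numerically identical to the joint fit (this equivalence is oracle-tested
to 1e-10). Covariates are age, sex, batch, assay modality, 5 genotype PCs
and (for accessibility) 30 phenotype PCs. Cis windows are feature-kind
specific: SNPs must fall inside the peak while indels get a ±200 bp margin;
genes use ±1 Mb from the gene body; methylation bins use a 10 kb window.
Window arithmetic is 0-based half-open throughout; the eQTL window anchors
at gene-body start/end, not the TSS.

p-values are two-sided t with explicit degrees of freedom (the nominal-pass
behaviour of standard QTL mappers). Benjamini–Hochberg correction is applied
once over the full concatenation of tests per assay — all cell types pooled
— never per stratum.

### The allele-specific test

For heterozygous donor \(d\), \(y_d\) of \(n_d\) allele-informative reads
come from the haplotype carrying the test variant's ALT allele. Counts from
all heterozygous helper variants in the 500 bp summit window are summed
after orienting each onto the test variant's haplotypes via the phase-set
(PS) information; helpers in a different or missing phase set are skipped,
and donors unphased at the test variant are excluded.

The counts are modelled as beta-binomial. Writing \(\alpha\) for the
REF-haplotype and \(\beta\) for the ALT-haplotype shape parameter, the
reported imbalance

\[ \iota = \beta / (\alpha + \beta) \]

is the expected ALT-haplotype read share: \(\iota = 0.5\) is balance and
\(\iota > 0.5\) means the ALT haplotype is more accessible, matching the
sign of the caQTL slope. \(\hat\alpha, \hat\beta\) are the free
two-parameter maximum-likelihood fit (deterministic: method-of-moments
start, optimisation on \(\log\alpha,\log\beta\) mirrored onto the minority
side so allele swap is an exact symmetry, concentration clipped at 1e7
where the model is numerically binomial).

**Calibration and shared dispersion.** Testing \(\iota = 0.5\) with a
likelihood ratio requires care at cohort-realistic group sizes. With the
overdispersion re-estimated inside every 5–10-donor test, the 1-df
\(\chi^2\) reference is miscalibrated in both directions (inflated for
overdispersed nulls, conservative for binomial ones); with ~50 donors per
test it calibrates. `asca_map()` therefore estimates one genome-wide
concentration — the median of the per-test free-fit \(\hat\alpha +
\hat\beta\) — and computes the LRT with the concentration fixed, leaving a
single free mean under the alternative. This mirrors how the combined
haplotype test lineage handles overdispersion (genome-wide, not per test)
and restores the nominal size (measured 0.045–0.053 at \(\alpha = 0.05\)
with 8 donors). The fully per-test variant remains available via
`as_cht_test(conc = NULL)`.

Tests require at least 5 heterozygous donors and 50 allele-specific reads;
below either threshold the group is reported untestable, never silently
fitted.

### Mappability filtering

Reads overlapping heterozygous sites are re-evaluated with every allele
combination substituted (Cartesian product, capped at \(2^6 = 64\)
versions; reads spanning more than 6 het sites are discarded and tallied).
A read is retained only if every version maps to the original locus with
mapping quality strictly above 10. The aligner is an injectable oracle so
the filter's logic is testable without a real read simulator; indel
substitutions shift downstream in-read coordinates.

### Variant-effect scoring

`build_ref_alt_inputs()` constructs fixed-length (default 2114 bp)
summit-centred REF/ALT windows. Indels keep both windows at exactly L bp by
recruiting (deletions) or trimming (insertions) flanking bases split as
evenly as possible, the odd base downstream. The scoring model is an
interface — any pure function from sequence to one positive scalar per cell
type. The bundled `toy_pwm_model()` scores the best-window PWM match per
motif through a softplus link; it is analytically evaluable, which turns
every ISM test into an exact oracle comparison (to 1e-9), and the cohort
generator plants its causal alleles inside motif occurrences so planted
direction is recoverable from sequence. Gene-level effects aggregate
base-resolution predictions over exon-overlapping bins (a bin counts when
its start lies in an exon) per cell type, with the `log2(x + 1)` link, and
report ALT − REF.

### GWAS LD-block screening

\(r^2\) is the squared Pearson correlation of phased 0/1 haplotype vectors.
Blocks around lead variants take candidate partners within ±1 Mb with MAF ≥
0.001 and \(r^2 \ge 0.05\); the region runs to the furthest partner with
\(r^2 \ge 0.6\) on each side, floored at 1,500 bp per side, so the minimal
region is exactly 3,000 bp. Screening tiers: callset variant in block;
callset ∧ |model logFC| > 0.2; additionally eQTL q < 0.05; and model-only
tiers at |logFC| > 0.2 / 0.5 sub-flagged by GWAS p < 5e-8.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions for all cohort-level checks: 80 donors, 2 × 5 Mb autosomes,
5 variants/kb (≈7% short indels), 500-bp consensus peaks at 5/100 kb, three
cell types with ~70 cells per donor each, 20% of peaks causal with
\(|b| \sim N(1.2, 0.25)\) (truncated at 0.3, random sign), methylation
coupling \(\kappa = -2\), expression coupling \(\gamma = 0.5\).

* **Haplotypes.** Donor haplotypes are copied block-wise from 12 founder
  haplotypes with exponentially distributed block lengths (mean 20 kb),
  giving monotone \(r^2\) decay with distance — enough LD structure for
  block construction without a coalescent simulator.
* **Fragments.** Per donor, cell type, peak and haplotype,
  counts are Poisson with rate \(\tfrac12\,\lambda_{\text{peak,ct}}\,
  \text{depth}_d\, e^{b a_h}\), where \(a_h\) is the ALT count of the causal
  variant on haplotype \(h\). The expected ALT-haplotype read share in a
  heterozygote is therefore \(\pi = e^b/(1+e^b)\). Fragments are emitted as
  intervals with per-fragment (variant, allele) annotations standing in for
  sequence; the haplotype label itself lives only in a truth sidecar, so the
  counting code must genuinely recover haplotypes through phased alleles.
* **Methylation.** CpG fractions follow
  \(\mathrm{logistic}(\mathrm{logit}(m_0) + \kappa\, b\, g/2)\) plus noise,
  so with \(\kappa < 0\) methylation falls as the dosage of the
  accessibility-raising allele rises.
* **Expression.** Donor × gene negative-binomial counts whose log-mean
  shifts by \(\gamma b g\) for genes linked to a causal variant within
  200 kb.
* **Sequence.** The genome is random with every REF allele written in; at
  causal variants the planting motif is embedded such that the
  accessibility-raising allele completes the consensus and the lowering
  allele breaks it.

Determinism: identical `(config, seed)` reproduce every output file
byte-identically; all stage seeds derive from the single config seed.

What the generator does *not* emulate — realistic read sequences and
qualities, doublets, ambient contamination, copy-number variation, cell-type
abundance imbalance, fine-scale recombination hotspots. Passing tests
therefore demonstrate correctness of the statistical machinery and its
thresholds, not robustness to every artefact of real snATAC data.

## Numerical and design choices

* Missing genotypes (`./.`) decode as homozygous reference (the
  cohort-merge convention); this deflates MAF at poorly covered sites and is
  deliberately loud in the documentation. MAF and HWE are both recomputed on
  whatever donor subset is analysed.
* HWE uses the exact conditional test (plain p, no mid-p), enumerated over
  all heterozygote counts; multiallelic records are dropped, not split.
* The conjunction callset requires significance in the *same* cell type in
  both assays (strictest reading); an any-cell-type mode is available behind
  a flag.
* Phenotype-PC covariates are auto-capped to preserve residual degrees of
  freedom (`k ≤ n_donors − reserve − 3`). At very small feature counts
  (~100 peaks) even fewer PCs are advisable: with so few features the top
  components align with the planted per-peak effects themselves and absorb
  them. At the default scale (500 peaks, 80 donors) the full 30 PCs leave
  recovery intact.
* With \(\kappa = 0\) essentially no callset variant passes the nominal
  meQTL filter (p < 1e-3), so the null-coupling diagnostic computes the
  slope correlation over all callset × meQTL pairs instead; with coupling
  the filtered and unfiltered versions agree in sign.
* Unphased-but-inferable helper variants are excluded from ASCA counting
  rather than rescued; reads spanning >6 het sites are discarded with a
  counter.
* Problem sizes in the test-suite and acceptance script (80-donor cohorts,
  2,000-test calibration runs, 25 replicates per recovery point) were chosen
  as the smallest sizes at which the measured properties are stable.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- cohort_config(n_donors = 40, genome = c(chr1 = 2e6),
                     cells_per_donor = 80, seed = 7)
res <- run_pipeline(pipeline_config(cohort = cfg, n_pheno_pcs = 10))
res$summary
concordance_stats(attr(res$callset, "detail"))
```

`run_pipeline()` chains simulation, genotype QC, the three QTL assays, ASCA,
integration and the GWAS screen; each stage's record counts land in
`res$summary`, and `scripts/acceptance.R` (see the README) recomputes the
headline quantities from scratch on fresh cohorts.

## Known limitations

* The ASCA counting path consumes the generator's (variant, allele)
  fragment annotations; plugging in real BAM-derived allelic counts requires
  producing the same long-format table from a pileup.
* The sequence-model interface ships only the analytic toy model; trained
  deep models are out of scope by design and can be plugged in behind
  `predict_accessibility()`.
* Conditional/independent-signal mapping, permutation-based empirical
  p-values, colocalisation and fine-mapping are out of scope.
* The LD-block construction assumes phased genotypes; a genotype-correlation
  fallback covers unphased input but is not the primary path.
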