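Package: ascaqtl
Title: Cis-Regulatory Variant Discovery from Single-Cell Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cis-acting regulatory variants from single-cell ATAC-seq
    cohorts by combining two orthogonal lines of evidence: pseudobulk cis-QTL
    linear mapping of chromatin accessibility, expression and CpG methylation
    against genotype dosage, and a phased beta-binomial test of allele-specific
    chromatin accessibility (ASCA) within heterozygous donors. Provides
    allele-swap mappability filtering, haplotype-oriented allelic counting,
    integration of the two callsets with concordance diagnostics, in-silico
    mutagenesis variant-effect scoring against a pluggable sequence model, and
    LD-block screening of GWAS loci. Ships a synthetic cohort generator with
    known ground truth (phased genotypes with linkage disequilibrium, per-cell
    fragments, methylation anti-coupled to accessibility, expression coupled to
    enhancer effects) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
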