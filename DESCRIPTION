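Package: svld
Title: Consensus Filtering of Structural Variants and Their Linkage
    Disequilibrium to SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building a high-confidence structural-variant (SV)
    callset from multiple short-read callers and for quantifying how well
    nearby SNPs capture SV alleles in livestock populations. Implements a
    breakpoint-tolerant consensus merge, a five-rule filtering procedure
    (caller overlap, genotype concordance, high-coverage region masking,
    flanking read-depth fold change, SNP support on deletions), phased-
    haplotype linkage disequilibrium (r2), its allele-frequency-standardized
    form (r2 divided by the maximum r2 attainable given the minor-allele
    frequency difference), distance-binned decay curves with bootstrap
    confidence intervals, tag-SNP analysis against whole-genome or array SNP
    pools, Hardy-Weinberg exact testing, and a founder-mosaic simulator that
    generates phased SNP+SV panels, per-caller error-prone callsets and
    windowed depth profiles so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
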