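# svld

Consensus filtering of structural variants (SVs) and analysis of their
linkage disequilibrium (LD) to SNPs.

## The problem

Structural variants — deletions (DEL), duplications (DUP), inversions
(INV) and translocation breakpoints (BND) — are hard to call accurately
from short-read sequencing, yet they carry real phenotypic signal in
livestock genetics. Two practical questions follow for anyone running
genomic prediction or GWAS on SNP panels:

1. **Can we build a trustworthy SV callset** by demanding agreement
   between several callers and cross-checking genotypes against read
   depth and SNP calls?
2. **Do nearby SNPs capture SV alleles** well enough (strong LD, good tag
   SNPs) that a separate SV analysis is unnecessary?

`svld` implements both: a five-rule consensus-filtering pipeline for
multi-caller SV callsets, and the LD/taggability machinery to answer the
second question — plus a founder-mosaic simulator that generates phased
SNP+SV panels with realistic population structure, so the whole pipeline
runs and is testable without any external data.

## The statistics at the core

For two loci with alternative-allele frequencies $p_A$, $p_B$ and
haplotype frequency $p_{AB}$, LD is the squared haplotype correlation

$$ r^2 = \frac{(p_{AB} - p_A p_B)^2}{p_A p_B (1-p_A)(1-p_B)} $$

Its ceiling depends on how different the two minor allele frequencies
are: $r^2_{max}$ is $r^2$ evaluated at the Fréchet bound of $p_{AB}$
(`r2max()` evaluates both bounds exactly — the quadratic's maximum over
the feasible interval is at an endpoint). The standardized coefficient
$r^2_S = r^2 / r^2_{max}$ measures LD with the allele-frequency
constraint removed; comparing class-wise $r^2$ and $r^2_S$ decay curves
(relative to the SNP–SNP baseline) attributes LD differences to local
MAF differences versus genotype quality.

Tag-SNP analysis uses $r^2_{tag}$, the maximum $r^2$ between a focal
variant and a pool of candidate SNPs within a distance; a variant counts
as *tagged* when $r^2_{tag} > 0.75$. Genotype quality is screened with a
Hardy–Weinberg exact test (Levene–Haldane conditional distribution,
two-sided by probability ordering) and with the duphold-style flanking
fold change (DHFFC), the ratio of windowed coverage inside a DEL/DUP to
its flanks.

The filtering pipeline applies, in order: (1) support by ≥ 2 of 3
callers after a 1000 bp breakpoint-tolerant merge, (2) 2-of-3 genotype
concordance with at most 2 discordant samples, (3) removal of SVs whose
breakpoint confidence intervals touch regions with coverage above
2·mean + 2·SD (windows merged when < 1000 bp apart), (4) DHFFC genotype
consistency (het DEL in [0.1, 0.9], hom DEL < 0.25, het DUP > 1.1, hom
DUP > 1.5; more than one wrong genotype or > 10 % wrong removes the SV),
and (5) SNP-call support on deletions (SNP calls must be homozygous on
het DELs and missing on hom DELs).

## Worked example

Simulate a small three-population study, run the consensus filter, and
inspect the per-rule report:

```r
library(svld)

st <- simulate_study(sim_config(
  seed = 7, chrom_lengths = c(chr1 = 2e6),
  n_samples = c(WL = 15L, BL = 15L, BR = 20L),
  sv_counts = c(DEL = 40L, DUP = 12L, INV = 12L, BND = 8L)
))
fr <- run_filter_pipeline(
  st$callsets, st$depth, st$snp_calls, st$snp_panel$variants,
  genome = st$genome
)
fr$report
#>                    rule input removed retained genotypes_set_missing
#> 1        caller_overlap    72       0       72                     0
#> 2  genotype_concordance    72       2       70                     0
#> 3 high_coverage_regions    70       0       70                     0
#> 4                 dhffc    70      12       58                    11
#> 5       del_snp_support    58       0       58                     0
```

Each row conserves counts (`input = removed + retained`). Here the
default caller-error rates cost two SVs at the concordance rule and
twelve at the DHFFC rule; eleven individual genotypes were set missing
for later re-imputation rather than discarding their SVs.

An exact Hardy–Weinberg test on genotype counts (homref, het, homvar):

```r
h <- hwe_exact(c(30, 18, 1))
c(p = h$p, deviation = h$deviation)
#> p: 0.661  deviation: -1.04
```

`deviation` is the observed count of homozygous-variant genotypes minus
the Hardy–Weinberg expectation $nq^2$ — here one observed versus 2.04
expected, a (non-significant) homozygote deficit of the kind that flags
systematic genotyping problems in DUP/INV/BND calls.

The full analysis — filter, fill/phase, LD decay per population,
relative LD, ΔMAF, taggability, HWE scan — runs as one call and writes
TSVs plus a results index:

```r
run <- run_all(sim_config(seed = 1), desk_run_config(seed = 1), out_dir = "out")
run$relative_pooled   # per-class r2 / r2s relative to SNP-SNP, pooled
run$shares            # tagged shares per class and population
```

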