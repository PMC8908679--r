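---
title: "Methods: consensus SV filtering, LD standardization, and the founder-mosaic simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus SV filtering, LD standardization, and the founder-mosaic simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`svld`: what each stage computes, which knobs matter, what the synthetic
data generator does and does not emulate, and the numerical decisions a
maintainer would otherwise have to reverse-engineer.

## Coordinates and containers

All internal coordinates are 0-based, half-open `[start, end)`; the VCF
boundary converts to and from 1-based `POS`/`END`. SNPs and BNDs are
point records (`end = start + 1`); a BND carries a single breakpoint and
no length. Genotypes are dosages in {0, 1, 2, NA}; phased panels
(`haplotype_panel`) are complete 0/1 matrices with two haplotype rows per
sample and exist only after the fill/phasing stage — missingness never
enters a panel silently. Multi-allelic SNP rows are rejected at the VCF
reader: every analysis here assumes bivariate variants.

## The filtering pipeline

The consensus merge chains calls of the same type and chromosome greedily
left-to-right, linking a call to a chain when both breakpoints lie within
the tolerance (default 1000 bp) of the previous member; BNDs compare only
their single breakpoint. Canonical breakpoints are per-chain medians,
taking the lower value on even ties. Whether the tolerance should
apply to each breakpoint separately or to a composite distance is
underdetermined; the both-breakpoints reading is the stricter and is
what we implement.

Rules are applied in a fixed order and every rule's report row conserves
`input = removed + retained`:

1. **Caller overlap** — at least 2 of 3 callers.
2. **Genotype concordance** — per sample, the consensus genotype is the
   value shared by ≥ 2 supporting callers; no 2-vote value means the
   genotype is set missing; more than 2 such samples removes the SV.
3. **High-coverage regions** — a window is flagged when its cross-sample
   mean coverage strictly exceeds `2·μ + 2·σ`. We parse the threshold as
   two separate terms (not `2(μ+σ)`), and define σ as the SD of the
   cross-sample window means over all autosomal windows — the rule does
   not pin down across what the SD is taken, and the
   window-mean reading makes the threshold a property of the genome-wide
   coverage profile rather than of per-sample noise. Flagged windows
   < 1000 bp apart merge; an SV is removed when the half-open interval
   `[bp−ci, bp+ci)` around either breakpoint intersects a region.
4. **DHFFC** — median windowed coverage inside the span over the pooled
   median of the two 1000 bp flanks. Bounds: het DEL valid in
   the closed interval [0.1, 0.9], hom DEL strictly < 0.25, het DUP
   strictly > 1.1, hom DUP strictly > 1.5. Reference genotypes are never
   tested (the rule's bounds only address variant genotypes). More
   than one wrong genotype, or > 10 % wrong among tested, removes the SV;
   otherwise wrong genotypes are set missing.
5. **SNP support on DELs** — SNP calls inside a deletion must be
   homozygous on het-DEL and missing on hom-DEL samples. The per-sample
   error rate is `violations / SNPs-on-the-DEL`. A worked example that
   circulates with this rule gives 0.1 for one error among five SNPs,
   conflicting with the simple ratio (1/5 = 0.2) and suggesting
   per-allele counting;
   both readings are implemented and `snp_support_halved = TRUE` selects
   the per-allele one. The simple ratio is the default because it is the
   literal reading of the rule's own wording.

INV and BND bypass rules 4–5: they produce no usable coverage signal,
which is precisely why their genotypes are the least trustworthy — the
pipeline can express that only as "cannot test", not as "verified".

**Fill and phasing stand-in.** Statistical imputation/phasing (beagle in
the original workflow) is out of scope. `fill_missing_genotypes()` fills
each missing genotype from the variant's non-missing allele frequency and
phases heterozygotes randomly, deterministically given a seed. Random
phasing is the correct *null* for filled genotypes but would be an unfair
caricature of statistical phasing for observed heterozygotes — real
phasing recovers phase from LD with high accuracy at these panel sizes —
so the function accepts a `phase_hint` matrix and `run_all()` passes the
simulator's true phases for genotypes whose value matches the truth.
Genotypes altered by error channels or filled from frequencies get no
hint and are phased randomly, so genotype errors still degrade
haplotype-level LD, as they do in real data.

## LD estimation

`r2` is the squared haplotype correlation computed from phased 0/1
vectors; on such vectors the sample correlation equals the
frequency-based formula exactly, so the vectorized engine uses
cross-products. `r2max` evaluates the quadratic at both Fréchet bounds of
the haplotype frequency — exact, no grid search — and `r2s = r2/r2max`
(clipped only against ≤ 1e−12 floating-point overshoot; a larger
overshoot is an error, not a clip).

Pairing rules: SV–SNP distance is the distance from the SNP to the
*nearest breakpoint* (an SV's interior is not "far away" — its
breakpoints are where the SNP information lives); SNPs located on an SV
are excluded for that SV only, since the stated concern (SV-corrupted SNP
calls) is specific to the overlapping SV. Pairs beyond 100 kb and
monomorphic-in-population variants are skipped; all LD is
within-population.

Decay bins are upper-closed 500 bp bins (a 500 bp pair is in bin 1, so
"within 500 bp" equals bin 1). The streaming engine keeps per-bin
accumulators so memory is independent of the pair count; per-bin values
are retained only up to the 1 M skip threshold, beyond which the
bootstrap CI is skipped anyway (with > 1 M values the interval is
degenerate at the printed precision). Bootstrap CIs are percentile
intervals from resampling within the bin, Bonferroni-corrected at
`0.05 / n_bins` with `n_bins` the bin-grid size (200 at 100 kb / 500 bp).
CIs are computed for both `r2` and `r2s` bins.

Relative LD expresses each of the first ten SV-class bin means as a
percentage of the matching SNP–SNP bin mean; the summary is the mean ± SD
*across the ten bin ratios* (across-bin SD is the only ±SD
computable from binned data, and is what we report).
The Δ column is relative `r2s` minus relative `r2` — how much of the LD
gap allele-frequency standardization closes. The pooled ("All") summary
pools pairs across populations via n-weighted bin means rather than
averaging the three per-population ratios, which would weight a sparse
population's noise equally with a dense one's signal.

## Taggability

`r2_tag` is the running maximum r² to a pool of variable SNPs, evaluated
on a distance grid (default 1–100 kb in 1 kb steps); ties resolve to the
smaller distance, then the smaller coordinate. Variants with no pool SNP
within the distance count as *untagged* in `share_tagged()` (availability
is a separate statistic) — dropping them would overstate taggability
exactly where pools are thin. The on-SV exclusion rule is the same as in
the LD analysis. Array pools are the exact (chromosome, position)
intersection of the WGS pool with a manifest. The compact letter display
for density comparisons uses greedy insert-and-absorb; any correct CLD
yields the same significant/non-significant partition.

## Hardy–Weinberg exact test

The test conditions on the observed minor-allele count; configuration
probabilities are proportional to the multinomial coefficient times
`2^n_het`, and the two-sided p sums all configurations no more probable
than the observed one (the standard exact-test convention; mid-p is not
used). The test suite checks the implementation against the
Levene–Haldane closed form — a different algebraic route to the same
distribution — exhaustively for all n ≤ 20. Bonferroni correction is
applied within SV class (the class sizes differ by an order of
magnitude; correcting across classes would let the large DEL class
swamp the small BND class).

The `deviation` statistic is observed homozygous-variant count minus
`n·q²` with q the variant-allele frequency; a systematic hom→het
genotyping deficit shows up as near-exclusively negative deviations among
significant tests.

## The synthetic-data generator

Haplotypes are mosaics of K founder haplotypes: along a chromosome, each
haplotype copies one founder per segment, with exponential segment
lengths of mean L. Two loci share founder ancestry with probability
decaying on scale L, so SNP–SNP r² decays with distance, and the
short-range LD level is set by the founder count (≈ 1/(K−1) for random
founder alleles). This is deliberately *not* a coalescent simulator: the
analyses need decay-shaped, magnitude-controllable LD, not demographic
realism. Three populations are generated independently on shared variant
positions with (K, L) = WL (3, 60 kb), BL (4, 40 kb), BR (6, 25 kb),
reproducing the WL > BL > BR LD ordering; per-population founder alleles
give realistic allele-frequency differentiation. SNP base frequencies are
Beta(0.5, 1.5) — a rare-heavy spectrum, as in WGS SNP data.

SVs are planted on *founder-subset backgrounds*: the carriers are exactly
the haplotypes whose ancestry at the SV position falls in a founder
subset whose combined frequency is nearest a per-type target MAF draw.
Before any resampling the SV is therefore in complete LD with its local
backbone. Each class then gets the mechanism the real callset displays:

* **DEL** — mostly background-coupled (15 % are resampled by a mild
  relative carrier drop, mean ≈ 17 %): DEL–SNP LD matches SNP–SNP LD and
  the MAF spectrum is slightly rare-shifted.
* **DUP** — resampled to rare targets (Beta(1, 6)): a strong local ΔMAF
  that caps r² but leaves r²_S high, plus a 0.45 hom→het miscall rate.
* **INV/BND** — resampled to common targets (Beta(4, 2), folded at 0.5),
  far from the rare SNP bulk (large ΔMAF), with strong hom→het miscall
  rates (0.6/0.65) and systematic random genotype noise (0.06/0.08)
  shared by all callers. The shared channels are deliberate: independent
  per-caller errors are repaired by 2-of-3 voting, so only a common-mode
  genotyper deficit can survive into the filtered callset, which is what
  the homozygote-deficit observation implies.
* **SNP thinning** — backbone SNPs within 5 kb of an SV span are removed
  with per-type probabilities (DEL 0.5, DUP 0.45, INV 0.35, BND 0.15),
  emulating the reduced SNP density observed around SVs; this is what
  makes SNPs slightly better tagged than DELs while their LD decay
  curves coincide.

Depth is Normal per 100 bp window, truncated at zero (the window-mean
scale justifies Gaussian over Poisson noise; SD is configurable), with
dosage factors 1/0.5/0 inside DELs and 1/1.5/2 inside DUPs applied to
fully-contained windows, per-sample means uniform on 5–17×, and optional
artifact regions multiplying all samples by a fold. SVs are planted with
a minimum 2.5 kb spacing so each SV's coverage signal (span and flanks)
is attributable to it alone. `error_free()` switches off every stochastic
corruption channel — sensitivity, jitter, all genotype error channels,
SNP-call errors, artifacts *and* depth noise — and on such data the
filtering pipeline is provably the identity, which the tests assert.

What the generator does **not** emulate: recurrent mutation and NAHR
hotspots, multi-copy CNVs, insert-size/read-level signal, reference
errors, recombination-rate variation, selection. Passing tests therefore
demonstrate that the *pipeline logic* behaves as specified under the
planted mechanisms, not that the pipeline would achieve any particular
precision on real sequencing data.

## Problem sizes and numerical choices

The desk-scale preset (`sim_config()` defaults plus `desk_run_config()`)
uses 2 × 5 Mb chromosomes, ~15 k SNPs, ~300 SVs, 75 samples, LD decay to
10 kb (the relative-LD summary needs only the first ten 500 bp bins), a
500-resample bootstrap and a 250-SNP sampled baseline for tag curves; a
full run takes about half a minute. These sizes were chosen so that the
class-level LD contrasts are resolvable above Monte-Carlo noise while a
complete run remains interactive; all constants scale up through the
configuration objects, whose defaults are the standard analysis constants
(100 kb, 500 bp bins, 100,000 bootstrap resamples, tag threshold 0.75,
5 kb density window).

Seeds: one top-level seed fans out to fixed per-stage seeds
(`derive_seed()`), so any stage can be re-run in isolation with identical
results and all outputs are byte-reproducible. Ties and degenerate
inputs: merge ties take the lower coordinate; zero-variance regressions
report p = 1 on the identity line; fully tied rank-sum comparisons report
p = 1; a DHFFC with zero flank median is undefined (NA) and untested
rather than wrong.

## Known limitations

* The chromosome-bias regression is fitted per variant type; a pooled
  regression across types is not implemented.
* The merge assumes at most one call per caller per chain and keeps the
  leftmost otherwise; pathological overlapping chains from one caller
  are resolved greedily, not optimally.
* `r2_tag` availability and the tagged share treat "no pool SNP" as
  untagged; no separate availability curve is emitted.
* The phasing stand-in leans on simulator truth for observed
  heterozygotes; with real (non-simulated) data `fill_missing_genotypes()`
  without a hint randomizes het phase and will underestimate SV–SNP LD —
  real data should be phased with a dedicated tool before import.
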