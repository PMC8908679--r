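# Fixtures shared across the suite. Everything is generated in code.

# a small simulation configuration that runs in a couple of seconds
tiny_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    chrom_lengths = c(chr1 = 1e6),
    n_samples = c(WL = 10L, BL = 10L, BR = 12L),
    sv_counts = c(DEL = 20L, DUP = 8L, INV = 8L, BND = 6L)
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# hand-built variant table: 4 SNPs and one SV of each class on one chromosome
toy_variants <- function() {
  variant_table(
    id = c("s1", "s2", "s3", "s4", "d1", "u1", "i1", "b1"),
    chrom = "chr1",
    start = c(100L, 300L, 900L, 5000L, 1000L, 2000L, 3000L, 4000L),
    end = c(101L, 301L, 901L, 5001L, 1500L, 2600L, 3900L, 4001L),
    vtype = c("SNP", "SNP", "SNP", "SNP", "DEL", "DUP", "INV", "BND"),
    ci_start = c(0L, 0L, 0L, 0L, 50L, 50L, 50L, 50L),
    ci_end = c(0L, 0L, 0L, 0L, 50L, 50L, 50L, 50L)
  )
}

# deterministic phased panel over the toy variants for 4 samples
toy_panel <- function() {
  v <- toy_variants()
  set.seed(42)
  al <- matrix(rbinom(8L * nrow(v), 1L, 0.5), nrow = 8L)
  # ensure every column is polymorphic
  al[1L, colSums(al) == 0L] <- 1L
  al[1L, colSums(al) == 8L] <- 0L
  haplotype_panel(
    al, paste0("S", 1:4), v, rep("pop1", 4)
  )
}

# constant-coverage depth profile: one chromosome, nwin windows, all samples
flat_depth <- function(cov = 10, nwin = 100L, samples = paste0("S", 1:4),
                       window = 100L) {
  m <- matrix(cov, nrow = nwin, ncol = length(samples),
    dimnames = list(NULL, samples)
  )
  depth_profile(list(chr1 = m), window = window)
}

# single-caller callset from a variant table and dosage matrix
toy_callset <- function(variants, geno, caller = "callerA") {
  sv_callset(variants, geno, caller = caller)
}

# Levene-Haldane closed-form conditional probabilities of heterozygote
# counts given (n individuals, minor allele count): the independent oracle
# for the exact HWE test
haldane_probs <- function(n, minor) {
  b <- seq.int(minor %% 2L, minor, by = 2L)
  keep <- (minor - b) / 2 + b <= n
  b <- b[keep]
  lp <- lfactorial(minor) + lfactorial(2 * n - minor) + lfactorial(n) -
    lfactorial(2 * n) - lfactorial((minor - b) / 2) - lfactorial(b) -
    lfactorial(n - (minor + b) / 2) + b * log(2)
  setNames(exp(lp), b)
}
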