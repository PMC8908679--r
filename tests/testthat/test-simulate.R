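# Founder-mosaic generator: determinism, frequency calibration, coverage
# closed forms, caller error construction and bookkeeping.

test_that("simulation is deterministic given the seed", {
  cfg <- tiny_config(seed = 7L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$panel$alleles, b$panel$alleles)
  expect_identical(a$truth$sv$dosages, b$truth$sv$dosages)
  expect_identical(a$depth$depth, b$depth$depth)
  expect_identical(
    lapply(a$callsets, `[[`, "geno"),
    lapply(b$callsets, `[[`, "geno")
  )
})

test_that("an empty configuration yields an empty panel", {
  cfg <- tiny_config(snp_density = 0, sv_counts = c(
    DEL = 0L, DUP = 0L, INV = 0L, BND = 0L
  ))
  sim <- simulate_panel(cfg)
  expect_equal(ncol(sim$panel$alleles), 0L)
  planted <- plant_svs(sim, cfg)
  expect_null(planted$truth$sv)
})

test_that("SNP-SNP r2 decays with distance on the configured scale", {
  # short-range LD should exceed long-range LD in nearly every replicate
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(
      seed = 100L + r,
      populations = "P1",
      n_samples = c(P1 = 25L), founders = c(P1 = 8L),
      segment_scale = c(P1 = 10000), chrom_lengths = c(chr1 = 300000),
      snp_density = 2e-3,
      sv_counts = c(DEL = 0L, DUP = 0L, INV = 0L, BND = 0L)
    )
    sim <- simulate_panel(cfg)
    pr <- ld_pairs(sim$panel, "P1", max_dist = 50000L, classes = "snp")
    near <- pr$r2[pr$distance <= 500L]
    far <- pr$r2[pr$distance > 45000L & pr$distance <= 50000L]
    if (length(near) && length(far) && mean(near) > mean(far)) {
      wins <- wins + 1L
    }
  }
  # one-sided sign test at p < 0.05: 15/20 successes suffice
  expect_gte(wins, 15L)
})

test_that("realized SV MAF tracks the per-population target", {
  devs <- numeric(0)
  for (r in 1:20) {
    cfg <- sim_config(
      seed = 300L + r,
      populations = "P1",
      n_samples = c(P1 = 100L), founders = c(P1 = 6L),
      segment_scale = c(P1 = 30000), chrom_lengths = c(chr1 = 5e5),
      snp_density = 5e-4,
      sv_counts = c(DEL = 0L, DUP = 10L, INV = 0L, BND = 0L)
    )
    planted <- plant_svs(simulate_panel(cfg), cfg)
    freq <- colMeans(planted$truth$sv$hap_alleles)
    devs <- c(devs, freq - planted$truth$sv$target_maf[, "P1"])
  }
  # resampling hits the target up to rounding: mean deviation within 3 SE
  expect_lt(abs(mean(devs)), 3 * sd(devs) / sqrt(length(devs)) + 1e-9)
  expect_lt(max(abs(devs)), 0.02) # binomial/rounding tolerance at 2N = 200
})

test_that("background-coupled SVs are in complete LD with their backbone", {
  cfg <- tiny_config(seed = 11L)
  planted <- plant_svs(simulate_panel(cfg), cfg, resample = FALSE)
  sv <- planted$truth$sv
  for (j in seq_len(ncol(sv$hap_alleles))) {
    a <- sv$hap_alleles[, j]
    b <- sv$background[, j]
    expect_identical(a, b)
    if (var(a) > 0) {
      expect_equal(haplotype_r2(a, b)$r2, 1.0)
    }
  }
})

test_that("depth dosage factors follow the closed forms", {
  cfg <- tiny_config(seed = 13L, depth_sd = 0, depth_mean_range = c(10, 10))
  st <- simulate_study(error_free(cfg))
  sv <- st$truth$sv
  dels <- which(sv$variants$vtype == "DEL")
  dups <- which(sv$variants$vtype == "DUP")
  check_span <- function(i, expected_factor) {
    v <- sv$variants[i, ]
    dh <- compute_dhffc(v$chrom, v$start, v$end, st$depth)
    dos <- sv$dosages[v$id, ]
    for (s in names(dos)) {
      expect_equal(unname(dh[s]), expected_factor[dos[[s]] + 1L])
    }
  }
  # het DUP with mean 10 and SD 0: windows inside the span equal 15
  check_span(dups[1L], c(1, 1.5, 2))
  # hom DEL: coverage (and DHFFC) exactly 0
  check_span(dels[1L], c(1, 0.5, 0))
})

test_that("artifact regions exceed the high-coverage threshold", {
  # fold 4 at mean 10, SD 1: 40 > 2*10 + 2*sigma for any plausible sigma
  cfg <- tiny_config(
    seed = 17L, depth_sd = 1, depth_mean_range = c(10, 10),
    artifact_n = 2L, artifact_fold = 4
  )
  st <- simulate_study(cfg)
  regions <- flag_high_coverage_regions(st$depth, st$genome)
  art <- st$truth$artifacts
  expect_equal(nrow(art), 2L)
  for (i in seq_len(nrow(art))) {
    reg <- regions$regions[regions$regions$chrom == art$chrom[i], ]
    hit <- any(reg$start < art$end[i] & art$start[i] < reg$end)
    expect_true(hit)
  }
})

test_that("noise-free full-sensitivity callsets equal the truth", {
  cfg <- error_free(tiny_config(seed = 19L))
  st <- simulate_study(cfg)
  for (cs in st$callsets) {
    expect_equal(nrow(cs$variants), nrow(st$truth$sv$variants))
    expect_equal(cs$variants$start, st$truth$sv$variants$start)
    expect_identical(
      unname(cs$geno[st$truth$sv$variants$id, ]),
      unname(st$truth$sv$dosages)
    )
  }
})

test_that("a saturated hom->het miscall channel leaves no dosage-2 INV", {
  cfg <- error_free(tiny_config(seed = 23L))
  cfg$hom_het_miscall <- c(DEL = 0, DUP = 0, INV = 1, BND = 0)
  st <- simulate_study(cfg)
  inv_ids <- st$truth$sv$variants$id[st$truth$sv$variants$vtype == "INV"]
  for (cs in st$callsets) {
    ids <- intersect(inv_ids, cs$variants$id)
    expect_false(any(cs$geno[ids, ] == 2L, na.rm = TRUE))
  }
})

test_that("breakpoint jitter stays within the merge tolerance", {
  # SD 300: 1000/300 = 3.3 sigma, at least 99% of offsets within 1 kb
  cfg <- tiny_config(
    seed = 29L,
    breakpoint_jitter = c(callerA = 300, callerB = 300, callerC = 300)
  )
  st <- simulate_study(cfg)
  offs <- unlist(lapply(st$callsets, function(cs) {
    cs$variants$start -
      st$truth$sv$variants$start[
        match(cs$variants$id, st$truth$sv$variants$id)
      ]
  }))
  expect_gte(mean(abs(offs) <= 1000), 0.99)
})

test_that("emitted genotype corruptions equal the recorded bookkeeping", {
  cfg <- tiny_config(seed = 31L)
  st <- simulate_study(cfg)
  base <- st$truth$miscall_geno # truth after the shared channels
  for (cal in names(st$callsets)) {
    cs <- st$callsets[[cal]]
    emitted <- sum(cs$geno != base[cs$variants$id, ])
    expect_identical(emitted, as.integer(st$truth$caller_errors[[cal]]))
  }
  # every cell differing from the truth is flagged by a shared channel
  changed <- st$truth$miscall_geno != st$truth$sv$dosages
  flagged <- st$truth$miscalls | st$truth$systematic_errors
  expect_true(all(flagged[changed]))
})

test_that("SNP calls on deletions follow the consistency construction", {
  cfg <- error_free(tiny_config(seed = 37L))
  st <- simulate_study(cfg)
  sv <- st$truth$sv
  snps <- st$snp_panel$variants
  dels <- sv$variants[sv$variants$vtype == "DEL", ]
  checked <- FALSE
  for (i in seq_len(nrow(dels))) {
    on_del <- snps$id[
      snps$chrom == dels$chrom[i] &
        snps$start >= dels$start[i] & snps$start < dels$end[i]
    ]
    if (length(on_del) == 0L) next
    dos <- sv$dosages[dels$id[i], ]
    hom <- names(dos)[dos == 2L]
    het <- names(dos)[dos == 1L]
    if (length(hom)) {
      expect_true(all(is.na(st$snp_calls[on_del, hom])))
      checked <- TRUE
    }
    if (length(het)) {
      expect_false(any(st$snp_calls[on_del, het] == 1L, na.rm = TRUE))
      checked <- TRUE
    }
  }
  expect_true(checked)
})
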