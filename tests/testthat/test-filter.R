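# Consensus merge and the five filtering rules.

# build three one-caller callsets holding the same variants with given
# per-caller start offsets and genotypes
three_callsets <- function(starts, ends, vtype = "DEL",
                           geno_by_caller = NULL, n_samples = 4L,
                           ci = 0L) {
  callers <- c("callerA", "callerB", "callerC")
  lapply(seq_along(callers), function(k) {
    v <- variant_table(
      id = sprintf("%s_v%d", callers[k], seq_along(starts[[k]])),
      chrom = "chr1", start = starts[[k]], end = ends[[k]],
      vtype = vtype, ci_start = ci, ci_end = ci
    )
    g <- if (is.null(geno_by_caller)) {
      matrix(1L, nrow(v), n_samples,
        dimnames = list(v$id, paste0("S", seq_len(n_samples)))
      )
    } else {
      m <- geno_by_caller[[k]]
      rownames(m) <- v$id
      m
    }
    sv_callset(v, g, caller = callers[k])
  })
}

test_that("breakpoint chains within tolerance merge into one record", {
  cs <- three_callsets(
    starts = list(1000L, 1400L, 1900L),
    ends = list(2000L, 2400L, 2900L)
  )
  m <- merge_callsets(cs, tolerance = 1000L)
  expect_equal(nrow(m$variants), 1L)
  expect_setequal(m$support[[1L]], c("callerA", "callerB", "callerC"))
  # canonical breakpoint: median of {1000, 1400, 1900}
  expect_equal(m$variants$start, 1400L)
})

test_that("distant records and mixed types never merge", {
  cs <- three_callsets(
    starts = list(c(1000L, 6000L), integer(0), integer(0)),
    ends = list(c(1500L, 6500L), integer(0), integer(0))
  )
  cs <- cs[1L] # single caller, two DELs 5 kb apart
  m <- merge_callsets(cs)
  expect_equal(nrow(m$variants), 2L)

  v_del <- variant_table("d", "chr1", 1000L, 1500L, "DEL")
  v_dup <- variant_table("u", "chr1", 1000L, 1500L, "DUP")
  g <- matrix(1L, 1L, 2L, dimnames = list(NULL, c("S1", "S2")))
  m2 <- merge_callsets(list(
    sv_callset(v_del, g, caller = "callerA"),
    sv_callset(v_dup, g, caller = "callerB")
  ))
  expect_equal(nrow(m2$variants), 2L)
  expect_setequal(m2$variants$vtype, c("DEL", "DUP"))
})

test_that("greedy chains match a brute-force chaining oracle", {
  set.seed(99)
  for (rep in 1:20) {
    starts <- sort(sample.int(50000L, 8L))
    cs <- three_callsets(
      starts = list(starts, integer(0), integer(0)),
      ends = list(starts + 1L, integer(0), integer(0)),
      vtype = "BND"
    )[1L]
    m <- merge_callsets(cs, tolerance = 1000L)
    # oracle: count breaks between consecutive sorted breakpoints
    expected <- 1L + sum(diff(starts) > 1000L)
    expect_equal(nrow(m$variants), expected)
  }
})

test_that("caller-overlap rule retains only 2-of-3 supported SVs", {
  cs <- three_callsets(
    starts = list(c(1000L, 9000L), 1100L, 1050L),
    ends = list(c(1001L, 9001L), 1101L, 1051L),
    vtype = "BND"
  )
  m <- merge_callsets(cs)
  r <- filter_caller_overlap(m)
  expect_equal(nrow(r$retained$variants), 1L)
  expect_equal(nrow(r$removed$variants), 1L)
  expect_equal(r$removed$variants$start, 9000L)
})

test_that("consensus genotypes follow 2-of-3 voting with a discordance cap", {
  g <- function(...) matrix(c(...), nrow = 1L,
    dimnames = list(NULL, paste0("S", 1:4))
  )
  cs <- three_callsets(
    starts = list(1000L, 1000L, 1000L),
    ends = list(2000L, 2000L, 2000L),
    geno_by_caller = list(
      g(1L, 0L, 0L, 2L),
      g(1L, 1L, 1L, 1L),
      g(2L, 2L, 0L, 0L)
    )
  )
  m <- merge_callsets(cs)
  r <- consensus_genotypes(m, max_discordant_samples = 2L)
  # S1: votes (1,1,2) -> 1; S2: (0,1,2) -> missing; S3: (0,1,0) -> 0;
  # S4: (2,1,0) -> missing. 2 discordant <= 2 -> retained.
  expect_equal(nrow(r$retained$variants), 1L)
  expect_equal(
    unname(r$retained$consensus[1L, ]), c(1L, NA, 0L, NA)
  )
  expect_equal(r$n_set_missing, 2L)

  r2 <- consensus_genotypes(m, max_discordant_samples = 1L)
  expect_equal(nrow(r2$retained$variants), 0L) # 2 > 1 -> removed
})

test_that("high-coverage windows are flagged at strictly 2*mu + 2*sigma", {
  # construct window means with known mu and sigma
  nwin <- 1000L
  base <- rep(10, nwin)
  m <- matrix(base, nwin, 2L, dimnames = list(NULL, c("S1", "S2")))
  prof <- depth_profile(list(chr1 = m), window = 100L)
  mu <- 10
  sigma <- 0
  # all equal: sigma = 0, threshold 20; no window above
  expect_equal(nrow(flag_high_coverage_regions(prof)$regions), 0L)

  m2 <- m
  m2[5L, ] <- 25
  m2[500L, ] <- 24.9
  prof2 <- depth_profile(list(chr1 = m2), window = 100L)
  fl <- flag_high_coverage_regions(prof2)
  # threshold moved by the outliers themselves; recompute explicitly
  means <- rowMeans(m2)
  thr <- 2 * mean(means) + 2 * sd(means)
  expect_equal(fl$threshold, thr)
  expect_equal(fl$regions$start, (which(means > thr) - 1L) * 100L)
})

test_that("flagged windows closer than the gap merge into one region", {
  nwin <- 100L
  m <- matrix(10, nwin, 1L, dimnames = list(NULL, "S1"))
  m[c(11L, 16L), ] <- 1000 # windows [1000,1100) and [1500,1600)
  prof <- depth_profile(list(chr1 = m), window = 100L)
  fl <- flag_high_coverage_regions(prof, merge_gap = 1000L)
  expect_equal(nrow(fl$regions), 1L)
  expect_equal(fl$regions$start, 1000L)
  expect_equal(fl$regions$end, 1600L)
})

test_that("CI overlap with flagged regions removes SVs (half-open)", {
  regions <- structure(
    list(regions = data.frame(
      chrom = "chr1", start = 5100L, end = 5300L
    )),
    class = "high_coverage_regions"
  )
  mk <- function(start, ci) {
    v <- variant_table("x", "chr1", start, start + 2000L, "DEL",
      ci_start = ci, ci_end = 0L
    )
    g <- matrix(1L, 1L, 2L, dimnames = list(NULL, c("S1", "S2")))
    merge_callsets(list(sv_callset(v, g, caller = "callerA")))
  }
  # breakpoint 5000 with CI +-200 overlaps [5100, 5300)
  expect_equal(
    nrow(filter_high_coverage(mk(5000L, 200L), regions)$removed$variants), 1L
  )
  # CI end exactly at region start: [4900, 5100) does not overlap
  expect_equal(
    nrow(filter_high_coverage(mk(5000L, 100L), regions)$removed$variants), 0L
  )
  # CI entirely elsewhere
  expect_equal(
    nrow(filter_high_coverage(mk(9000L, 100L), regions)$removed$variants), 0L
  )
})

test_that("DHFFC is inside median over pooled flank median", {
  nwin <- 100L
  m <- matrix(10, nwin, 1L, dimnames = list(NULL, "S1"))
  m[21:30, ] <- 5 # span [2000, 3000)
  prof <- depth_profile(list(chr1 = m), window = 100L)
  dh <- compute_dhffc("chr1", 2000L, 3000L, prof, flank = 1000L)
  expect_equal(unname(dh), 0.5)
  dh2 <- compute_dhffc("chr1", 5000L, 6000L, prof, flank = 1000L)
  expect_equal(unname(dh2), 1.0)
  # zero flank -> undefined
  m0 <- matrix(0, nwin, 1L, dimnames = list(NULL, "S1"))
  prof0 <- depth_profile(list(chr1 = m0), window = 100L)
  expect_true(is.na(compute_dhffc("chr1", 2000L, 3000L, prof0)))
})

test_that("DHFFC rule applies the printed genotype bounds", {
  # one DEL and one DUP, 4 samples with chosen coverage patterns
  nwin <- 200L
  samples <- paste0("S", 1:4)
  m <- matrix(10, nwin, 4L, dimnames = list(NULL, samples))
  # DEL span [2000,3000): S1 het valid (0.5), S2 het wrong (0.95),
  # S3 hom valid (0.0), S4 homref untested
  m[21:30, 1L] <- 5
  m[21:30, 2L] <- 9.5
  m[21:30, 3L] <- 0
  # DUP span [8000,9000): S1 het wrong (1.05), S2 hom wrong (1.3),
  # S3 het valid (1.5), S4 hom valid (2.0)
  m[81:90, 1L] <- 10.5
  m[81:90, 2L] <- 13
  m[81:90, 3L] <- 15
  m[81:90, 4L] <- 20
  prof <- depth_profile(list(chr1 = m), window = 100L)
  v <- variant_table(
    c("d1", "u1"), "chr1", c(2000L, 8000L), c(3000L, 9000L),
    c("DEL", "DUP")
  )
  g <- matrix(
    c(
      1L, 1L, 2L, 0L,
      1L, 2L, 1L, 2L
    ),
    nrow = 2L, byrow = TRUE, dimnames = list(v$id, samples)
  )
  merged <- merge_callsets(list(
    sv_callset(v, g, caller = "callerA"),
    sv_callset(v, g, caller = "callerB")
  ))
  r2c <- consensus_genotypes(merged)
  r4 <- filter_dhffc(r2c$retained, prof)
  # DEL has 1 wrong of 3 tested (<= 1 error, 33% > 10%) -> removed
  # DUP has 2 wrong -> removed
  expect_equal(nrow(r4$removed$variants), 2L)

  # a single wrong genotype among many tested is set missing instead
  n <- 20L
  samples <- paste0("S", seq_len(n))
  m <- matrix(10, nwin, n, dimnames = list(NULL, samples))
  m[21:30, ] <- 5
  m[21:30, 2L] <- 9.5 # one wrong het
  prof <- depth_profile(list(chr1 = m), window = 100L)
  v <- variant_table("d1", "chr1", 2000L, 3000L, "DEL")
  g <- matrix(1L, 1L, n, dimnames = list("d1", samples))
  merged <- merge_callsets(list(
    sv_callset(v, g, caller = "callerA"),
    sv_callset(v, g, caller = "callerB")
  ))
  r4b <- filter_dhffc(consensus_genotypes(merged)$retained, prof)
  expect_equal(nrow(r4b$removed$variants), 0L)
  expect_true(is.na(r4b$retained$consensus[1L, 2L]))
  expect_equal(r4b$n_set_missing, 1L)
})

test_that("deletion SNP-support rule follows the summed error thresholds", {
  # DEL [1000, 2000) with 5 SNPs on it
  snps <- variant_table(
    paste0("s", 1:5), "chr1", seq(1100L, 1900L, by = 200L),
    seq(1101L, 1901L, by = 200L), "SNP"
  )
  mk_merged <- function(geno_row, n) {
    samples <- paste0("S", seq_len(n))
    v <- variant_table("d1", "chr1", 1000L, 2000L, "DEL")
    g <- matrix(geno_row, 1L, n, dimnames = list("d1", samples))
    m <- merge_callsets(list(
      sv_callset(v, g, caller = "callerA"),
      sv_callset(v, g, caller = "callerB")
    ))
    consensus_genotypes(m)$retained
  }
  # 10 het carriers, each with 1 heterozygous SNP call of 5 -> e_s = 0.2,
  # sum = 2.0: not > 2 and not > 5 -> kept, violating genotypes missing
  n <- 12L
  geno <- c(rep(1L, 10L), 0L, 0L)
  calls <- matrix(0L, 5L, n,
    dimnames = list(snps$id, paste0("S", seq_len(n)))
  )
  calls[1L, 1:10] <- 1L
  r <- filter_del_snp_support(mk_merged(geno, n), calls, snps)
  expect_equal(nrow(r$removed$variants), 0L)
  expect_equal(sum(is.na(r$retained$consensus)), 10L)

  # one more violation: sum = 2.2 > 2 -> removed
  calls2 <- calls
  calls2[2L, 1L] <- 1L
  r2 <- filter_del_snp_support(mk_merged(geno, n), calls2, snps)
  expect_equal(nrow(r2$removed$variants), 1L)

  # 3 carriers with sum e = 1.6 > 1.5 = 50% of carriers -> removed
  n3 <- 5L
  geno3 <- c(1L, 1L, 1L, 0L, 0L)
  calls3 <- matrix(0L, 5L, n3,
    dimnames = list(snps$id, paste0("S", seq_len(n3)))
  )
  calls3[1:4, 1L] <- 1L # e = 0.8
  calls3[1:4, 2L] <- 1L # e = 0.8
  r3 <- filter_del_snp_support(mk_merged(geno3, n3), calls3, snps)
  expect_equal(nrow(r3$removed$variants), 1L)

  # halved (per-allele) reading: e_s = violations / (2 * 5)
  r4 <- filter_del_snp_support(
    mk_merged(geno3, n3), calls3, snps,
    config = filter_config(snp_support_halved = TRUE)
  )
  expect_equal(nrow(r4$removed$variants), 0L) # sum = 0.8, kept
})

test_that("fill_missing_genotypes fills from the allele frequency", {
  v <- variant_table(c("a", "b"), "chr1", c(100L, 200L), c(101L, 201L),
    "SNP"
  )
  n <- 6L
  g <- matrix(
    c(
      0L, 2L, 1L, 0L, 2L, 1L, # no missing
      2L, 2L, 2L, NA, NA, NA # freq 1 among non-missing
    ),
    nrow = 2L, byrow = TRUE,
    dimnames = list(v$id, paste0("S", 1:6))
  )
  p <- fill_missing_genotypes(
    v, g, paste0("S", 1:6), rep("pop1", 6L),
    seed = 5L
  )
  d <- panel_dosages(p)
  expect_equal(unname(d["a", ]), unname(g["a", ]))
  expect_equal(unname(d["b", ]), rep(2L, 6L))

  # fill frequency calibration: p = 0.3, 10k fills within 0.3 +- 0.02
  v1 <- variant_table("x", "chr1", 100L, 101L, "SNP")
  nbig <- 5200L
  gg <- matrix(NA_integer_, 1L, nbig,
    dimnames = list("x", paste0("S", seq_len(nbig)))
  )
  gg[1L, 1:200] <- rep(c(0L, 1L, 0L, 1L, 1L), 40L)[1:200] # p = 0.3
  pf <- fill_missing_genotypes(
    v1, gg, colnames(gg), rep("pop1", nbig),
    seed = 9L
  )
  filled <- panel_dosages(pf)[1L, -(1:200)]
  expect_lt(abs(mean(filled) / 2 - 0.3), 0.02)
})

test_that("pipeline is the identity on error-free data and conserves counts", {
  cfg <- error_free(tiny_config(seed = 41L))
  st <- simulate_study(cfg)
  fr <- run_filter_pipeline(
    st$callsets, st$depth, st$snp_calls, st$snp_panel$variants,
    genome = st$genome
  )
  expect_equal(sum(fr$report$removed), 0L)
  expect_equal(sum(fr$report$genotypes_set_missing), 0L)
  expect_equal(nrow(fr$svs$variants), nrow(st$truth$sv$variants))
  expect_true(all(
    fr$report$input == fr$report$removed + fr$report$retained
  ))
  expect_identical(
    unname(fr$svs$consensus[order(rownames(fr$svs$consensus)), ]),
    unname(st$truth$sv$dosages[order(rownames(st$truth$sv$dosages)), ])
  )
})

test_that("planted caller dropout is removed at exactly the overlap rule", {
  cfg <- error_free(tiny_config(seed = 43L))
  st <- simulate_study(cfg)
  # drop two callers for a subset of SVs -> support 1
  drop_ids <- st$truth$sv$variants$id[c(2L, 5L, 9L)]
  callsets <- st$callsets
  for (cal in c("callerB", "callerC")) {
    keep <- !(callsets[[cal]]$variants$id %in% drop_ids)
    callsets[[cal]] <- sv_callset(
      {
        v <- callsets[[cal]]$variants[keep, , drop = FALSE]
        rownames(v) <- NULL
        class(v) <- c("variant_table", "data.frame")
        v
      },
      callsets[[cal]]$geno[keep, , drop = FALSE],
      caller = cal
    )
  }
  fr <- run_filter_pipeline(
    callsets, st$depth, st$snp_calls, st$snp_panel$variants,
    genome = st$genome
  )
  expect_equal(
    fr$report$removed[fr$report$rule == "caller_overlap"], 3L
  )
  expect_equal(sum(fr$report$removed), 3L)
  expect_false(any(drop_ids %in% rownames(fr$svs$consensus)))
})

test_that("a planted artifact region removes exactly the overlapping SV", {
  cfg <- error_free(tiny_config(seed = 47L))
  st <- simulate_study(cfg)
  # plant an artifact region over one SV's start breakpoint by raising
  # the coverage fourfold there in every sample
  target <- st$truth$sv$variants[3L, ]
  w <- st$depth$window
  wi <- max(1L, target$start %/% w):min(
    nrow(st$depth$depth[[target$chrom]]), target$start %/% w + 2L
  )
  st$depth$depth[[target$chrom]][wi, ] <-
    st$depth$depth[[target$chrom]][wi, ] * 4
  fr <- run_filter_pipeline(
    st$callsets, st$depth, st$snp_calls, st$snp_panel$variants,
    genome = st$genome
  )
  removed_at_3 <- fr$report$removed[
    fr$report$rule == "high_coverage_regions"
  ]
  expect_equal(removed_at_3, 1L)
  expect_false(target$id %in% rownames(fr$svs$consensus))
})
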