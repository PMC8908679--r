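# r2, r2max, r2s, pair enumeration, decay binning, bootstrap CIs,
# relative LD and the DHFFC correlation.

test_that("haplotype r2 matches hand-computed fixtures", {
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 1, 0, 0, 0)
  res <- haplotype_r2(a, b)
  expect_equal(res$p_a, 0.5)
  expect_equal(res$p_b, 0.5)
  expect_equal(res$p_ab, 0.375)
  expect_equal(res$r2, 0.25)

  expect_equal(haplotype_r2(a, a)$r2, 1.0)
  expect_equal(haplotype_r2(c(1, 1, 0, 0), c(1, 0, 1, 0))$r2, 0)
  expect_error(haplotype_r2(a, rep(1, 8)), "monomorphic")
})

test_that("r2max boundary evaluation matches known values", {
  expect_equal(r2max(0.3, 0.3), 1.0)
  expect_equal(r2max(0.5, 0.25), 1 / 3)
  expect_equal(r2max(0.1, 0.9), 1.0)
})

test_that("r2max equals a fine grid search over the Frechet interval", {
  grid_r2max <- function(p_a, p_b, n_grid = 2001L) {
    lo <- max(0, p_a + p_b - 1)
    hi <- min(p_a, p_b)
    p_ab <- seq(lo, hi, length.out = n_grid)
    den <- p_a * p_b * (1 - p_a) * (1 - p_b)
    max((p_ab - p_a * p_b)^2 / den)
  }
  set.seed(17)
  for (i in 1:200) {
    p_a <- runif(1, 0.01, 0.99)
    p_b <- runif(1, 0.01, 0.99)
    expect_equal(r2max(p_a, p_b), grid_r2max(p_a, p_b), tolerance = 1e-12)
  }
})

test_that("r2s is the standardized ratio with overshoot guard", {
  expect_equal(r2s(0.25, r2max(0.5, 0.25)), 0.75)
  expect_equal(r2s(1 / 3, 1 / 3), 1.0)
  expect_equal(r2s(0, 0.5), 0)
  expect_error(r2s(0.6, 0.5), "exceeds")
  # a fully coupled pair at unequal MAFs reaches r2s = 1
  a <- c(rep(1, 2), rep(0, 8))
  b <- c(rep(1, 5), rep(0, 5))
  r <- haplotype_r2(a, b)
  expect_lt(r$r2, 1)
  expect_equal(r2s(r$r2, r2max(r$p_a, r$p_b)), 1.0)
})

test_that("pair enumeration applies distance and on-SV exclusion rules", {
  # panel: DEL [1000, 11000), SNPs at 900 (left), 1500 (inside), 11200
  v <- variant_table(
    id = c("sL", "sI", "sR", "d"),
    chrom = "chr1",
    start = c(900L, 1500L, 11200L, 1000L),
    end = c(901L, 1501L, 11201L, 11000L),
    vtype = c("SNP", "SNP", "SNP", "DEL")
  )
  set.seed(3)
  al <- matrix(rbinom(4L * 8L, 1L, 0.5), nrow = 8L)
  al[1:4, ] <- 1L - al[5:8, ] # force polymorphism
  panel <- haplotype_panel(al, paste0("S", 1:4), v, rep("p", 4))
  pr <- ld_pairs(panel, "p", max_dist = 100000L, classes = "sv")
  expect_false("sI" %in% pr$id_b) # on the DEL -> excluded
  # distance to nearest breakpoint, not span-aware midpoints
  expect_equal(pr$distance[pr$id_b == "sL"], 100L)
  expect_equal(pr$distance[pr$id_b == "sR"], 200L)

  pr2 <- ld_pairs(panel, "p", max_dist = 150L, classes = "sv")
  expect_equal(pr2$id_b, "sL") # 200 > 150 excluded
})

test_that("pair statistics agree with the scalar implementation", {
  cfg <- tiny_config(seed = 53L)
  st <- simulate_study(error_free(cfg))
  pr <- ld_pairs(st$panel, "BL", max_dist = 3000L)
  expect_gt(nrow(pr), 10L)
  sub <- panel_subset(st$panel, "BL")
  for (k in sample.int(nrow(pr), 10L)) {
    a <- sub$alleles[, pr$id_a[k]]
    b <- sub$alleles[, pr$id_b[k]]
    ref <- haplotype_r2(a, b)
    expect_equal(pr$r2[k], ref$r2, tolerance = 1e-12)
    expect_equal(pr$p_ab[k], ref$p_ab, tolerance = 1e-12)
    expect_equal(
      pr$r2s[k], r2s(ref$r2, r2max(ref$p_a, ref$p_b)),
      tolerance = 1e-12
    )
  }
  # invariant: r2 <= r2max
  expect_true(all(pr$r2 <= pr$r2max + 1e-12))
})

test_that("decay bins are upper-closed with width 500", {
  pairs <- data.frame(
    class = "SNP-SNP", distance = c(250L, 500L, 501L),
    r2 = c(0.4, 0.2, 0.6), r2s = c(0.5, 0.25, 0.7)
  )
  b <- bin_decay(pairs, bin = 500L, max_dist = 2000L)
  expect_equal(b$n[b$bin == 1L], 2L)
  expect_equal(b$mean_r2[b$bin == 1L], 0.3)
  expect_equal(b$n[b$bin == 2L], 1L)
  expect_equal(b$mean_r2[b$bin == 2L], 0.6)
  expect_equal(b$n[b$bin == 3L], 0L) # empty bins reported
})

test_that("bootstrap CI behaves as a percentile bootstrap", {
  expect_equal(
    bootstrap_bin_ci(rep(0.4, 10L), n_boot = 100L, n_bins = 10L),
    c(0.4, 0.4)
  )
  expect_null(bootstrap_bin_ci(0.4, n_boot = 100L, n_bins = 10L))
  expect_null(
    bootstrap_bin_ci(runif(20L), n_boot = 10L, n_bins = 10L, skip_above = 19L)
  )
  set.seed(11)
  vals <- runif(50L)
  ci <- with_seed(1L, bootstrap_bin_ci(vals, n_boot = 100000L, n_bins = 200L))
  expect_lt(ci[1L], mean(vals))
  expect_gt(ci[2L], mean(vals))
})

test_that("relative LD summarises bin ratios", {
  snp <- data.frame(
    bin = 1:10, n = 100L, mean_r2 = seq(0.5, 0.05, length.out = 10L),
    mean_r2s = seq(0.6, 0.06, length.out = 10L)
  )
  expect_equal(relative_ld(snp, snp)$rel_r2_mean, 100)
  expect_equal(relative_ld(snp, snp)$rel_r2_sd, 0)
  expect_equal(relative_ld(snp, snp)$delta, 0)
  half <- snp
  half$mean_r2 <- snp$mean_r2 / 2
  half$mean_r2s <- snp$mean_r2s / 2
  expect_equal(relative_ld(half, snp)$rel_r2_mean, 50)
  empty <- snp
  empty$n[3L] <- 0L
  expect_error(relative_ld(empty, snp), "non-empty")
})

test_that("delta-MAF summary separates planted rare DUPs", {
  cfg <- tiny_config(
    seed = 59L,
    sv_counts = c(DEL = 0L, DUP = 20L, INV = 0L, BND = 0L)
  )
  cfg$sv_maf_shape$DUP <- c(0.6, 10) # very rare targets
  st <- simulate_study(error_free(cfg))
  pr <- ld_pairs(st$panel, "BR", max_dist = 5000L)
  dm <- delta_maf_summary(pr, max_dist = 5000L)
  expect_gt(
    dm$median[dm$class == "DUP-SNP"], dm$median[dm$class == "SNP-SNP"]
  )
  # pairs beyond the window are excluded
  expect_true(all(pr$distance[pr$distance <= 5000L] <= 5000L))
  pr2 <- data.frame(
    class = "SNP-SNP", distance = c(4000L, 5001L),
    dmaf = c(0.1, 0.4)
  )
  expect_equal(delta_maf_summary(pr2, 5000L)$n, 1L)
})

test_that("dosage-DHFFC correlation matches the closed form", {
  dos <- c(0, 1, 2, 1, 0)
  expect_equal(dosage_dhffc_r2(dos, 1 - 0.5 * dos), 1.0)
  expect_error(dosage_dhffc_r2(dos, rep(1, 5)), "constant")
  d5 <- c(0, 0, 1, 1, 2)
  f5 <- c(1.0, 0.9, 0.6, 0.5, 0.1)
  manual <- (sum((d5 - mean(d5)) * (f5 - mean(f5))))^2 /
    (sum((d5 - mean(d5))^2) * sum((f5 - mean(f5))^2))
  expect_equal(dosage_dhffc_r2(d5, f5), manual)
})

test_that("streaming decay equals the materialized pair computation", {
  cfg <- tiny_config(seed = 61L)
  st <- simulate_study(error_free(cfg))
  pr <- ld_pairs(st$panel, "WL", max_dist = 10000L)
  ref <- bin_decay(pr, bin = 500L, max_dist = 10000L)
  dec <- ld_decay(st$panel, "WL", max_dist = 10000L, bin = 500L)
  for (cl in unique(ref$class)) {
    a <- ref[ref$class == cl, ]
    b <- dec[dec$class == cl, ]
    expect_equal(a$n, b$n)
    expect_equal(a$mean_r2, b$mean_r2, tolerance = 1e-12)
    expect_equal(a$mean_r2s, b$mean_r2s, tolerance = 1e-12)
  }
})

test_that("SNP-SNP decay is monotone decreasing over bins", {
  cfg <- sim_config(
    seed = 71L, populations = "P1", n_samples = c(P1 = 30L),
    founders = c(P1 = 4L), segment_scale = c(P1 = 20000),
    chrom_lengths = c(chr1 = 2e6), snp_density = 1.5e-3,
    sv_counts = c(DEL = 0L, DUP = 0L, INV = 0L, BND = 0L)
  )
  sim <- simulate_panel(cfg)
  dec <- ld_decay(sim$panel, "P1", max_dist = 100000L, bin = 500L)
  snp <- dec[dec$class == "SNP-SNP" & dec$n > 0L, ]
  rho <- suppressWarnings(
    cor(snp$bin, snp$mean_r2, method = "spearman")
  )
  expect_lt(rho, 0)
})
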