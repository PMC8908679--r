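# Linkage disequilibrium between phased variants.
#
# r2 is the squared haplotype correlation
#   r2 = (p_AB - p_A p_B)^2 / (p_A p_B (1 - p_A)(1 - p_B)),
# its upper bound r2max given the two allele frequencies is reached at one
# of the Frechet bounds of the haplotype frequency, and r2s = r2 / r2max is
# LD with the allele-frequency-difference constraint removed. Pairing rules:
# SV-SNP distance is the distance from the SNP to the nearest SV breakpoint;
# SNPs located on an SV are excluded for that SV; all LD is computed within
# one population's haplotypes; monomorphic variants are excluded.

#' Haplotype r2 between two phased 0/1 vectors
#'
#' @param alleles_a,alleles_b equal-length 0/1 haplotype vectors, both
#'   polymorphic.
#' @return list with `r2`, `p_a`, `p_b`, `p_ab`.
#' @export
haplotype_r2 <- function(alleles_a, alleles_b) {
  stopifnot(length(alleles_a) == length(alleles_b))
  p_a <- mean(alleles_a)
  p_b <- mean(alleles_b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    stop("r2 is undefined for monomorphic vectors")
  }
  p_ab <- mean(alleles_a == 1L & alleles_b == 1L)
  r2 <- (p_ab - p_a * p_b)^2 / (p_a * p_b * (1 - p_a) * (1 - p_b))
  list(r2 = r2, p_a = p_a, p_b = p_b, p_ab = p_ab)
}

#' Maximum attainable r2 given two allele frequencies
#'
#' r2 is a convex quadratic in the haplotype frequency, so its maximum over
#' the feasible (Frechet) interval `[max(0, p_a + p_b - 1), min(p_a, p_b)]`
#' is attained at one of the two bounds; both are evaluated and the larger
#' returned. Vectorized.
#'
#' @param p_a,p_b alternative-allele frequencies in (0, 1).
#' @return numeric vector of maximal r2 values.
#' @export
r2max <- function(p_a, p_b) {
  stopifnot(all(p_a > 0 & p_a < 1), all(p_b > 0 & p_b < 1))
  den <- p_a * p_b * (1 - p_a) * (1 - p_b)
  d_low <- pmax(0, p_a + p_b - 1) - p_a * p_b
  d_high <- pmin(p_a, p_b) - p_a * p_b
  pmax(d_low^2, d_high^2) / den
}

#' Standardized r2
#'
#' @param r2 observed r2.
#' @param r2max maximum attainable r2 (> 0), e.g. from [r2max()].
#' @return `r2 / r2max` in `[0, 1]`; values exceeding 1 by more than
#'   floating-point overshoot (1e-12) are an error.
#' @export
r2s <- function(r2, r2max) {
  stopifnot(all(r2max > 0))
  ratio <- r2 / r2max
  if (any(ratio > 1 + 1e-12)) {
    stop("r2 exceeds r2max beyond floating-point tolerance")
  }
  pmin(pmax(ratio, 0), 1)
}

pair_class <- function(vtype_a) {
  ifelse(vtype_a == "SNP", "SNP-SNP", paste0(vtype_a, "-SNP"))
}

# vectorized pair statistics from frequencies
pair_stats <- function(p_a, p_b, p_ab) {
  den <- p_a * p_b * (1 - p_a) * (1 - p_b)
  r2 <- (p_ab - p_a * p_b)^2 / den
  rmax <- r2max(p_a, p_b)
  maf_a <- pmin(p_a, 1 - p_a)
  maf_b <- pmin(p_b, 1 - p_b)
  data.frame(
    p_a = p_a, p_b = p_b, p_ab = p_ab,
    dmaf = abs(maf_a - maf_b),
    r2 = r2, r2max = rmax, r2s = pmin(r2 / rmax, 1)
  )
}

# iterate LD pair chunks for one population; callback(df) is called with
# columns id_a, id_b, class, distance, p_a, p_b, p_ab, dmaf, r2, r2max, r2s
iterate_ld_pairs <- function(panel, population, max_dist = 100000L,
                             classes = c("snp", "sv"), block = 512L,
                             callback) {
  sub <- panel_subset(panel, population)
  H <- sub$alleles
  v <- sub$variants
  nhap <- nrow(H)
  p_all <- colMeans(H)
  poly <- p_all > 0 & p_all < 1
  for (ch in unique(v$chrom)) {
    on_ch <- which(v$chrom == ch & poly)
    snp_i <- on_ch[v$vtype[on_ch] == "SNP"]
    if ("snp" %in% classes && length(snp_i) >= 2L) {
      pos <- v$start[snp_i]
      m <- length(snp_i)
      for (b0 in seq(1L, m - 1L, by = block)) {
        bi <- b0:min(b0 + block - 1L, m - 1L)
        jmax <- min(m, findInterval(pos[max(bi)] + max_dist, pos))
        if (jmax < b0 + 1L) next
        jr <- (b0 + 1L):jmax
        A <- H[, snp_i[bi], drop = FALSE]
        B <- H[, snp_i[jr], drop = FALSE]
        pab <- crossprod(A, B) / nhap
        ii <- rep(bi, times = length(jr))
        jj <- rep(jr, each = length(bi))
        dist <- pos[jj] - pos[ii]
        ok <- jj > ii & dist > 0L & dist <= max_dist
        if (!any(ok)) next
        st <- pair_stats(
          p_all[snp_i[ii[ok]]], p_all[snp_i[jj[ok]]],
          as.numeric(pab)[ok]
        )
        callback(cbind(
          data.frame(
            id_a = v$id[snp_i[ii[ok]]], id_b = v$id[snp_i[jj[ok]]],
            class = "SNP-SNP", distance = dist[ok]
          ),
          st
        ))
      }
    }
    if ("sv" %in% classes) {
      sv_i <- on_ch[v$vtype[on_ch] != "SNP"]
      all_snp <- which(v$chrom == ch & poly & v$vtype == "SNP")
      if (length(all_snp) == 0L) next
      spos <- v$start[all_snp]
      for (i in sv_i) {
        bp1 <- v$start[i]
        bp2 <- v$end[i]
        point <- v$vtype[i] == "BND"
        dist <- if (point) {
          abs(spos - bp1)
        } else {
          pmin(abs(spos - bp1), abs(spos - bp2))
        }
        on_sv <- !point & spos >= v$start[i] & spos < v$end[i]
        ok <- which(!on_sv & dist > 0L & dist <= max_dist)
        if (length(ok) == 0L) next
        a <- H[, i]
        pab <- as.numeric(crossprod(a, H[, all_snp[ok], drop = FALSE])) / nhap
        st <- pair_stats(rep(p_all[i], length(ok)), p_all[all_snp[ok]], pab)
        callback(cbind(
          data.frame(
            id_a = v$id[i], id_b = v$id[all_snp[ok]],
            class = pair_class(v$vtype[i]), distance = dist[ok]
          ),
          st
        ))
      }
    }
  }
  invisible(NULL)
}

#' Enumerate LD pairs within one population
#'
#' @param panel a [haplotype_panel()].
#' @param population population label.
#' @param max_dist maximum pair distance in bp (default 100 kb).
#' @param classes which pair classes to emit: `"snp"` (SNP-SNP), `"sv"`
#'   (SV-SNP), or both.
#' @return data.frame with one row per pair: ids, class, distance, allele
#'   and haplotype frequencies, `dmaf`, `r2`, `r2max`, `r2s`.
#' @export
ld_pairs <- function(panel, population, max_dist = 100000L,
                     classes = c("snp", "sv")) {
  chunks <- list()
  iterate_ld_pairs(
    panel, population, max_dist, classes,
    callback = function(df) chunks[[length(chunks) + 1L]] <<- df
  )
  if (length(chunks) == 0L) {
    return(data.frame(
      id_a = character(0), id_b = character(0), class = character(0),
      distance = integer(0), p_a = numeric(0), p_b = numeric(0),
      p_ab = numeric(0), dmaf = numeric(0), r2 = numeric(0),
      r2max = numeric(0), r2s = numeric(0)
    ))
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

#' Bin pair distances into decay bins
#'
#' Bins are upper-closed with width `bin`: bin b covers
#' `(bin (b-1), bin b]`, so a 500 bp pair falls in bin 1. Empty bins are
#' reported with `n = 0`.
#'
#' @param pairs data.frame from [ld_pairs()] (columns `class`, `distance`,
#'   `r2`, `r2s`).
#' @param bin bin width in bp (default 500).
#' @param max_dist bin grid upper end (default 100 kb).
#' @return data.frame: `class`, `bin`, `bin_start` (exclusive), `bin_end`
#'   (inclusive), `n`, `mean_r2`, `mean_r2s`.
#' @export
bin_decay <- function(pairs, bin = 500L, max_dist = 100000L) {
  n_bins <- ceiling(max_dist / bin)
  classes <- unique(pairs$class)
  if (length(classes) == 0L) classes <- character(0)
  out <- list()
  for (cl in classes) {
    p <- pairs[pairs$class == cl, , drop = FALSE]
    b <- ceiling(p$distance / bin)
    n <- tabulate(b, nbins = n_bins)
    s2 <- vapply(
      seq_len(n_bins),
      function(k) sum(p$r2[b == k]), numeric(1)
    )
    s2s <- vapply(
      seq_len(n_bins),
      function(k) sum(p$r2s[b == k]), numeric(1)
    )
    out[[cl]] <- data.frame(
      class = cl, bin = seq_len(n_bins),
      bin_start = (seq_len(n_bins) - 1L) * bin,
      bin_end = seq_len(n_bins) * bin,
      n = n,
      mean_r2 = ifelse(n > 0L, s2 / n, NA_real_),
      mean_r2s = ifelse(n > 0L, s2s / n, NA_real_)
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected percentile bootstrap CI for a bin mean
#'
#' Resamples the bin's values `n_boot` times with replacement and returns
#' the percentile interval at level `alpha / n_bins` with
#' `alpha = 0.05` (Bonferroni across the decay bins). Returns `NULL` for
#' bins with more than `skip_above` values (the interval would be
#' degenerate) or fewer than 2.
#'
#' @param values numeric vector of r2 (or r2s) values in the bin.
#' @param n_boot number of resamples (default 100,000).
#' @param n_bins number of bins corrected across.
#' @param skip_above skip threshold on the bin size (default 1e6).
#' @return numeric `c(lower, upper)` or `NULL`.
#' @export
bootstrap_bin_ci <- function(values, n_boot = 100000L, n_bins = 200L,
                             skip_above = 1000000L) {
  m <- length(values)
  if (m < 2L || m > skip_above) {
    return(NULL)
  }
  means <- colMeans(matrix(
    sample(values, m * n_boot, replace = TRUE), nrow = m
  ))
  alpha <- 0.05 / n_bins
  unname(quantile(means, c(alpha / 2, 1 - alpha / 2)))
}

#' LD decay curves with bootstrap confidence intervals
#'
#' Streams the pair enumeration into per-bin accumulators (memory is
#' independent of the pair count; per-bin values are retained for the
#' bootstrap only up to the skip threshold) and attaches
#' Bonferroni-corrected percentile bootstrap CIs for both r2 and r2s.
#'
#' @inheritParams ld_pairs
#' @param bin bin width in bp (default 500).
#' @param n_boot bootstrap resamples per bin (0 disables CIs).
#' @param seed RNG seed for the bootstrap.
#' @param skip_above bins with more values than this get no CI.
#' @return data.frame as [bin_decay()] plus `population` and CI columns
#'   `r2_lo`, `r2_hi`, `r2s_lo`, `r2s_hi` (NA where skipped).
#' @export
ld_decay <- function(panel, population, max_dist = 100000L, bin = 500L,
                     classes = c("snp", "sv"), n_boot = 0L, seed = 1L,
                     skip_above = 1000000L) {
  n_bins <- ceiling(max_dist / bin)
  acc <- new.env(parent = emptyenv())
  acc$stats <- list() # class -> list(n, s2, s2s)
  acc$vals <- list() # class -> list of per-bin value lists
  iterate_ld_pairs(
    panel, population, max_dist, classes,
    callback = function(df) {
      for (cl in unique(df$class)) {
        d <- df[df$class == cl, , drop = FALSE]
        b <- ceiling(d$distance / bin)
        if (is.null(acc$stats[[cl]])) {
          acc$stats[[cl]] <- list(
            n = integer(n_bins), s2 = numeric(n_bins), s2s = numeric(n_bins)
          )
          acc$vals[[cl]] <- list(
            r2 = replicate(n_bins, numeric(0), simplify = FALSE),
            r2s = replicate(n_bins, numeric(0), simplify = FALSE)
          )
        }
        st <- acc$stats[[cl]]
        st$n <- st$n + tabulate(b, nbins = n_bins)
        for (k in unique(b)) {
          sel <- b == k
          st$s2[k] <- st$s2[k] + sum(d$r2[sel])
          st$s2s[k] <- st$s2s[k] + sum(d$r2s[sel])
          if (length(acc$vals[[cl]]$r2[[k]]) <= skip_above) {
            acc$vals[[cl]]$r2[[k]] <- c(acc$vals[[cl]]$r2[[k]], d$r2[sel])
            acc$vals[[cl]]$r2s[[k]] <- c(acc$vals[[cl]]$r2s[[k]], d$r2s[sel])
          }
        }
        acc$stats[[cl]] <- st
      }
    }
  )
  rows <- list()
  for (cl in names(acc$stats)) {
    st <- acc$stats[[cl]]
    df <- data.frame(
      class = cl, population = population, bin = seq_len(n_bins),
      bin_start = (seq_len(n_bins) - 1L) * bin,
      bin_end = seq_len(n_bins) * bin, n = st$n,
      mean_r2 = ifelse(st$n > 0L, st$s2 / st$n, NA_real_),
      mean_r2s = ifelse(st$n > 0L, st$s2s / st$n, NA_real_),
      r2_lo = NA_real_, r2_hi = NA_real_,
      r2s_lo = NA_real_, r2s_hi = NA_real_
    )
    if (n_boot > 0L) {
      with_seed(derive_seed(seed, paste0("boot_", cl)), {
        for (k in seq_len(n_bins)) {
          if (st$n[k] < 2L || st$n[k] > skip_above) next
          ci <- bootstrap_bin_ci(
            acc$vals[[cl]]$r2[[k]], n_boot, n_bins, skip_above
          )
          ci_s <- bootstrap_bin_ci(
            acc$vals[[cl]]$r2s[[k]], n_boot, n_bins, skip_above
          )
          if (!is.null(ci)) {
            df$r2_lo[k] <- ci[1L]
            df$r2_hi[k] <- ci[2L]
          }
          if (!is.null(ci_s)) {
            df$r2s_lo[k] <- ci_s[1L]
            df$r2s_hi[k] <- ci_s[2L]
          }
        }
      })
    }
    rows[[cl]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative LD of an SV class versus the SNP-SNP baseline
#'
#' Expresses each of the first `first_n` bin means of the SV class as a
#' percentage of the matching SNP-SNP bin mean and averages across bins,
#' for both r2 and r2s. The `delta` column is the relative r2s minus the
#' relative r2 (how much of the gap allele-frequency standardization
#' closes).
#'
#' @param decay_sv,decay_snp decay data.frames ([bin_decay()]/[ld_decay()])
#'   for the SV class and the SNP-SNP baseline.
#' @param first_n number of leading bins to average (default 10).
#' @return one-row data.frame: `rel_r2_mean`, `rel_r2_sd`, `rel_r2s_mean`,
#'   `rel_r2s_sd`, `delta` (all in percent except `delta`, percent points).
#' @export
relative_ld <- function(decay_sv, decay_snp, first_n = 10L) {
  sv <- decay_sv[order(decay_sv$bin), ][seq_len(first_n), ]
  sn <- decay_snp[order(decay_snp$bin), ][seq_len(first_n), ]
  if (!identical(as.integer(sv$bin), seq_len(first_n)) ||
    !identical(as.integer(sn$bin), seq_len(first_n)) ||
    any(sv$n == 0L) || any(sn$n == 0L)) {
    stop("relative LD requires the first ", first_n,
      " bins to be non-empty for both classes")
  }
  rel_r2 <- 100 * sv$mean_r2 / sn$mean_r2
  rel_r2s <- 100 * sv$mean_r2s / sn$mean_r2s
  data.frame(
    rel_r2_mean = mean(rel_r2), rel_r2_sd = sd(rel_r2),
    rel_r2s_mean = mean(rel_r2s), rel_r2s_sd = sd(rel_r2s),
    delta = mean(rel_r2s) - mean(rel_r2)
  )
}

#' Local minor-allele-frequency difference summary per pair class
#'
#' @param pairs data.frame from [ld_pairs()].
#' @param max_dist restrict to pairs within this distance (default 5 kb).
#' @return data.frame per class: `n`, `median`, `q25`, `q75` of the
#'   pairwise MAF difference.
#' @export
delta_maf_summary <- function(pairs, max_dist = 5000L) {
  p <- pairs[pairs$distance <= max_dist, , drop = FALSE]
  out <- lapply(split(p$dmaf, p$class), function(x) {
    data.frame(
      n = length(x), median = median(x),
      q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75))
    )
  })
  cbind(
    data.frame(class = names(out)),
    do.call(rbind, out)
  )
}

#' Squared Pearson correlation between SNP dosages and DHFFC
#'
#' @param snp_dosages 0/1/2 coded genotypes.
#' @param dhffc_values paired DHFFC values.
#' @return squared Pearson correlation; pairs with missing values are
#'   dropped; constant input is an error.
#' @export
dosage_dhffc_r2 <- function(snp_dosages, dhffc_values) {
  stopifnot(length(snp_dosages) == length(dhffc_values))
  ok <- !is.na(snp_dosages) & !is.na(dhffc_values)
  x <- snp_dosages[ok]
  y <- dhffc_values[ok]
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for constant or empty input")
  }
  cor(x, y)^2
}
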