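# Callset descriptive statistics: genotype counts, Hardy-Weinberg exact
# testing with per-class Bonferroni correction, per-individual genome
# fractions affected by each variant type, length/coverage/MAF summaries,
# and the chromosome-length bias regression.

#' Genotype counts from a dosage vector
#' @param dosages 0/1/2 dosages with `NA` for missing.
#' @return named integer vector `n_homref`, `n_het`, `n_homvar`
#'   (non-missing only).
#' @export
genotype_counts <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  c(
    n_homref = sum(d == 0L), n_het = sum(d == 1L), n_homvar = sum(d == 2L)
  )
}

#' Exact Hardy-Weinberg test (Haldane/Levene conditional distribution)
#'
#' Conditions on the observed minor-allele count: the probability of a
#' genotype configuration (n_homref, n_het, n_homvar) is proportional to
#' the multinomial coefficient times `2^n_het`. The two-sided p-value sums
#' the probabilities of all configurations no more probable than the
#' observed one.
#'
#' @param counts named vector as from [genotype_counts()] (order homref,
#'   het, homvar also accepted unnamed).
#' @return list: `p` (exact two-sided p), `deviation` (observed n_homvar
#'   minus `n q^2` with q the variant-allele frequency), `q`, `n`.
#' @export
hwe_exact <- function(counts) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0L))
  n <- sum(counts)
  n_var <- counts[2L] + 2L * counts[3L]
  if (n_var == 0L || n_var == 2L * n) {
    stop("HWE test undefined for monomorphic genotype counts")
  }
  minor <- min(n_var, 2L * n - n_var)
  # heterozygote counts compatible with (n, minor): same parity, feasible homs
  b <- seq.int(minor %% 2L, minor, by = 2L)
  n_min_hom <- (minor - b) %/% 2L
  n_maj_hom <- n - b - n_min_hom
  b <- b[n_maj_hom >= 0L]
  n_min_hom <- n_min_hom[n_maj_hom >= 0L]
  n_maj_hom <- n_maj_hom[n_maj_hom >= 0L]
  lw <- lfactorial(n) - lfactorial(n_maj_hom) - lfactorial(b) -
    lfactorial(n_min_hom) + b * log(2)
  pr <- exp(lw - max(lw))
  pr <- pr / sum(pr)
  obs <- match(counts[2L], b)
  stopifnot(!is.na(obs))
  p <- sum(pr[pr <= pr[obs] * (1 + 1e-12)])
  q <- n_var / (2 * n)
  list(p = min(p, 1), deviation = counts[3L] - n * q^2, q = q, n = n)
}

#' HWE exact-test scan with within-class Bonferroni correction
#'
#' Tests every polymorphic variant of the given population; the correction
#' factor for a variant is the number of testable variants of its class.
#'
#' @param variants a [variant_table()].
#' @param geno dosage matrix (variants x samples).
#' @param samples optional subset of sample ids (e.g. one population).
#' @return data.frame: id, class, counts, `p`, `p_bonf`, `deviation`,
#'   `significant` (at 0.05 after correction).
#' @export
hwe_scan <- function(variants, geno, samples = NULL) {
  g <- geno[variants$id, , drop = FALSE]
  if (!is.null(samples)) g <- g[, samples, drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    cnt <- genotype_counts(g[i, ])
    nv <- cnt[2L] + 2L * cnt[3L]
    if (nv == 0L || nv == 2L * sum(cnt)) next
    h <- hwe_exact(cnt)
    rows[[length(rows) + 1L]] <- data.frame(
      id = variants$id[i], class = variants$vtype[i],
      n_homref = cnt[1L], n_het = cnt[2L], n_homvar = cnt[3L],
      p = h$p, deviation = h$deviation
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(
      id = character(0), class = character(0), n_homref = integer(0),
      n_het = integer(0), n_homvar = integer(0), p = numeric(0),
      deviation = numeric(0), p_bonf = numeric(0), significant = logical(0)
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class_n <- table(out$class)
  out$p_bonf <- pmin(1, out$p * as.integer(class_n[out$class]))
  out$significant <- out$p_bonf < 0.05
  out
}

#' Per-individual genome fraction affected by each variant type
#'
#' For each individual and variant type: the union length of spans carrying
#' the non-reference allele on a haplotype (SNPs and BNDs contribute 1 bp),
#' averaged over the individual's two haplotypes, divided by the autosomal
#' genome length. Also returns the homozygously deleted fraction (positions
#' deleted on both haplotypes).
#'
#' @param panel a [haplotype_panel()].
#' @param genome a [genome_table()].
#' @return data.frame: `sample`, `population`, one column per variant type
#'   (fractions), `hom_del` (fraction).
#' @export
affected_fraction <- function(panel, genome) {
  auto <- genome$chrom[genome$autosome]
  auto_len <- sum(as.numeric(genome$length[genome$autosome]))
  v <- panel$variants
  on_auto <- v$chrom %in% auto
  n <- length(panel$samples)
  types <- intersect(VARIANT_TYPES, unique(v$vtype))
  out <- data.frame(
    sample = panel$samples, population = panel$populations
  )
  for (t in types) out[[t]] <- 0
  out$hom_del <- 0
  idx_t <- lapply(types, function(t) which(on_auto & v$vtype == t))
  names(idx_t) <- types
  for (s in seq_len(n)) {
    h1 <- panel$alleles[2L * s - 1L, ]
    h2 <- panel$alleles[2L * s, ]
    for (t in types) {
      ii <- idx_t[[t]]
      lens <- vapply(list(h1, h2), function(h) {
        jj <- ii[h[ii] == 1L]
        if (length(jj) == 0L) {
          return(0)
        }
        tot <- 0
        for (ch in unique(v$chrom[jj])) {
          kk <- jj[v$chrom[jj] == ch]
          tot <- tot + interval_union_length(v$start[kk], v$end[kk])
        }
        tot
      }, numeric(1))
      out[[t]][s] <- mean(lens) / auto_len
    }
    dd <- idx_t[["DEL"]]
    if (!is.null(dd) && length(dd)) {
      hom <- 0
      for (ch in unique(v$chrom[dd])) {
        kk <- dd[v$chrom[dd] == ch]
        a <- kk[h1[kk] == 1L]
        b <- kk[h2[kk] == 1L]
        if (length(a) && length(b)) {
          hom <- hom + interval_intersect_length(
            data.frame(start = v$start[a], end = v$end[a]),
            data.frame(start = v$start[b], end = v$end[b])
          )
        }
      }
      out$hom_del[s] <- hom / auto_len
    }
  }
  out
}

#' Callset summaries: lengths, genome coverage, MAF spectra
#'
#' @param variants a [variant_table()].
#' @param geno dosage matrix (variants x samples) used for allele
#'   frequencies.
#' @param genome a [genome_table()].
#' @param populations optional per-sample population labels (adds per-
#'   population MAF columns).
#' @return list: `lengths` (per type median/max, BND excluded), `coverage`
#'   (per type union span fraction of the autosomes; SNPs count 1 bp each),
#'   `maf` (per variant, pooled and per population).
#' @export
callset_summaries <- function(variants, geno, genome, populations = NULL) {
  auto <- genome$chrom[genome$autosome]
  auto_len <- sum(as.numeric(genome$length[genome$autosome]))
  v <- variants[variants$chrom %in% auto, , drop = FALSE]
  span_types <- setdiff(unique(v$vtype), c("SNP", "BND"))
  lengths_df <- do.call(rbind, lapply(span_types, function(t) {
    len <- v$end[v$vtype == t] - v$start[v$vtype == t]
    data.frame(
      vtype = t, n = length(len), median_bp = median(len),
      max_bp = max(len)
    )
  })) %||% data.frame(
    vtype = character(0), n = integer(0),
    median_bp = numeric(0), max_bp = numeric(0)
  )
  cov_rows <- lapply(unique(v$vtype), function(t) {
    ii <- which(v$vtype == t)
    covered <- sum(vapply(unique(v$chrom[ii]), function(ch) {
      kk <- ii[v$chrom[ii] == ch]
      as.numeric(interval_union_length(v$start[kk], v$end[kk]))
    }, numeric(1)))
    data.frame(vtype = t, fraction = covered / auto_len)
  })
  coverage <- do.call(rbind, cov_rows)
  g <- geno[v$id, , drop = FALSE]
  p <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  maf <- data.frame(
    id = v$id, vtype = v$vtype, maf = pmin(p, 1 - p)
  )
  if (!is.null(populations)) {
    for (pp in unique(populations)) {
      gp <- g[, populations == pp, drop = FALSE]
      fp <- rowSums(gp, na.rm = TRUE) / (2 * rowSums(!is.na(gp)))
      maf[[paste0("maf_", pp)]] <- pmin(fp, 1 - fp)
    }
  }
  list(lengths = lengths_df, coverage = coverage, maf = maf)
}

#' Chromosome-length bias regression for one variant type
#'
#' Regresses the relative number of called variants per chromosome on the
#' relative chromosome length (OLS with intercept) and t-tests the slope
#' against 1 (the line of identity). A perfect fit (zero residual variance)
#' reports p = 1 when the slope equals 1.
#'
#' @param variants a [variant_table()].
#' @param genome a [genome_table()] (autosomes used).
#' @param vtype variant type to count.
#' @return list: `slope`, `p` (H0: slope = 1), `r_squared`, `n_chrom`.
#' @export
chromosome_bias <- function(variants, genome, vtype) {
  gen <- genome[genome$autosome, , drop = FALSE]
  if (nrow(gen) < 3L) {
    stop("chromosome bias regression needs at least 3 chromosomes")
  }
  cnt <- vapply(gen$chrom, function(ch) {
    sum(variants$chrom == ch & variants$vtype == vtype)
  }, numeric(1))
  if (sum(cnt) == 0L) stop("no variants of type ", vtype)
  y <- cnt / sum(cnt)
  x <- gen$length / sum(as.numeric(gen$length))
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  fs <- suppressWarnings(summary(fit)) # perfect fits warn in summary.lm
  se <- fs$coefficients[2L, 2L]
  rss <- sum(residuals(fit)^2)
  p <- if (rss < 1e-20 || se == 0) {
    if (abs(slope - 1) < 1e-12) 1 else 0
  } else {
    tval <- (slope - 1) / se
    2 * pt(-abs(tval), df = nrow(gen) - 2L)
  }
  list(
    slope = slope, p = p,
    r_squared = fs$r.squared, n_chrom = nrow(gen)
  )
}
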