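# Consensus merge of per-caller SV callsets and the five-rule filtering
# procedure: (1) caller overlap, (2) genotype concordance, (3) high-coverage
# region masking, (4) flanking fold-change consistency (DHFFC), (5) SNP
# support on deletions. INV/BND bypass rules 4-5 (no usable coverage
# signal). Genotypes that lose support are set missing and only refilled by
# fill_missing_genotypes().

#' Filtering configuration (rule thresholds in pipeline order)
#'
#' @param tolerance merge breakpoint tolerance in bp.
#' @param max_discordant_samples max samples without a 2-of-3 consensus
#'   genotype before the SV is dropped.
#' @param merge_gap high-coverage windows closer than this merge into one
#'   region (bp).
#' @param flank DHFFC flank width (bp).
#' @param dhffc_het_del closed interval of valid het-DEL DHFFC.
#' @param dhffc_hom_del hom-DEL DHFFC must be strictly below this.
#' @param dhffc_het_dup,dhffc_hom_dup het/hom DUP DHFFC must strictly
#'   exceed these.
#' @param max_dhffc_errors,max_dhffc_error_rate removal thresholds for
#'   rule 4 (strictly more than `max_dhffc_errors` wrong genotypes, or a
#'   wrong fraction strictly above `max_dhffc_error_rate`).
#' @param snp_support_halved if `TRUE`, rule-5 per-sample error rates are
#'   violations / (2 x SNPs on the DEL) (per-allele reading) instead of the
#'   default simple ratio.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(tolerance = 1000L,
                          max_discordant_samples = 2L,
                          merge_gap = 1000L,
                          flank = 1000L,
                          dhffc_het_del = c(0.1, 0.9),
                          dhffc_hom_del = 0.25,
                          dhffc_het_dup = 1.1,
                          dhffc_hom_dup = 1.5,
                          max_dhffc_errors = 1L,
                          max_dhffc_error_rate = 0.10,
                          snp_support_halved = FALSE) {
  structure(
    list(
      tolerance = tolerance,
      max_discordant_samples = max_discordant_samples,
      merge_gap = merge_gap, flank = flank,
      dhffc_het_del = dhffc_het_del, dhffc_hom_del = dhffc_hom_del,
      dhffc_het_dup = dhffc_het_dup, dhffc_hom_dup = dhffc_hom_dup,
      max_dhffc_errors = max_dhffc_errors,
      max_dhffc_error_rate = max_dhffc_error_rate,
      snp_support_halved = snp_support_halved
    ),
    class = "filter_config"
  )
}

#' Merge per-caller callsets with breakpoint tolerance
#'
#' SVs of the same type on the same chromosome are chained greedily
#' left-to-right: a call joins the chain when both its start and its end lie
#' within `tolerance` bp of the previous chain member (BNDs compare the
#' single breakpoint only). Canonical breakpoints are the per-chain medians
#' (lower value on even ties). Mixed types never merge.
#'
#' @param callsets list of per-caller [sv_callset()]s.
#' @param tolerance breakpoint tolerance in bp (default 1000).
#' @return list of class `merged_svs`: `variants` (canonical
#'   [variant_table()]), `support` (list of caller-id vectors),
#'   `caller_geno` (per-caller dosage matrices aligned to merged ids, `NA`
#'   where the caller has no call), `samples`.
#' @export
merge_callsets <- function(callsets, tolerance = 1000L) {
  callers <- vapply(
    callsets, function(x) x$caller %||% "caller", character(1)
  )
  names(callsets) <- callers
  samples <- callsets[[1L]]$samples
  long <- do.call(rbind, lapply(callers, function(cal) {
    v <- callsets[[cal]]$variants
    data.frame(
      caller = cal, id = v$id, chrom = v$chrom, start = v$start,
      end = v$end, vtype = v$vtype, ci_start = v$ci_start,
      ci_end = v$ci_end
    )
  }))
  long <- long[order(long$vtype, long$chrom, long$start, long$end), ,
    drop = FALSE
  ]
  point <- long$vtype == "BND"
  chain <- integer(nrow(long))
  cur <- 0L
  for (i in seq_len(nrow(long))) {
    new <- i == 1L ||
      long$vtype[i] != long$vtype[i - 1L] ||
      long$chrom[i] != long$chrom[i - 1L] ||
      abs(long$start[i] - long$start[i - 1L]) > tolerance ||
      (!point[i] && abs(long$end[i] - long$end[i - 1L]) > tolerance)
    if (new) cur <- cur + 1L
    chain[i] <- cur
  }
  groups <- split(seq_len(nrow(long)), chain)

  nvar <- length(groups)
  mids <- character(nvar)
  m_chrom <- character(nvar)
  m_start <- integer(nvar)
  m_end <- integer(nvar)
  m_type <- character(nvar)
  m_cis <- integer(nvar)
  m_cie <- integer(nvar)
  support <- vector("list", nvar)
  geno <- lapply(callers, function(cal) {
    matrix(NA_integer_, nvar, length(samples),
      dimnames = list(NULL, samples)
    )
  })
  names(geno) <- callers
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    # at most one record per caller per chain: keep the leftmost
    first <- idx[!duplicated(long$caller[idx])]
    m_type[g] <- long$vtype[first[1L]]
    m_chrom[g] <- long$chrom[first[1L]]
    m_start[g] <- median_low(long$start[first])
    m_end[g] <- if (m_type[g] %in% c("BND", "SNP")) {
      m_start[g] + 1L
    } else {
      max(m_start[g] + 1L, median_low(long$end[first]))
    }
    m_cis[g] <- max(long$ci_start[first])
    m_cie[g] <- max(long$ci_end[first])
    support[[g]] <- long$caller[first]
    mids[g] <- sprintf("msv_%s_%s_%d", tolower(m_type[g]), m_chrom[g], m_start[g])
    for (j in first) {
      cal <- long$caller[j]
      geno[[cal]][g, ] <- callsets[[cal]]$geno[long$id[j], ]
    }
  }
  dup <- duplicated(mids)
  mids[dup] <- paste0(mids[dup], "_", seq_len(sum(dup)))
  variants <- variant_table(
    id = mids, chrom = m_chrom, start = m_start, end = m_end,
    vtype = m_type, ci_start = m_cis, ci_end = m_cie
  )
  ord <- match(variants$id, mids)
  geno <- lapply(geno, function(m) {
    m <- m[ord, , drop = FALSE]
    rownames(m) <- variants$id
    m
  })
  structure(
    list(
      variants = variants, support = support[ord],
      caller_geno = geno, samples = samples,
      consensus = NULL
    ),
    class = "merged_svs"
  )
}

subset_merged <- function(merged, keep) {
  structure(
    list(
      variants = {
        v <- merged$variants[keep, , drop = FALSE]
        rownames(v) <- NULL
        class(v) <- c("variant_table", "data.frame")
        v
      },
      support = merged$support[keep],
      caller_geno = lapply(
        merged$caller_geno, function(m) m[keep, , drop = FALSE]
      ),
      samples = merged$samples,
      consensus = if (!is.null(merged$consensus)) {
        merged$consensus[keep, , drop = FALSE]
      }
    ),
    class = "merged_svs"
  )
}

#' Rule 1: caller overlap
#'
#' Retains merged SVs supported by at least two of the three callers.
#'
#' @param merged a `merged_svs` object.
#' @return list `retained`, `removed` (both `merged_svs`).
#' @export
filter_caller_overlap <- function(merged) {
  keep <- lengths(merged$support) >= 2L
  list(retained = subset_merged(merged, keep),
       removed = subset_merged(merged, !keep))
}

#' Rule 2: genotype concordance
#'
#' Per sample, the consensus genotype is the value shared by at least two
#' supporting callers; samples without such a 2-vote genotype are set
#' missing. SVs with more than `max_discordant_samples` such samples are
#' removed.
#'
#' @param merged a `merged_svs` object (after rule 1).
#' @param max_discordant_samples threshold (default 2).
#' @return list `retained` (with `$consensus` dosage matrix), `removed`,
#'   and `n_set_missing` (genotypes set missing on retained SVs).
#' @export
consensus_genotypes <- function(merged, max_discordant_samples = 2L) {
  nv <- nrow(merged$variants)
  ns <- length(merged$samples)
  cons <- matrix(NA_integer_, nv, ns,
    dimnames = list(merged$variants$id, merged$samples)
  )
  n_disc <- integer(nv)
  for (i in seq_len(nv)) {
    votes <- do.call(rbind, lapply(
      merged$support[[i]],
      function(cal) merged$caller_geno[[cal]][i, ]
    ))
    for (v in 0:2) {
      cnt <- colSums(votes == v, na.rm = TRUE)
      cons[i, cnt >= 2L] <- v
    }
    n_disc[i] <- sum(is.na(cons[i, ]))
  }
  keep <- n_disc <= max_discordant_samples
  merged$consensus <- cons
  out <- subset_merged(merged, keep)
  list(
    retained = out,
    removed = subset_merged(merged, !keep),
    n_set_missing = sum(n_disc[keep])
  )
}

#' Rule 3a: flag unusually highly covered regions
#'
#' A window is flagged when its cross-sample mean coverage strictly exceeds
#' `2 * mu + 2 * sigma`, where `mu` and `sigma` are the mean and SD of the
#' cross-sample window means over all autosomal windows. Flagged windows
#' closer than `merge_gap` bp are merged into regions.
#'
#' @param depth a [depth_profile()].
#' @param genome optional [genome_table()]; non-autosomal chromosomes are
#'   excluded from the threshold estimation and flagging.
#' @param merge_gap merge distance in bp (default 1000).
#' @return list of class `high_coverage_regions`: `regions` (data.frame
#'   `chrom`,`start`,`end`), `threshold`, `mu`, `sigma`.
#' @export
flag_high_coverage_regions <- function(depth, genome = NULL,
                                       merge_gap = 1000L) {
  chroms <- names(depth$depth)
  if (!is.null(genome)) {
    chroms <- intersect(chroms, genome$chrom[genome$autosome])
  }
  means <- lapply(depth$depth[chroms], rowMeans)
  all_means <- unlist(means, use.names = FALSE)
  mu <- mean(all_means)
  sigma <- sd(all_means)
  thr <- 2 * mu + 2 * sigma
  w <- depth$window
  regions <- do.call(rbind, lapply(chroms, function(ch) {
    flagged <- which(means[[ch]] > thr)
    if (length(flagged) == 0L) {
      return(NULL)
    }
    m <- merge_intervals((flagged - 1L) * w, flagged * w, gap = merge_gap)
    cbind(data.frame(chrom = ch), m)
  }))
  if (is.null(regions)) {
    regions <- data.frame(
      chrom = character(0), start = integer(0), end = integer(0)
    )
  }
  structure(
    list(regions = regions, threshold = thr, mu = mu, sigma = sigma),
    class = "high_coverage_regions"
  )
}

#' Rule 3b: remove SVs whose breakpoint CIs fall in flagged regions
#'
#' The half-open interval `[bp - ci, bp + ci)` around each breakpoint (only
#' the single breakpoint for BNDs) is intersected with the flagged regions.
#'
#' @param merged a `merged_svs` object.
#' @param regions output of [flag_high_coverage_regions()].
#' @return list `retained`, `removed`.
#' @export
filter_high_coverage <- function(merged, regions) {
  v <- merged$variants
  hit <- logical(nrow(v))
  for (ch in unique(v$chrom)) {
    reg <- regions$regions[regions$regions$chrom == ch, , drop = FALSE]
    ii <- which(v$chrom == ch)
    if (nrow(reg) == 0L || length(ii) == 0L) next
    s1 <- v$start[ii] - v$ci_start[ii]
    e1 <- v$start[ii] + v$ci_start[ii]
    hs <- intervals_overlap_any(s1, e1, reg$start, reg$end)
    point <- v$vtype[ii] == "BND"
    s2 <- v$end[ii] - v$ci_end[ii]
    e2 <- v$end[ii] + v$ci_end[ii]
    he <- intervals_overlap_any(s2, e2, reg$start, reg$end)
    hit[ii] <- hs | (he & !point)
  }
  list(retained = subset_merged(merged, !hit),
       removed = subset_merged(merged, hit))
}

#' Duphold-style flanking fold change (DHFFC)
#'
#' Median windowed coverage inside the span divided by the median over the
#' two flanks (pooled, `flank` bp each). Undefined (NA) when the flank
#' median is zero.
#'
#' @param chrom,start,end SV span (0-based half-open).
#' @param depth a [depth_profile()].
#' @param flank flank width in bp (default 1000).
#' @return named numeric vector of per-sample DHFFC values.
#' @export
compute_dhffc <- function(chrom, start, end, depth, flank = 1000L) {
  m <- depth$depth[[chrom]]
  if (is.null(m)) stop("no depth for chromosome ", chrom)
  w <- depth$window
  nwin <- nrow(m)
  inside <- windows_inside(start, end, w, nwin)
  lf <- windows_inside(max(0L, start - flank), start, w, nwin)
  rf <- windows_inside(end, min(nwin * w, end + flank), w, nwin)
  lf <- lf[lf * w <= start]
  rf <- rf[(rf - 1L) * w >= end]
  fl <- union(lf, rf)
  ins_med <- apply(m[inside, , drop = FALSE], 2L, median)
  fl_med <- apply(m[fl, , drop = FALSE], 2L, median)
  out <- ins_med / fl_med
  out[fl_med == 0] <- NA_real_
  setNames(out, depth$samples)
}

#' Rule 4: DHFFC genotype consistency for DELs and DUPs
#'
#' Het DELs are valid in the closed interval `[0.1, 0.9]`, hom DELs
#' strictly below 0.25, het DUPs strictly above 1.1, hom DUPs strictly
#' above 1.5 (reference genotypes are never tested). SVs with more than one
#' wrong genotype or more than 10% wrong among tested are removed;
#' otherwise wrong genotypes are set missing. INV/BND pass through.
#'
#' @param merged a `merged_svs` object with consensus genotypes.
#' @param depth a [depth_profile()].
#' @param config a [filter_config()].
#' @return list `retained`, `removed`, `n_set_missing`, `dhffc` (matrix for
#'   DEL/DUP rows of the input).
#' @export
filter_dhffc <- function(merged, depth, config = filter_config()) {
  v <- merged$variants
  cn <- which(v$vtype %in% c("DEL", "DUP"))
  remove <- logical(nrow(v))
  n_missing <- 0L
  dh_all <- matrix(NA_real_, nrow(v), length(merged$samples),
    dimnames = list(v$id, merged$samples)
  )
  for (i in cn) {
    dh <- compute_dhffc(
      v$chrom[i], v$start[i], v$end[i], depth,
      flank = config$flank
    )
    dh_all[i, ] <- dh
    g <- merged$consensus[i, ]
    tested <- which(!is.na(g) & g > 0L & !is.na(dh))
    if (length(tested) == 0L) next
    wrong <- if (v$vtype[i] == "DEL") {
      ifelse(g[tested] == 1L,
        dh[tested] < config$dhffc_het_del[1L] |
          dh[tested] > config$dhffc_het_del[2L],
        !(dh[tested] < config$dhffc_hom_del)
      )
    } else {
      ifelse(g[tested] == 1L,
        !(dh[tested] > config$dhffc_het_dup),
        !(dh[tested] > config$dhffc_hom_dup)
      )
    }
    nw <- sum(wrong)
    if (nw > config$max_dhffc_errors ||
      nw / length(tested) > config$max_dhffc_error_rate) {
      remove[i] <- TRUE
    } else if (nw > 0L) {
      merged$consensus[i, tested[wrong]] <- NA_integer_
      n_missing <- n_missing + nw
    }
  }
  list(
    retained = subset_merged(merged, !remove),
    removed = subset_merged(merged, remove),
    n_set_missing = n_missing,
    dhffc = dh_all
  )
}

#' Rule 5: SNP support on deletions
#'
#' SNP calls inside a DEL span must be homozygous on het-DEL samples and
#' missing on hom-DEL samples. The per-sample error rate is the number of
#' violating SNP calls over the number of SNPs on the DEL (or twice that
#' with `snp_support_halved`). A DEL is removed when the summed error rate
#' exceeds 2 or half the number of carrier samples; otherwise the violating
#' DEL genotypes are set missing.
#'
#' @param merged a `merged_svs` object with consensus genotypes.
#' @param snp_calls SNP dosage matrix (SNPs x samples, `NA` = missing),
#'   pre-imputation.
#' @param snp_variants [variant_table()] of the SNP rows.
#' @param config a [filter_config()].
#' @return list `retained`, `removed`, `n_set_missing`.
#' @export
filter_del_snp_support <- function(merged, snp_calls, snp_variants,
                                   config = filter_config()) {
  v <- merged$variants
  remove <- logical(nrow(v))
  n_missing <- 0L
  denom_mult <- if (config$snp_support_halved) 2L else 1L
  for (i in which(v$vtype == "DEL")) {
    on_del <- snp_variants$chrom == v$chrom[i] &
      snp_variants$start >= v$start[i] & snp_variants$start < v$end[i]
    n_snps <- sum(on_del)
    if (n_snps == 0L) next
    calls <- snp_calls[snp_variants$id[on_del], , drop = FALSE]
    g <- merged$consensus[i, ]
    carriers <- which(!is.na(g) & g >= 1L)
    if (length(carriers) == 0L) next
    e_s <- setNames(numeric(length(carriers)), names(g)[carriers])
    for (k in seq_along(carriers)) {
      s <- carriers[k]
      viol <- if (g[s] == 1L) {
        sum(calls[, s] == 1L, na.rm = TRUE)
      } else {
        sum(!is.na(calls[, s]))
      }
      e_s[k] <- viol / (denom_mult * n_snps)
    }
    tot <- sum(e_s)
    if (tot > 2 || tot > 0.5 * length(carriers)) {
      remove[i] <- TRUE
    } else {
      bad <- carriers[e_s > 0]
      if (length(bad)) {
        merged$consensus[i, bad] <- NA_integer_
        n_missing <- n_missing + length(bad)
      }
    }
  }
  list(
    retained = subset_merged(merged, !remove),
    removed = subset_merged(merged, remove),
    n_set_missing = n_missing
  )
}

#' Fill missing consensus genotypes and build a phased panel
#'
#' Stand-in for statistical imputation/phasing: each missing genotype is
#' replaced by two alleles drawn from the variant's non-missing allele
#' frequency; heterozygotes are phased by random assignment unless a
#' `phase_hint` allele matrix (e.g. simulator truth, emulating the high
#' accuracy of LD-based phasing) resolves them. Deterministic given `seed`.
#'
#' @param variants a [variant_table()].
#' @param geno dosage matrix (variants x samples) with `NA` for missing.
#' @param samples sample ids (columns of `geno`).
#' @param populations per-sample population labels.
#' @param seed integer seed.
#' @param phase_hint optional 0/1 allele matrix (2N x variants, columns
#'   named by variant id) giving the preferred phase for het genotypes.
#' @return a [haplotype_panel()] over `variants`.
#' @export
fill_missing_genotypes <- function(variants, geno, samples, populations,
                                   seed = 1L, phase_hint = NULL) {
  with_seed(seed, {
    nv <- nrow(variants)
    n <- length(samples)
    al <- matrix(0L, nrow = 2L * n, ncol = nv)
    colnames(al) <- variants$id
    for (i in seq_len(nv)) {
      id <- variants$id[i]
      d <- geno[id, ]
      nm <- !is.na(d)
      p <- if (any(nm)) sum(d[nm]) / (2 * sum(nm)) else 0.5
      a1 <- integer(n)
      a2 <- integer(n)
      miss <- which(!nm)
      if (length(miss)) {
        a1[miss] <- rbinom(length(miss), 1L, p)
        a2[miss] <- rbinom(length(miss), 1L, p)
      }
      hom <- which(nm & d == 2L)
      a1[hom] <- 1L
      a2[hom] <- 1L
      het <- which(nm & d == 1L)
      if (length(het)) {
        flip <- rbinom(length(het), 1L, 0.5) == 1L
        if (!is.null(phase_hint) && id %in% colnames(phase_hint)) {
          hintA <- phase_hint[2L * het - 1L, id]
          hintB <- phase_hint[2L * het, id]
          use <- hintA + hintB == 1L
          flip[use] <- hintB[use] == 1L
        }
        a1[het] <- as.integer(!flip)
        a2[het] <- as.integer(flip)
      }
      al[2L * seq_len(n) - 1L, i] <- a1
      al[2L * seq_len(n), i] <- a2
    }
    haplotype_panel(al, samples, variants, populations)
  })
}

#' Run the full filtering pipeline in its fixed rule order
#'
#' merge -> caller overlap -> genotype concordance -> high-coverage region
#' masking -> DHFFC -> deletion SNP support. Emits the filtered callset, a
#' per-rule conservation report, the flagged regions and a review manifest
#' (DHFFC summaries per retained SV, replacing the visual screen).
#'
#' @param callsets list of per-caller [sv_callset()]s.
#' @param depth a [depth_profile()].
#' @param snp_calls,snp_variants SNP dosage matrix and variant table for
#'   rule 5.
#' @param config a [filter_config()].
#' @param genome optional [genome_table()] for autosome selection in rule 3.
#' @return list of class `filter_result`: `svs` (retained `merged_svs` with
#'   consensus genotypes), `report` (data.frame rule/input/removed/
#'   retained/genotypes_set_missing), `regions`, `manifest`.
#' @export
run_filter_pipeline <- function(callsets, depth, snp_calls, snp_variants,
                                config = filter_config(), genome = NULL) {
  merged <- merge_callsets(callsets, tolerance = config$tolerance)
  report <- data.frame(
    rule = character(0), input = integer(0), removed = integer(0),
    retained = integer(0), genotypes_set_missing = integer(0)
  )
  note <- function(rule, input, removed, miss = 0L) {
    rbind(report, data.frame(
      rule = rule, input = input, removed = removed,
      retained = input - removed, genotypes_set_missing = miss
    ))
  }

  r1 <- filter_caller_overlap(merged)
  report <- note(
    "caller_overlap", nrow(merged$variants), nrow(r1$removed$variants)
  )
  r2 <- consensus_genotypes(r1$retained, config$max_discordant_samples)
  report <- note(
    "genotype_concordance", nrow(r1$retained$variants),
    nrow(r2$removed$variants), r2$n_set_missing
  )
  regions <- flag_high_coverage_regions(
    depth,
    genome = genome, merge_gap = config$merge_gap
  )
  r3 <- filter_high_coverage(r2$retained, regions)
  report <- note(
    "high_coverage_regions", nrow(r2$retained$variants),
    nrow(r3$removed$variants)
  )
  r4 <- filter_dhffc(r3$retained, depth, config)
  report <- note(
    "dhffc", nrow(r3$retained$variants), nrow(r4$removed$variants),
    r4$n_set_missing
  )
  r5 <- filter_del_snp_support(r4$retained, snp_calls, snp_variants, config)
  report <- note(
    "del_snp_support", nrow(r4$retained$variants),
    nrow(r5$removed$variants), r5$n_set_missing
  )
  final <- r5$retained
  dh <- r4$dhffc[final$variants$id[final$variants$vtype %in% c("DEL", "DUP")],
    ,
    drop = FALSE
  ]
  manifest <- data.frame(
    id = final$variants$id, vtype = final$variants$vtype,
    support = vapply(final$support, length, integer(1)),
    n_missing_genotypes = rowSums(is.na(final$consensus)),
    median_dhffc = NA_real_
  )
  if (nrow(dh)) {
    manifest$median_dhffc[match(rownames(dh), manifest$id)] <-
      apply(dh, 1L, median, na.rm = TRUE)
  }
  structure(
    list(svs = final, report = report, regions = regions, manifest = manifest),
    class = "filter_result"
  )
}
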