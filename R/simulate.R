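# Founder-mosaic simulator.
#
# Haplotypes are mosaics of K founder haplotypes: along each chromosome a
# haplotype copies one founder per segment, segment lengths are exponential
# with mean L. Two loci share founder ancestry with a probability that
# decays on the scale L, so SNP-SNP r2 decays with distance and its level is
# controlled by the founder count (fewer founders => stronger LD). Three
# populations with different (K, L) reproduce the ordering of LD strength
# between a low-diversity layer line, a second layer line and a more diverse
# broiler line. SVs are planted on founder-segment backgrounds (complete LD
# with the local backbone) and then resampled towards a type-specific target
# MAF, which creates controlled local MAF differences; caller error channels
# add genotype noise and a systematic hom->het miscall for DUP/INV/BND.

#' Simulation configuration
#'
#' Defaults are the desk-scale study conditions: three populations with
#' decreasing LD strength (WL > BL > BR), two 5 Mb chromosomes, ~15k SNPs
#' and ~300 SVs per run, SV MAF spectra shifted towards rare variants for
#' DEL (slightly) and DUP (strongly) and towards common variants for
#' INV/BND, per-sample median coverage between 5 and 17x in 100 bp windows,
#' and a systematic heterozygote-miscall channel for hom DUP/INV/BND
#' genotypes shared by all callers.
#'
#' @param seed integer seed; all stage seeds derive from it.
#' @param populations population labels.
#' @param n_samples,founders,segment_scale named per-population vectors:
#'   sample count, founder-haplotype count K, and mosaic segment scale L
#'   (bp, the LD-decay scale).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param snp_density SNPs per bp.
#' @param sv_counts named integer vector of SV counts by type.
#' @param snp_maf_shape beta shape pair for SNP site frequencies.
#' @param sv_maf_shape named list of beta shape pairs for per-type target
#'   SV MAFs.
#' @param sv_snp_thinning named per-type probability that a backbone SNP
#'   within `sv_snp_thinning_margin` bp of a planted SV span is removed
#'   from the panel, emulating the reduced SNP density observed around
#'   structural variants (strongest for DEL).
#' @param sv_snp_thinning_margin margin in bp around SV spans for thinning.
#' @param sv_resample_prob named per-type probability that an SV's carriers
#'   are resampled towards an independent target MAF draw (creating local
#'   MAF differences); non-resampled SVs inherit their founder background
#'   frequency and therefore behave like backbone SNPs. Deletions are
#'   mostly background-coupled (their LD to SNPs matches SNP-SNP LD), the
#'   other classes are fully resampled.
#' @param sv_length named list of (meanlog, sdlog) log-normal span
#'   parameters for DEL/DUP/INV (BND is a point).
#' @param depth_mean_range per-sample mean coverage drawn uniformly from
#'   this range (x).
#' @param depth_sd per-window coverage SD.
#' @param window depth window width (bp).
#' @param artifact_n,artifact_fold,artifact_length number, coverage fold and
#'   length of planted low-complexity coverage artifact regions.
#' @param sv_min_gap minimum spacing (bp) kept between planted SV spans so
#'   that each SV's coverage signal (span and flanks) is attributable to it.
#' @param callers caller labels (three).
#' @param caller_sensitivity matrix (callers x types) of detection
#'   probabilities.
#' @param genotype_error matrix (callers x types) of independent per-call
#'   genotype error rates.
#' @param hom_het_miscall named per-type probability that a true homozygous
#'   variant genotype is systematically miscalled heterozygous by all
#'   callers (the genotyper deficit channel for non-DEL SVs).
#' @param systematic_error named per-type probability that a genotype is
#'   replaced by a random different value consistently in all callsets
#'   (shared genotyper failure; consensus voting cannot repair it, and for
#'   INV/BND no coverage signal can catch it either).
#' @param breakpoint_jitter named per-caller SD (bp) of breakpoint jitter.
#' @param snp_call_error probability that an emitted SNP genotype call is
#'   corrupted (used by the deletion SNP-support filter inputs).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    populations = c("WL", "BL", "BR"),
    n_samples = c(WL = 25L, BL = 25L, BR = 40L),
    founders = c(WL = 3L, BL = 4L, BR = 6L),
    segment_scale = c(WL = 60000, BL = 40000, BR = 25000),
    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
    snp_density = 1.5e-3,
    sv_counts = c(DEL = 180L, DUP = 40L, INV = 45L, BND = 35L),
    snp_maf_shape = c(0.5, 1.5),
    sv_maf_shape = list(
      DEL = c(1.2, 4.0), DUP = c(1.0, 6.0),
      INV = c(4.0, 2.0), BND = c(4.0, 2.0)
    ),
    sv_resample_prob = c(DEL = 0.15, DUP = 1, INV = 1, BND = 1),
    sv_snp_thinning = c(DEL = 0.5, DUP = 0.45, INV = 0.35, BND = 0.15),
    sv_snp_thinning_margin = 5000L,
    sv_length = list(
      DEL = c(log(450), 0.6), DUP = c(log(1500), 0.7),
      INV = c(log(3000), 0.8)
    ),
    depth_mean_range = c(5, 17),
    depth_sd = 2,
    window = 100L,
    artifact_n = 0L, artifact_fold = 4, artifact_length = 3000L,
    sv_min_gap = 2500L,
    callers = c("callerA", "callerB", "callerC"),
    caller_sensitivity = NULL,
    genotype_error = NULL,
    hom_het_miscall = c(DEL = 0, DUP = 0.45, INV = 0.6, BND = 0.65),
    systematic_error = c(DEL = 0, DUP = 0, INV = 0.06, BND = 0.08),
    breakpoint_jitter = c(callerA = 120, callerB = 80, callerC = 200),
    snp_call_error = 0) {
  if (is.null(caller_sensitivity)) {
    caller_sensitivity <- matrix(
      0.97, length(callers), length(SV_TYPES),
      dimnames = list(callers, SV_TYPES)
    )
  }
  if (is.null(genotype_error)) {
    genotype_error <- outer(
      setNames(c(1, 1, 1.5), callers),
      c(DEL = 0.004, DUP = 0.02, INV = 0.04, BND = 0.04)
    )
  }
  cfg <- list(
    seed = as.integer(seed), populations = populations,
    n_samples = n_samples, founders = founders,
    segment_scale = segment_scale, chrom_lengths = chrom_lengths,
    snp_density = snp_density, sv_counts = sv_counts,
    snp_maf_shape = snp_maf_shape, sv_maf_shape = sv_maf_shape,
    sv_resample_prob = sv_resample_prob,
    sv_snp_thinning = sv_snp_thinning,
    sv_snp_thinning_margin = as.integer(sv_snp_thinning_margin),
    sv_length = sv_length, depth_mean_range = depth_mean_range,
    depth_sd = depth_sd, window = as.integer(window),
    artifact_n = as.integer(artifact_n), artifact_fold = artifact_fold,
    artifact_length = as.integer(artifact_length),
    sv_min_gap = as.integer(sv_min_gap),
    callers = callers, caller_sensitivity = caller_sensitivity,
    genotype_error = genotype_error, hom_het_miscall = hom_het_miscall,
    systematic_error = systematic_error,
    breakpoint_jitter = breakpoint_jitter, snp_call_error = snp_call_error
  )
  rates <- c(
    cfg$caller_sensitivity, cfg$genotype_error, cfg$hom_het_miscall,
    cfg$systematic_error, cfg$sv_resample_prob, cfg$sv_snp_thinning,
    cfg$snp_call_error
  )
  stopifnot(all(rates >= 0 & rates <= 1), all(cfg$segment_scale > 0))
  class(cfg) <- "sim_config"
  cfg
}

#' Turn off every stochastic corruption channel of a configuration
#'
#' Returns a copy of `config` with perfect caller sensitivity, zero
#' genotype-error/miscall rates, zero breakpoint jitter, no artifact
#' regions, no SNP-call errors and noise-free depth. On such a
#' configuration the filtering pipeline is the identity.
#'
#' @param config a [sim_config()].
#' @return a [sim_config()].
#' @export
error_free <- function(config) {
  config$caller_sensitivity[] <- 1
  config$genotype_error[] <- 0
  config$hom_het_miscall[] <- 0
  config$systematic_error[] <- 0
  config$breakpoint_jitter[] <- 0
  config$artifact_n <- 0L
  config$snp_call_error <- 0
  config$depth_sd <- 0
  config
}

#' Evaluate code with a fixed, restored RNG state
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

# sample one haplotype's founder mosaic: returns list(ends, founder)
mosaic_one <- function(len, L, K) {
  ends <- numeric(0)
  pos <- 0
  while (pos < len) {
    pos <- pos + rexp(1L, rate = 1 / L)
    ends <- c(ends, min(pos, len))
  }
  list(ends = ends, founder = sample.int(K, length(ends), replace = TRUE))
}

# founder subset (indices) with combined frequency nearest the target:
# polymorphic single founders are considered first, then greedy unions of
# a random founder order for targets above any single frequency
founder_subset <- function(freqs, target) {
  ok <- which(freqs > 0 & freqs < 1)
  if (length(ok) == 0L) ok <- seq_along(freqs)
  best_single <- ok[which.min(abs(freqs[ok] - target))]
  if (target <= max(freqs[ok]) + 1e-9) {
    return(best_single)
  }
  ord <- ok[sample.int(length(ok))]
  cum <- cumsum(freqs[ord])
  kf <- which.min(abs(cum - target))
  sub <- ord[seq_len(kf)]
  if (abs(sum(freqs[sub]) - target) < abs(freqs[best_single] - target)) {
    sub
  } else {
    best_single
  }
}

mosaic_founder_at <- function(mosaic, positions) {
  idx <- findInterval(positions, mosaic$ends, left.open = TRUE) + 1L
  mosaic$founder[idx]
}

#' Simulate the phased SNP backbone panel
#'
#' Builds the founder-mosaic haplotypes for all populations on a shared set
#' of SNP positions (per-population founder alleles, so allele frequencies
#' differ between populations). SNPs monomorphic across all samples are
#' dropped.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (a [haplotype_panel()] of SNPs) and `truth`
#'   (list holding the mosaic ancestries and generator bookkeeping, extended
#'   by the later stages).
#' @export
simulate_panel <- function(config) {
  with_seed(derive_seed(config$seed, "panel"), {
    pops <- config$populations
    samples <- unlist(lapply(pops, function(p) {
      sprintf("%s_%02d", p, seq_len(config$n_samples[[p]]))
    }))
    pop_of <- rep(pops, times = config$n_samples[pops])

    snp_pos <- lapply(config$chrom_lengths, function(len) {
      m <- round(len * config$snp_density)
      if (m == 0L) {
        return(integer(0))
      }
      sort(sample.int(len, m))  - 1L
    })
    mosaics <- list()
    allele_blocks <- list()
    for (ch in names(config$chrom_lengths)) {
      pos <- snp_pos[[ch]]
      m <- length(pos)
      cols <- vector("list", length(pops))
      names(cols) <- pops
      mosaics[[ch]] <- list()
      for (p in pops) {
        K <- config$founders[[p]]
        L <- config$segment_scale[[p]]
        n_hap <- 2L * config$n_samples[[p]]
        pf <- rbeta(m, config$snp_maf_shape[1L], config$snp_maf_shape[2L])
        founder_alleles <- matrix(
          rbinom(m * K, 1L, rep(pf, each = K)),
          nrow = K
        )
        haps <- matrix(0L, nrow = n_hap, ncol = m)
        mos <- vector("list", n_hap)
        for (h in seq_len(n_hap)) {
          mos[[h]] <- mosaic_one(config$chrom_lengths[[ch]], L, K)
          if (m > 0L) {
            f <- mosaic_founder_at(mos[[h]], pos)
            haps[h, ] <- founder_alleles[cbind(f, seq_len(m))]
          }
        }
        mosaics[[ch]][[p]] <- mos
        cols[[p]] <- haps
      }
      allele_blocks[[ch]] <- do.call(rbind, cols[pops])
    }
    alleles <- do.call(cbind, allele_blocks[names(config$chrom_lengths)])
    ids <- unlist(lapply(names(snp_pos), function(ch) {
      if (length(snp_pos[[ch]]) == 0L) {
        return(character(0))
      }
      sprintf("snp_%s_%d", ch, snp_pos[[ch]] + 1L)
    }))
    chrom <- rep(names(snp_pos), times = lengths(snp_pos))
    start <- unlist(snp_pos, use.names = FALSE)
    if (length(ids) > 0L) {
      poly <- colSums(alleles) > 0L & colSums(alleles) < nrow(alleles)
    } else {
      poly <- logical(0)
    }
    variants <- variant_table(
      id = ids[poly], chrom = chrom[poly],
      start = start[poly], end = start[poly] + 1L,
      vtype = rep("SNP", sum(poly))
    )
    alleles <- alleles[, poly, drop = FALSE]
    colnames(alleles) <- ids[poly]
    alleles <- alleles[, variants$id, drop = FALSE]
    panel <- haplotype_panel(alleles, samples, variants, pop_of)
    truth <- list(
      config = config, mosaics = mosaics, samples = samples,
      populations = pop_of
    )
    list(panel = panel, truth = truth)
  })
}

#' Plant structural variants on the SNP backbone
#'
#' Each SV is assigned to one founder-segment background at its locus: the
#' haplotypes whose mosaic ancestry at the SV position matches a chosen
#' founder carry the SV allele, so before resampling the SV is in complete
#' LD with its local backbone. With `resample = TRUE` (default) carriers are
#' then added/removed at random to hit a per-population target MAF drawn
#' from the type's MAF spectrum, creating controlled local MAF differences.
#'
#' @param sim output of [simulate_panel()].
#' @param config a [sim_config()].
#' @param resample if `FALSE` ("inherit background" mode) carriers stay
#'   exactly the founder-background haplotypes.
#' @return list with `panel` (SNPs + SVs, a [haplotype_panel()]) and `truth`
#'   extended with `sv` (variant table, true haplotype alleles, true dosages,
#'   background indicators and target MAFs).
#' @export
plant_svs <- function(sim, config, resample = TRUE) {
  with_seed(derive_seed(config$seed, "sv"), {
    panel <- sim$panel
    truth <- sim$truth
    pops <- config$populations
    n_hap_pop <- 2L * config$n_samples[pops]
    total <- sum(config$sv_counts)
    if (total == 0L) {
      truth$sv <- NULL
      return(list(panel = panel, truth = truth))
    }
    chroms <- names(config$chrom_lengths)
    vtype <- rep(names(config$sv_counts), times = config$sv_counts)
    chrom <- sample(chroms, total,
      replace = TRUE,
      prob = as.numeric(config$chrom_lengths) / sum(config$chrom_lengths)
    )
    len <- integer(total)
    for (i in seq_len(total)) {
      len[i] <- if (vtype[i] == "BND") {
        1L
      } else {
        pl <- config$sv_length[[vtype[i]]]
        max(150L, round(exp(rnorm(1L, pl[1L], pl[2L]))))
      }
    }
    start <- integer(total)
    occupied <- lapply(chroms, function(x) {
      data.frame(start = integer(0), end = integer(0))
    })
    names(occupied) <- chroms
    gap <- config$sv_min_gap
    for (i in seq_len(total)) {
      maxs <- config$chrom_lengths[[chrom[i]]] - len[i] - 1L
      occ <- occupied[[chrom[i]]]
      for (try in 1:50) {
        cand <- sample.int(max(1L, maxs), 1L)
        if (!any(cand - gap < occ$end & occ$start < cand + len[i] + gap)) {
          break
        }
      }
      start[i] <- cand
      occupied[[chrom[i]]] <- rbind(
        occ, data.frame(start = cand, end = cand + len[i])
      )
    }
    id <- sprintf("%s_%s_%d", tolower(vtype), chrom, start)
    keep <- !duplicated(id)
    id <- id[keep]
    vtype <- vtype[keep]
    chrom <- chrom[keep]
    start <- start[keep]
    len <- len[keep]
    total <- sum(keep)

    sv_alleles <- matrix(0L, nrow = nrow(panel$alleles), ncol = total)
    background <- matrix(0L, nrow = nrow(panel$alleles), ncol = total)
    target_maf <- matrix(NA_real_, nrow = total, ncol = length(pops),
      dimnames = list(id, pops)
    )
    hap_pop <- rep(panel$populations, each = 2L)
    do_resample <- resample &
      runif(total) < config$sv_resample_prob[vtype]
    for (i in seq_len(total)) {
      for (p in pops) {
        rows <- which(hap_pop == p)
        n_hap <- length(rows)
        mos <- truth$mosaics[[chrom[i]]][[p]]
        anc <- vapply(
          mos, function(m) mosaic_founder_at(m, start[i]), integer(1)
        )
        freqs <- tabulate(anc, nbins = config$founders[[p]]) / n_hap
        shp <- config$sv_maf_shape[[vtype[i]]]
        tm <- rbeta(1L, shp[1L], shp[2L])
        tm <- min(max(tm, 1 / n_hap), 0.5)
        # background = founder subset whose combined frequency is nearest
        # the target draw: the SV sits on a real haplotype background and
        # is in complete LD with the local backbone before resampling
        bg <- founder_subset(freqs, tm)
        if (!do_resample[i]) {
          tm <- sum(freqs[bg])
        } else if (vtype[i] == "DEL") {
          # deletions: resampling is a relative carrier drop from the
          # background frequency (slight rare-shift, mild LD loss)
          tm <- max(1 / n_hap, sum(freqs[bg]) * (1 - rbeta(1L, 1, 5)))
        }
        target_maf[i, p] <- tm
        carriers <- anc %in% bg
        background[rows, i] <- as.integer(carriers)
        if (do_resample[i]) {
          k <- max(1L, round(tm * n_hap))
          cur <- which(carriers)
          if (length(cur) > k) {
            drop <- sample(cur, length(cur) - k)
            carriers[drop] <- FALSE
          } else if (length(cur) < k) {
            add <- sample(which(!carriers), k - length(cur))
            carriers[add] <- TRUE
          }
        }
        sv_alleles[rows, i] <- as.integer(carriers)
      }
    }
    colnames(sv_alleles) <- id
    colnames(background) <- id
    sv_variants <- variant_table(
      id = id, chrom = chrom, start = start, end = start + pmax(len, 1L),
      vtype = vtype
    )
    # thin backbone SNPs near planted SV spans (reduced local SNP density)
    snp_v <- panel$variants
    keep_snp <- rep(TRUE, nrow(snp_v))
    marg <- config$sv_snp_thinning_margin
    for (i in seq_len(total)) {
      thin <- config$sv_snp_thinning[[vtype[i]]]
      if (is.null(thin) || thin <= 0) next
      near <- which(
        snp_v$chrom == chrom[i] &
          snp_v$start >= start[i] - marg &
          snp_v$start < start[i] + max(len[i], 1L) + marg
      )
      if (length(near)) {
        keep_snp[near] <- keep_snp[near] & runif(length(near)) >= thin
      }
    }
    snp_v <- snp_v[keep_snp, , drop = FALSE]
    all_variants <- variant_table(
      id = c(snp_v$id, sv_variants$id),
      chrom = c(snp_v$chrom, sv_variants$chrom),
      start = c(snp_v$start, sv_variants$start),
      end = c(snp_v$end, sv_variants$end),
      vtype = c(snp_v$vtype, sv_variants$vtype)
    )
    comb <- cbind(
      panel$alleles[, snp_v$id, drop = FALSE], sv_alleles
    )[, all_variants$id, drop = FALSE]
    aug <- haplotype_panel(
      comb, panel$samples, all_variants, panel$populations
    )
    truth$sv <- list(
      variants = sv_variants,
      hap_alleles = sv_alleles[, sv_variants$id, drop = FALSE],
      dosages = {
        a <- sv_alleles[, sv_variants$id, drop = FALSE]
        d <- t(a[seq(1L, nrow(a), 2L), , drop = FALSE] +
          a[seq(2L, nrow(a), 2L), , drop = FALSE])
        colnames(d) <- panel$samples
        storage.mode(d) <- "integer"
        d
      },
      background = background[, sv_variants$id, drop = FALSE],
      target_maf = target_maf[sv_variants$id, , drop = FALSE]
    )
    list(panel = aug, truth = truth)
  })
}

#' Simulate windowed depth profiles from the SV truth
#'
#' Per-window coverage is Normal(mean_s * f, SD) truncated at zero, where
#' the dosage factor f is 1/0.5/0 inside DEL spans and 1/1.5/2 inside DUP
#' spans for dosage 0/1/2, and planted artifact regions multiply coverage by
#' the artifact fold in every sample.
#'
#' @param truth truth list from [plant_svs()].
#' @param config a [sim_config()].
#' @return list with `depth` (a [depth_profile()]) and `truth` extended with
#'   `depth_mean` (per-sample means) and `artifacts` (planted regions).
#' @export
simulate_depth <- function(truth, config) {
  with_seed(derive_seed(config$seed, "depth"), {
    samples <- truth$samples
    n <- length(samples)
    w <- config$window
    mean_s <- runif(n, config$depth_mean_range[1L], config$depth_mean_range[2L])
    names(mean_s) <- samples
    artifacts <- NULL
    if (config$artifact_n > 0L) {
      ch <- sample(names(config$chrom_lengths), config$artifact_n,
        replace = TRUE
      )
      st <- vapply(ch, function(c2) {
        as.integer(sample.int(
          max(1L, config$chrom_lengths[[c2]] - config$artifact_length), 1L
        ))
      }, integer(1))
      st <- (st %/% w) * w
      artifacts <- data.frame(
        chrom = ch, start = st, end = st + config$artifact_length
      )
    }
    depth <- list()
    for (ch in names(config$chrom_lengths)) {
      nwin <- ceiling(config$chrom_lengths[[ch]] / w)
      fac <- matrix(1, nrow = nwin, ncol = n)
      if (!is.null(truth$sv)) {
        sv <- truth$sv$variants
        cn <- sv[sv$chrom == ch & sv$vtype %in% c("DEL", "DUP"), ,
          drop = FALSE
        ]
        for (i in seq_len(nrow(cn))) {
          wi <- windows_inside(cn$start[i], cn$end[i], w, nwin)
          if (length(wi) == 0L) next
          dos <- truth$sv$dosages[cn$id[i], ]
          f <- if (cn$vtype[i] == "DEL") {
            c(1, 0.5, 0)[dos + 1L]
          } else {
            c(1, 1.5, 2)[dos + 1L]
          }
          fac[wi, ] <- sweep(
            fac[wi, , drop = FALSE], 2L, f, `*`
          )
        }
      }
      m <- matrix(
        rnorm(nwin * n,
          mean = rep(mean_s, each = nwin) * as.numeric(fac),
          sd = config$depth_sd
        ),
        nrow = nwin
      )
      m <- pmax(m, 0)
      if (!is.null(artifacts)) {
        aa <- artifacts[artifacts$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(aa))) {
          wi <- windows_inside(aa$start[i], aa$end[i], w, nwin)
          m[wi, ] <- m[wi, ] * config$artifact_fold
        }
      }
      colnames(m) <- samples
      depth[[ch]] <- m
    }
    truth$depth_mean <- mean_s
    truth$artifacts <- artifacts
    list(depth = depth_profile(depth, window = w), truth = truth)
  })
}

# indices of depth windows fully inside [start, end)
windows_inside <- function(start, end, window, nwin) {
  first <- ceiling(start / window) + 1L
  last <- floor(end / window)
  if (last < first) {
    # fall back to windows overlapping the span (short variants)
    first <- start %/% window + 1L
    last <- min(nwin, (end - 1L) %/% window + 1L)
  }
  seq.int(max(1L, first), min(nwin, last))
}

#' Simulate three error-prone caller callsets from the SV truth
#'
#' Each caller detects each SV with a per-type sensitivity, jitters the
#' breakpoints with caller-specific Normal noise, and corrupts genotypes at
#' per-caller/per-type rates. Homozygous DUP/INV/BND genotypes additionally
#' pass through a systematic hom->het miscall channel shared by all callers
#' (one draw per SV x sample), emulating a genotyper deficit that consensus
#' voting cannot repair. All intended corruptions are recorded in the truth.
#'
#' @param truth truth list from [plant_svs()].
#' @param config a [sim_config()].
#' @return list with `callsets` (list of [sv_callset()], one per caller)
#'   and `truth` extended with `miscalls` and `caller_errors` bookkeeping.
#' @export
simulate_callsets <- function(truth, config) {
  with_seed(derive_seed(config$seed, "callers"), {
    sv <- truth$sv
    stopifnot(!is.null(sv))
    nv <- nrow(sv$variants)
    samples <- truth$samples
    n <- length(samples)

    # systematic hom->het channel, shared across callers
    cons_geno <- sv$dosages
    mis <- matrix(FALSE, nv, n, dimnames = dimnames(cons_geno))
    for (t in names(config$hom_het_miscall)) {
      rate <- config$hom_het_miscall[[t]]
      if (rate <= 0) next
      rows <- which(sv$variants$vtype == t)
      hom <- which(cons_geno[rows, , drop = FALSE] == 2L)
      if (length(hom) == 0L) next
      hit <- hom[runif(length(hom)) < rate]
      m <- matrix(FALSE, length(rows), n)
      m[hit] <- TRUE
      mis[rows, ] <- m
    }
    cons_geno[mis] <- 1L
    truth$miscalls <- mis

    # systematic random genotype failures shared by all callers
    sys_err <- matrix(FALSE, nv, n, dimnames = dimnames(cons_geno))
    for (t in names(config$systematic_error)) {
      rate <- config$systematic_error[[t]]
      if (rate <= 0) next
      rows <- which(sv$variants$vtype == t)
      if (length(rows) == 0L) next
      sub <- cons_geno[rows, , drop = FALSE]
      hit <- which(matrix(runif(length(sub)) < rate, nrow(sub)))
      if (length(hit) == 0L) next
      sub[hit] <- (sub[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
      cons_geno[rows, ] <- sub
      m <- matrix(FALSE, length(rows), n)
      m[hit] <- TRUE
      sys_err[rows, ] <- m
    }
    truth$systematic_errors <- sys_err

    callsets <- list()
    errors <- list()
    for (cal in config$callers) {
      sens <- config$caller_sensitivity[cal, sv$variants$vtype]
      det <- runif(nv) < sens
      v <- sv$variants[det, , drop = FALSE]
      jit <- config$breakpoint_jitter[[cal]]
      ds <- if (jit > 0) round(rnorm(nrow(v), 0, jit)) else 0L
      de <- if (jit > 0) round(rnorm(nrow(v), 0, jit)) else 0L
      point <- v$vtype %in% c("SNP", "BND")
      ns <- pmax(0L, as.integer(v$start + ds))
      ne <- as.integer(ifelse(point, ns + 1L, pmax(v$end + de, ns + 50L)))
      ci <- as.integer(max(10L, round(2 * jit)))
      cv <- variant_table(
        id = v$id, chrom = v$chrom, start = ns, end = ne, vtype = v$vtype,
        ci_start = ci, ci_end = ci
      )
      g <- cons_geno[v$id, , drop = FALSE]
      err_rate <- config$genotype_error[cal, v$vtype]
      hit <- matrix(runif(length(g)) < err_rate, nrow(g), ncol(g))
      if (any(hit)) {
        idx <- which(hit)
        g[idx] <- (g[idx] + sample(1:2, length(idx), replace = TRUE)) %% 3L
      }
      storage.mode(g) <- "integer"
      errors[[cal]] <- sum(g != cons_geno[v$id, , drop = FALSE])
      colnames(g) <- samples
      callsets[[cal]] <- sv_callset(cv, g[cv$id, , drop = FALSE], caller = cal)
    }
    truth$caller_errors <- unlist(errors)
    truth$miscall_geno <- cons_geno
    list(callsets = callsets, truth = truth)
  })
}

#' Emit SNP genotype calls with deletion-consistency adjustments
#'
#' The SNP calls used by the deletion SNP-support filter: derived from the
#' phased SNP backbone, then adjusted inside true DEL spans (missing for
#' hom-DEL samples, homozygous from the intact haplotype for het-DEL
#' samples) and optionally corrupted at `snp_call_error`.
#'
#' @param panel SNP [haplotype_panel()] (backbone only).
#' @param truth truth list from [plant_svs()].
#' @param config a [sim_config()].
#' @return integer dosage matrix (SNPs x samples) with `NA` for missing.
#' @export
simulate_snp_calls <- function(panel, truth, config) {
  with_seed(derive_seed(config$seed, "misc"), {
    snps <- panel$variants[panel$variants$vtype == "SNP", , drop = FALSE]
    calls <- panel_dosages(panel)[snps$id, , drop = FALSE]
    if (!is.null(truth$sv)) {
      dels <- truth$sv$variants[truth$sv$variants$vtype == "DEL", ,
        drop = FALSE
      ]
      hapA <- panel$alleles[seq(1L, nrow(panel$alleles), 2L), , drop = FALSE]
      hapB <- panel$alleles[seq(2L, nrow(panel$alleles), 2L), , drop = FALSE]
      delA <- truth$sv$hap_alleles[seq(1L, nrow(truth$sv$hap_alleles), 2L), ,
        drop = FALSE
      ]
      delB <- truth$sv$hap_alleles[seq(2L, nrow(truth$sv$hap_alleles), 2L), ,
        drop = FALSE
      ]
      for (i in seq_len(nrow(dels))) {
        on_del <- snps$chrom == dels$chrom[i] &
          snps$start >= dels$start[i] & snps$start < dels$end[i]
        if (!any(on_del)) next
        dos <- truth$sv$dosages[dels$id[i], ]
        sid <- snps$id[on_del]
        hom <- which(dos == 2L)
        if (length(hom)) calls[sid, hom] <- NA_integer_
        het <- which(dos == 1L)
        for (s in het) {
          intact <- if (delA[s, dels$id[i]] == 0L) hapA else hapB
          calls[sid, s] <- 2L * intact[s, sid]
        }
      }
    }
    if (config$snp_call_error > 0) {
      hit <- which(runif(length(calls)) < config$snp_call_error)
      calls[hit] <- sample(0:2, length(hit), replace = TRUE)
    }
    calls
  })
}

#' Run the full generator: panel, SVs, depth, callsets, SNP calls
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study` with elements `panel` (truth panel,
#'   SNPs + SVs), `snp_panel` (backbone only), `truth`, `depth`, `callsets`,
#'   `snp_calls`, `genome`.
#' @export
simulate_study <- function(config) {
  base <- simulate_panel(config)
  planted <- plant_svs(base, config)
  snp_panel <- panel_subset_variants(
    planted$panel,
    planted$panel$variants$id[planted$panel$variants$vtype == "SNP"]
  )
  dep <- simulate_depth(planted$truth, config)
  cs <- simulate_callsets(dep$truth, config)
  snp_calls <- simulate_snp_calls(snp_panel, cs$truth, config)
  genome <- genome_table(
    names(config$chrom_lengths), as.numeric(config$chrom_lengths)
  )
  structure(
    list(
      panel = planted$panel, snp_panel = snp_panel, truth = cs$truth,
      depth = dep$depth, callsets = cs$callsets, snp_calls = snp_calls,
      genome = genome, config = config
    ),
    class = "sim_study"
  )
}
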