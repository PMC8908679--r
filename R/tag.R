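# Tag-SNP analysis: maximal r2 to a pool of candidate tag SNPs as a
# function of distance (r2_tag), tagged shares at a threshold, local SNP
# density, and array-restricted pools.

#' Candidate tag-SNP pool for one population
#'
#' Variable (polymorphic within the population) SNPs, optionally restricted
#' to positions present on an array manifest.
#'
#' @param panel a [haplotype_panel()].
#' @param population population label.
#' @param manifest optional data.frame `chrom`,`pos` (0-based) from
#'   [read_array_manifest()].
#' @return character vector of SNP ids.
#' @export
tag_pool <- function(panel, population, manifest = NULL) {
  sub <- panel_subset(panel, population)
  p <- colMeans(sub$alleles)
  v <- sub$variants
  ids <- v$id[v$vtype == "SNP" & p > 0 & p < 1]
  if (!is.null(manifest)) ids <- array_pool(ids, panel, manifest)
  ids
}

#' Restrict a pool to array manifest positions
#'
#' @param pool character vector of SNP ids.
#' @param panel a [haplotype_panel()] carrying the variant coordinates.
#' @param manifest data.frame `chrom`, `pos` (0-based).
#' @return the subset of `pool` matching the manifest by exact
#'   (chrom, position).
#' @export
array_pool <- function(pool, panel, manifest) {
  v <- panel$variants
  v <- v[match(pool, v$id), , drop = FALSE]
  keep <- paste(v$chrom, v$start) %in% paste(manifest$chrom, manifest$pos)
  pool[keep]
}

#' Tag curve (running maximal r2 by distance) for one variant
#'
#' Pool SNPs on the same chromosome within `max(grid)` of the variant's
#' nearest breakpoint (SNPs located on the variant are excluded) are sorted
#' by distance; `r2_tag` at each grid distance is the maximum r2 among pool
#' SNPs at most that far away. Ties on r2 resolve to the smaller distance,
#' then the smaller coordinate.
#'
#' @param panel a [haplotype_panel()].
#' @param population population label.
#' @param id focal variant id (must be polymorphic in the population).
#' @param pool character vector of pool SNP ids (see [tag_pool()]).
#' @param grid increasing distances in bp (default 1-100 kb in 1 kb steps).
#' @return data.frame of class `tag_result`: `distance`, `r2_tag`,
#'   `best_id`, `n_pool`; `r2_tag` is NA before the first pool SNP.
#' @export
tag_curve <- function(panel, population, id, pool,
                      grid = seq(1000L, 100000L, by = 1000L)) {
  sub <- panel_subset(panel, population)
  v <- sub$variants
  i <- match(id, v$id)
  stopifnot(!is.na(i))
  pool <- setdiff(pool, id)
  pj <- match(pool, v$id)
  pj <- pj[!is.na(pj) & v$chrom[pj] == v$chrom[i]]
  point <- v$vtype[i] %in% c("SNP", "BND")
  spos <- v$start[pj]
  dist <- if (point) {
    abs(spos - v$start[i])
  } else {
    pmin(abs(spos - v$start[i]), abs(spos - v$end[i]))
  }
  on_sv <- !point & spos >= v$start[i] & spos < v$end[i]
  keep <- !on_sv & dist > 0L & dist <= max(grid)
  pj <- pj[keep]
  dist <- dist[keep]
  res <- data.frame(
    distance = grid, r2_tag = NA_real_, best_id = NA_character_,
    n_pool = findInterval(grid, sort(dist))
  )
  if (length(pj)) {
    a <- sub$alleles[, i]
    p_a <- mean(a)
    p_b <- colMeans(sub$alleles[, pj, drop = FALSE])
    p_ab <- as.numeric(
      crossprod(a, sub$alleles[, pj, drop = FALSE])
    ) / nrow(sub$alleles)
    r2 <- (p_ab - p_a * p_b)^2 / (p_a * p_b * (1 - p_a) * (1 - p_b))
    o <- order(dist, v$start[pj])
    r2 <- r2[o]
    dsort <- dist[o]
    ids <- v$id[pj][o]
    best <- cummax(r2)
    # index of the first pool SNP attaining the running maximum
    best_at <- vapply(
      seq_along(r2), function(k) which(r2[seq_len(k)] >= best[k])[1L],
      integer(1)
    )
    last <- findInterval(grid, dsort)
    has <- last >= 1L
    res$r2_tag[has] <- best[last[has]]
    res$best_id[has] <- ids[best_at[last[has]]]
  }
  attr(res, "id") <- id
  attr(res, "vtype") <- v$vtype[i]
  class(res) <- c("tag_result", "data.frame")
  res
}

#' Tag curves for many variants as a matrix
#'
#' @inheritParams tag_curve
#' @param ids focal variant ids.
#' @return numeric matrix (variants x grid points) of `r2_tag`, NA where no
#'   pool SNP is within the distance.
#' @export
tag_curve_matrix <- function(panel, population, ids, pool,
                             grid = seq(1000L, 100000L, by = 1000L)) {
  out <- matrix(NA_real_, length(ids), length(grid),
    dimnames = list(ids, grid)
  )
  for (k in seq_along(ids)) {
    out[k, ] <- tag_curve(panel, population, ids[k], pool, grid)$r2_tag
  }
  out
}

#' Mean tag curves with Bonferroni bootstrap confidence intervals
#'
#' The mean at each grid distance is over the variants with a defined
#' `r2_tag` there; the CI resamples variants with replacement at level
#' `0.05 / length(grid)`.
#'
#' @param curves matrix from [tag_curve_matrix()].
#' @param n_boot bootstrap resamples (0 disables the CI).
#' @param seed RNG seed.
#' @return data.frame: `distance`, `n`, `mean_r2_tag`, `lo`, `hi`.
#' @export
mean_tag_curves <- function(curves, n_boot = 0L, seed = 1L) {
  grid <- as.integer(colnames(curves))
  n <- colSums(!is.na(curves))
  mean_tag <- suppressWarnings(colMeans(curves, na.rm = TRUE))
  mean_tag[n == 0L] <- NA_real_
  lo <- hi <- rep(NA_real_, length(grid))
  if (n_boot > 0L && nrow(curves) >= 2L) {
    alpha <- 0.05 / length(grid)
    with_seed(derive_seed(seed, "tag"), {
      bm <- matrix(NA_real_, n_boot, length(grid))
      for (b in seq_len(n_boot)) {
        rows <- sample.int(nrow(curves), replace = TRUE)
        bm[b, ] <- suppressWarnings(
          colMeans(curves[rows, , drop = FALSE], na.rm = TRUE)
        )
      }
      lo <- apply(bm, 2L, quantile, probs = alpha / 2, na.rm = TRUE)
      hi <- apply(bm, 2L, quantile, probs = 1 - alpha / 2, na.rm = TRUE)
    })
  }
  data.frame(
    distance = grid, n = n, mean_r2_tag = mean_tag, lo = lo, hi = hi
  )
}

#' Share of variants tagged above a threshold
#'
#' A variant counts as tagged when its `r2_tag` at `distance` strictly
#' exceeds `threshold`; variants with no pool SNP within the distance count
#' as untagged.
#'
#' @param curves matrix from [tag_curve_matrix()].
#' @param distance grid distance (bp) at which to evaluate.
#' @param threshold tagging threshold (default 0.75, strict `>`).
#' @return fraction in `[0, 1]`.
#' @export
share_tagged <- function(curves, distance, threshold = 0.75) {
  col <- match(as.character(distance), colnames(curves))
  stopifnot(!is.na(col))
  vals <- curves[, col]
  mean(!is.na(vals) & vals > threshold)
}

#' Number of variable pool SNPs near each variant
#'
#' Counts pool SNPs within `distance` bp of the variant's breakpoints
#' (optionally only those with r2 at least `r2_floor`) and summarizes
#' per-class medians.
#'
#' @inheritParams tag_curve
#' @param ids focal variant ids.
#' @param distance window in bp (default 5 kb).
#' @param r2_floor optional minimum r2 for a SNP to count.
#' @return list: `counts` (data.frame `id`, `class`, `count`) and `medians`
#'   (data.frame `class`, `median`).
#' @export
snp_density <- function(panel, population, ids, pool, distance = 5000L,
                        r2_floor = NULL) {
  sub <- panel_subset(panel, population)
  v <- sub$variants
  counts <- integer(length(ids))
  classes <- character(length(ids))
  for (k in seq_along(ids)) {
    tc <- tag_curve(panel, population, ids[k], pool, grid = distance)
    classes[k] <- attr(tc, "vtype")
    if (is.null(r2_floor)) {
      counts[k] <- tc$n_pool[1L]
    } else {
      i <- match(ids[k], v$id)
      pj <- match(setdiff(pool, ids[k]), v$id)
      pj <- pj[!is.na(pj) & v$chrom[pj] == v$chrom[i]]
      point <- v$vtype[i] %in% c("SNP", "BND")
      spos <- v$start[pj]
      dist <- if (point) {
        abs(spos - v$start[i])
      } else {
        pmin(abs(spos - v$start[i]), abs(spos - v$end[i]))
      }
      on_sv <- !point & spos >= v$start[i] & spos < v$end[i]
      pj <- pj[!on_sv & dist > 0L & dist <= distance]
      if (length(pj)) {
        a <- sub$alleles[, i]
        p_a <- mean(a)
        p_b <- colMeans(sub$alleles[, pj, drop = FALSE])
        p_ab <- as.numeric(
          crossprod(a, sub$alleles[, pj, drop = FALSE])
        ) / nrow(sub$alleles)
        r2 <- (p_ab - p_a * p_b)^2 / (p_a * p_b * (1 - p_a) * (1 - p_b))
        counts[k] <- sum(r2 >= r2_floor)
      }
    }
  }
  med <- vapply(
    split(counts, classes), median, numeric(1)
  )
  list(
    counts = data.frame(id = ids, class = classes, count = counts),
    medians = data.frame(class = names(med), median = unname(med))
  )
}

#' Pairwise Bonferroni-corrected rank-sum comparison of density counts
#'
#' All pairwise two-sided Wilcoxon rank-sum tests between classes, p-values
#' multiplied by the number of pairs (capped at 1), plus a greedy compact
#' letter display: classes ordered by median; classes that do not differ
#' significantly share a letter.
#'
#' @param counts numeric vector of per-variant counts.
#' @param classes class label per count.
#' @param alpha significance level (default 0.05).
#' @return list: `p` (corrected p-value matrix), `letters` (named character
#'   vector of letter groups).
#' @export
compare_density <- function(counts, classes, alpha = 0.05) {
  cls <- names(sort(vapply(
    split(counts, classes), median, numeric(1)
  ), decreasing = TRUE))
  k <- length(cls)
  p <- matrix(NA_real_, k, k, dimnames = list(cls, cls))
  if (k < 2L) {
    return(list(p = p, letters = setNames(rep("a", k), cls)))
  }
  n_pairs <- k * (k - 1L) / 2L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pv <- suppressWarnings(wilcox.test(
        counts[classes == cls[i]], counts[classes == cls[j]]
      )$p.value)
      if (is.na(pv)) pv <- 1 # fully tied samples
      p[i, j] <- p[j, i] <- min(1, pv * n_pairs)
    }
  }
  # greedy insert-and-absorb letter assignment
  groups <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(p[cls[groups[[g]]], cls[i]] >= alpha, na.rm = TRUE)) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  letters_out <- setNames(rep("", k), cls)
  for (g in seq_along(groups)) {
    for (i in groups[[g]]) {
      letters_out[i] <- paste0(letters_out[i], letters[g])
    }
  }
  list(p = p, letters = letters_out)
}
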