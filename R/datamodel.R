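# Core domain containers.
#
# All coordinates are 0-based, half-open internally. VCF I/O converts to and
# from the 1-based inclusive convention at the file boundary only.

#' Construct a variant table
#'
#' The central tabular container: one row per variant (SNP or SV) with its
#' span, breakpoint confidence intervals and type. Genotypes live in a
#' separate matrix aligned by variant id (see [sv_callset()]).
#'
#' @param id character variant ids (unique).
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open span. SNPs and BNDs have
#'   `end = start + 1` (a BND is a single breakpoint without a length).
#' @param vtype character, one of `"SNP"`, `"DEL"`, `"DUP"`, `"INV"`, `"BND"`.
#' @param ci_start,ci_end non-negative symmetric breakpoint confidence
#'   interval half-widths in bp (`+- ci`).
#' @param ref,alt REF/ALT strings for VCF round-trips; symbolic ALTs
#'   (`"<DEL>"` etc.) are generated automatically for SVs when omitted.
#' @return data.frame of class `variant_table`, sorted by (chrom, start).
#' @export
variant_table <- function(id, chrom, start, end, vtype,
                          ci_start = 0L, ci_end = 0L,
                          ref = NULL, alt = NULL) {
  n <- length(id)
  chrom <- rep_len(as.character(chrom), n)
  vtype <- rep_len(vtype, n)
  stopifnot(
    !anyDuplicated(id),
    length(start) == n, length(end) == n,
    all(vtype %in% VARIANT_TYPES)
  )
  start <- as.integer(start)
  end <- as.integer(end)
  point <- vtype %in% c("SNP", "BND")
  if (any(end[point] != start[point] + 1L)) {
    stop("SNP and BND records must have end = start + 1")
  }
  if (any(end[!point] <= start[!point])) {
    stop("DEL/DUP/INV records must have end > start")
  }
  if (is.null(ref)) ref <- ifelse(vtype == "SNP", "A", "N")
  if (is.null(alt)) {
    alt <- ifelse(vtype == "SNP", "C", paste0("<", vtype, ">"))
  }
  df <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = start, end = end, vtype = vtype,
    ci_start = as.integer(rep_len(ci_start, n)),
    ci_end = as.integer(rep_len(ci_end, n)),
    ref = ref, alt = alt,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start, df$end, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Construct a callset (variants plus a dosage matrix)
#'
#' @param variants a [variant_table()].
#' @param genotypes integer matrix of allele dosages in `{0, 1, 2, NA}` with
#'   one row per variant (rownames = variant ids) and one column per sample.
#' @param caller optional caller label for single-caller callsets.
#' @return list of class `sv_callset` with elements `variants`, `geno`,
#'   `samples`, `caller`.
#' @export
sv_callset <- function(variants, genotypes, caller = NULL) {
  stopifnot(inherits(variants, "variant_table"), is.matrix(genotypes))
  if (is.null(rownames(genotypes))) {
    stopifnot(nrow(genotypes) == nrow(variants))
    rownames(genotypes) <- variants$id
  }
  genotypes <- genotypes[variants$id, , drop = FALSE]
  ok <- genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or NA")
  structure(
    list(
      variants = variants,
      geno = genotypes,
      samples = colnames(genotypes),
      caller = caller
    ),
    class = "sv_callset"
  )
}

#' Construct a phased haplotype panel
#'
#' A complete (no missing alleles) phased 0/1 allele matrix: two haplotype
#' rows per sample, one column per variant, aligned to a variant table.
#'
#' @param alleles integer matrix in `{0,1}`, `2N x M`; rows ordered as
#'   sample1-hapA, sample1-hapB, sample2-hapA, ...
#' @param samples character vector of N sample ids.
#' @param variants a [variant_table()] with M rows, in column order.
#' @param populations character vector of per-sample population labels.
#' @return list of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, samples, variants, populations) {
  stopifnot(
    is.matrix(alleles),
    nrow(alleles) == 2L * length(samples),
    ncol(alleles) == nrow(variants),
    length(populations) == length(samples),
    !anyNA(alleles), all(alleles %in% c(0L, 1L))
  )
  colnames(alleles) <- variants$id
  rownames(alleles) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  structure(
    list(
      alleles = alleles, samples = samples,
      variants = variants, populations = populations
    ),
    class = "haplotype_panel"
  )
}

#' Restrict a haplotype panel to one population
#' @param panel a [haplotype_panel()].
#' @param population population label to keep.
#' @return a [haplotype_panel()] with only that population's samples.
#' @export
panel_subset <- function(panel, population) {
  keep <- panel$populations == population
  rows <- rep(keep, each = 2L)
  haplotype_panel(
    panel$alleles[rows, , drop = FALSE],
    panel$samples[keep], panel$variants, panel$populations[keep]
  )
}

#' Restrict a haplotype panel to a subset of variants
#' @param panel a [haplotype_panel()].
#' @param ids variant ids to keep (panel order preserved).
#' @return a [haplotype_panel()].
#' @export
panel_subset_variants <- function(panel, ids) {
  keep <- panel$variants$id %in% ids
  v <- panel$variants[keep, , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("variant_table", "data.frame")
  haplotype_panel(
    panel$alleles[, v$id, drop = FALSE], panel$samples, v,
    panel$populations
  )
}

#' Dosage matrix of a haplotype panel
#' @param panel a [haplotype_panel()].
#' @return integer matrix, variants x samples.
#' @export
panel_dosages <- function(panel) {
  a <- panel$alleles
  d <- a[seq(1L, nrow(a), by = 2L), , drop = FALSE] +
    a[seq(2L, nrow(a), by = 2L), , drop = FALSE]
  d <- t(d)
  colnames(d) <- panel$samples
  storage.mode(d) <- "integer"
  d
}

#' Construct a windowed depth profile
#'
#' Per-sample mean read depth in fixed-width windows tiling each chromosome,
#' the shape produced by windowed depth extractors such as mosdepth.
#'
#' @param depth named list: chromosome -> numeric matrix (windows x samples),
#'   window w covering `[(w-1)*window, w*window)`.
#' @param window window width in bp (default 100).
#' @return list of class `depth_profile`.
#' @export
depth_profile <- function(depth, window = 100L) {
  stopifnot(is.list(depth), length(depth) > 0L)
  samples <- colnames(depth[[1L]])
  for (m in depth) {
    stopifnot(is.matrix(m), identical(colnames(m), samples), all(m >= 0))
  }
  structure(
    list(depth = depth, window = as.integer(window), samples = samples),
    class = "depth_profile"
  )
}

#' Construct a genome table
#' @param chrom chromosome names (unique).
#' @param length chromosome lengths in bp (> 0).
#' @param autosome logical autosome flags (default all TRUE).
#' @return data.frame of class `genome_table`.
#' @export
genome_table <- function(chrom, length, autosome = TRUE) {
  stopifnot(!anyDuplicated(chrom), all(length > 0))
  df <- data.frame(
    chrom = as.character(chrom), length = as.integer(length),
    autosome = rep_len(autosome, base::length(chrom))
  )
  class(df) <- c("genome_table", "data.frame")
  df
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(
    "<sv_callset>", nrow(x$variants), "variants x",
    length(x$samples), "samples"
  )
  if (!is.null(x$caller)) cat(" [caller:", x$caller, "]")
  cat("\n  types:", paste(names(table(x$variants$vtype)),
    table(x$variants$vtype),
    sep = "=", collapse = " "
  ), "\n")
  invisible(x)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(
    "<haplotype_panel>", nrow(x$alleles), "haplotypes x",
    ncol(x$alleles), "variants;",
    length(unique(x$populations)), "population(s)\n"
  )
  invisible(x)
}
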