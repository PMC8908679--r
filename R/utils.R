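# Interval helpers (all intervals 0-based half-open) and small shared utilities.

#' Merge overlapping or near-adjacent intervals
#'
#' Intervals closer than `gap` base pairs (end-to-start) are joined into one.
#' With `gap = 0` only touching/overlapping intervals merge.
#'
#' @param start,end integer vectors of half-open interval bounds.
#' @param gap non-negative integer; intervals with `next_start - end < gap`
#'   are merged.
#' @return data.frame with columns `start`, `end`, sorted and disjoint.
#' @keywords internal
merge_intervals <- function(start, end, gap = 0L) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1L]
  me <- end[1L]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] - me < gap || start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Total length covered by a set of intervals (union semantics)
#' @inheritParams merge_intervals
#' @return integer union length in bp.
#' @keywords internal
interval_union_length <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end - m$start)
}

#' Length of the intersection of two interval sets
#' @param a,b data.frames with `start`/`end` columns (half-open).
#' @keywords internal
interval_intersect_length <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  a <- merge_intervals(a$start, a$end)
  b <- merge_intervals(b$start, b$end)
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$end[i], b$end)
    tot <- tot + sum(pmax(0L, e - s))
  }
  tot
}

# TRUE where half-open [s1,e1) overlaps any [s2,e2)
intervals_overlap_any <- function(s1, e1, s2, e2) {
  if (length(s2) == 0L) return(rep(FALSE, length(s1)))
  vapply(seq_along(s1), function(i) any(s1[i] < e2 & s2 < e1[i]), logical(1))
}

#' Derive a per-stage RNG seed from one top-level seed
#'
#' A single user-facing seed fans out to fixed per-stage seeds so that a
#' stage can be re-run in isolation with identical results. Kept below 2^31.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  offs <- c(
    panel = 101L, sv = 211L, depth = 307L, callers = 401L,
    fill = 503L, boot = 601L, tag = 701L, misc = 811L
  )
  off <- if (stage %in% names(offs)) offs[[stage]] else {
    sum(utf8ToInt(stage)) %% 997L
  }
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

# median of integer breakpoints with the lower value taken on even ties
median_low <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
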