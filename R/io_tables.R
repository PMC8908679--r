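# Plain-text table I/O: mosdepth-style windowed depth BEDs, array manifest
# position lists, and the chromosome-length table.

#' Read per-sample windowed depth BED files
#'
#' Each file holds rows `chrom  start  end  coverage` over fixed-width
#' windows (mosdepth-style, default 100 bp). Missing windows are zero-filled
#' (with a warning reporting the count); overlapping windows are an error.
#'
#' @param paths character vector of BED paths, named by sample id (an
#'   unnamed vector uses the file base names).
#' @param window expected window width in bp.
#' @return a [depth_profile()].
#' @export
read_depth_bed <- function(paths, window = 100L) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.bed$", "", basename(paths))
  }
  per_sample <- lapply(paths, function(p) {
    df <- read.table(
      p,
      sep = "\t", col.names = c("chrom", "start", "end", "coverage"),
      colClasses = c("character", "integer", "integer", "numeric")
    )
    if (any(df$end - df$start != window)) {
      stop("window width mismatch in ", p, " (expected ", window, " bp)")
    }
    df
  })
  chroms <- unique(unlist(lapply(per_sample, function(d) d$chrom)))
  n_filled <- 0L
  depth <- list()
  for (ch in chroms) {
    nwin <- max(vapply(
      per_sample,
      function(d) {
        e <- d$end[d$chrom == ch]
        if (length(e)) max(e) else 0L
      }, numeric(1)
    )) / window
    m <- matrix(0, nrow = nwin, ncol = length(per_sample),
      dimnames = list(NULL, names(paths))
    )
    for (s in seq_along(per_sample)) {
      d <- per_sample[[s]][per_sample[[s]]$chrom == ch, , drop = FALSE]
      idx <- d$start / window + 1L
      if (anyDuplicated(idx)) stop("overlapping depth windows on ", ch)
      m[idx, s] <- d$coverage
      n_filled <- n_filled + (nwin - nrow(d))
    }
    depth[[ch]] <- m
  }
  if (n_filled > 0L) {
    warning(n_filled, " missing depth window(s) zero-filled")
  }
  depth_profile(depth, window = window)
}

#' Write a depth profile as per-sample BED files
#' @param profile a [depth_profile()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_depth_bed <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- profile$window
  paths <- setNames(
    file.path(dir, paste0(profile$samples, ".bed")),
    profile$samples
  )
  for (s in seq_along(profile$samples)) {
    rows <- lapply(names(profile$depth), function(ch) {
      m <- profile$depth[[ch]]
      data.frame(
        chrom = ch, start = (seq_len(nrow(m)) - 1L) * w,
        end = seq_len(nrow(m)) * w, coverage = m[, s]
      )
    })
    write.table(
      do.call(rbind, rows), paths[s],
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  paths
}

#' Read an array manifest (chromosome, 1-based position)
#'
#' @param path two-column TSV; positions are converted to the internal
#'   0-based convention and duplicates dropped (count reported via message).
#' @return data.frame with columns `chrom`, `pos` (0-based), unique rows.
#' @export
read_array_manifest <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  df <- read.table(path, sep = "\t", col.names = c("chrom", "pos"),
    colClasses = c("character", "character")
  )
  pos <- suppressWarnings(as.numeric(df$pos))
  if (anyNA(pos) || any(pos != floor(pos))) {
    stop("non-integer position in manifest ", path)
  }
  out <- data.frame(chrom = df$chrom, pos = as.integer(pos) - 1L)
  dup <- duplicated(out)
  if (any(dup)) {
    message(sum(dup), " duplicate manifest position(s) removed")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read/write a chromosome-length table
#'
#' TSV with columns `chrom`, `length` and optional `autosome` (logical).
#' @param path file path.
#' @return a [genome_table()].
#' @export
read_genome_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  genome_table(df$chrom, df$length, if ("autosome" %in% names(df)) df$autosome else TRUE)
}

#' @rdname read_genome_table
#' @param genome a [genome_table()] to write.
#' @export
write_genome_table <- function(genome, path) {
  write.table(genome, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
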