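# VCF 4.2 reader/writer for the restricted dialect the pipeline exchanges:
# bivariate SNPs and symbolic SV ALTs (<DEL>/<DUP>/<INV>/<BND>) with INFO
# SVTYPE/END/CIPOS/CIEND and a GT-only FORMAT. POS is 1-based in the file and
# converted to the internal 0-based half-open convention on read.

vcf_header_lines <- function(samples) {
  h <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"Confidence interval around END\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=BND,Description=\"Translocation breakpoint\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  cols <- c(
    "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"
  )
  if (length(samples) > 0L) cols <- c(cols, "FORMAT", samples)
  c(h, paste(cols, collapse = "\t"))
}

parse_info <- function(info) {
  if (info == "." || info == "") {
    return(list())
  }
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  out <- lapply(kv, function(x) if (length(x) > 1L) x[2L] else TRUE)
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}

parse_ci <- function(x) {
  if (is.null(x)) {
    return(0L)
  }
  v <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1L]]))
  if (anyNA(v)) stop("malformed CIPOS/CIEND field: ", x)
  max(abs(v))
}

#' Read a VCF file
#'
#' Parses SNP and symbolic-SV records into a [variant_table()] plus a dosage
#' matrix, converting 1-based `POS` to the internal 0-based half-open span
#' (`start = POS - 1`; `end = INFO/END` for DEL/DUP/INV, `start + 1` for
#' SNP/BND). Records that cannot be represented (multi-allelic ALT, symbolic
#' ALT without `SVTYPE`, DEL/DUP/INV without `END`) are collected in a
#' rejected-record table rather than aborting the read; a malformed GT field
#' aborts with the offending line number.
#'
#' @param path VCF file path.
#' @param panel if `TRUE`, additionally build a phased [haplotype_panel()];
#'   requires every GT to be phased (`a|b`) and non-missing.
#' @return list with elements `variants` ([variant_table()]), `geno`
#'   (dosage matrix or `NULL` for site-only files), `panel`
#'   ([haplotype_panel()] or `NULL`), and `rejected`
#'   (data.frame `line`, `reason`).
#' @export
read_vcf <- function(path, panel = FALSE) {
  lines <- readLines(path)
  hdr <- startsWith(lines, "#")
  chrom_line <- lines[startsWith(lines, "#CHROM")]
  if (length(chrom_line) != 1L) stop("missing #CHROM header line")
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1L]]
  samples <- if (length(cols) > 9L) cols[-(1:9)] else character(0)
  body_idx <- which(!hdr & nzchar(lines))

  rec <- list()
  rej_line <- integer(0)
  rej_reason <- character(0)
  geno_rows <- list()
  hap_rows <- list()

  for (li in body_idx) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) stop("line ", li, ": truncated VCF record")
    alt <- f[5L]
    if (grepl(",", alt, fixed = TRUE)) {
      rej_line <- c(rej_line, li)
      rej_reason <- c(rej_reason, "multi-allelic ALT")
      next
    }
    info <- parse_info(f[8L])
    symbolic <- startsWith(alt, "<")
    if (symbolic && is.null(info$SVTYPE)) {
      rej_line <- c(rej_line, li)
      rej_reason <- c(rej_reason, "symbolic ALT without SVTYPE")
      next
    }
    vtype <- if (symbolic) info$SVTYPE else "SNP"
    if (!vtype %in% VARIANT_TYPES) {
      rej_line <- c(rej_line, li)
      rej_reason <- c(rej_reason, paste0("unsupported SVTYPE ", vtype))
      next
    }
    start <- as.integer(f[2L]) - 1L
    if (vtype %in% c("SNP", "BND")) {
      end <- start + 1L
    } else {
      if (is.null(info$END)) {
        rej_line <- c(rej_line, li)
        rej_reason <- c(rej_reason, "missing END for spanning SV")
        next
      }
      end <- as.integer(info$END)
    }
    dosage <- NULL
    haps <- NULL
    if (length(samples) > 0L) {
      if (length(f) < 9L + length(samples)) {
        stop("line ", li, ": missing genotype columns")
      }
      gt <- sub(":.*$", "", f[10:(9L + length(samples))])
      ok <- grepl("^([0-9.])([|/])([0-9.])$", gt)
      if (!all(ok)) {
        stop("line ", li, ": malformed GT field '", gt[which(!ok)[1L]], "'")
      }
      a1 <- substr(gt, 1L, 1L)
      a2 <- substr(gt, 3L, 3L)
      if (any(c(a1, a2) %in% as.character(2:9))) {
        stop("line ", li, ": only biallelic GT values 0/1 supported")
      }
      miss <- a1 == "." | a2 == "."
      dosage <- ifelse(miss, NA_integer_,
        as.integer(a1 == "1") + as.integer(a2 == "1")
      )
      if (panel) {
        phased <- substr(gt, 2L, 2L) == "|"
        if (any(miss) || !all(phased)) {
          stop(
            "line ", li,
            ": unphased or missing GT but a haplotype panel was requested"
          )
        }
        haps <- rbind(as.integer(a1 == "1"), as.integer(a2 == "1"))
      }
    }
    rec[[length(rec) + 1L]] <- list(
      id = f[3L], chrom = f[1L], start = start, end = end, vtype = vtype,
      ci_start = parse_ci(info$CIPOS), ci_end = parse_ci(info$CIEND),
      ref = f[4L], alt = alt, dosage = dosage, haps = haps
    )
  }

  rejected <- data.frame(line = rej_line, reason = rej_reason)
  if (length(rec) == 0L) {
    return(list(
      variants = variant_table(
        character(0), character(0), integer(0), integer(0), character(0)
      ),
      geno = NULL, panel = NULL, rejected = rejected
    ))
  }
  pull <- function(k) vapply(rec, function(r) r[[k]], rec[[1L]][[k]])
  variants <- variant_table(
    id = pull("id"), chrom = pull("chrom"),
    start = pull("start"), end = pull("end"), vtype = pull("vtype"),
    ci_start = pull("ci_start"), ci_end = pull("ci_end"),
    ref = pull("ref"), alt = pull("alt")
  )
  geno <- NULL
  hp <- NULL
  if (length(samples) > 0L) {
    geno <- do.call(rbind, lapply(rec, `[[`, "dosage"))
    rownames(geno) <- vapply(rec, `[[`, "", "id")
    geno <- geno[variants$id, , drop = FALSE]
    colnames(geno) <- samples
    storage.mode(geno) <- "integer"
    if (panel) {
      al <- do.call(cbind, lapply(rec, function(r) as.vector(r$haps)))
      colnames(al) <- vapply(rec, `[[`, "", "id")
      al <- al[, variants$id, drop = FALSE]
      hp <- haplotype_panel(
        al, samples, variants,
        populations = rep("pop1", length(samples))
      )
    }
  }
  list(variants = variants, geno = geno, panel = hp, rejected = rejected)
}

format_gt <- function(dosage, phased_alleles = NULL) {
  if (!is.null(phased_alleles)) {
    paste0(phased_alleles[1L, ], "|", phased_alleles[2L, ])
  } else {
    out <- c("0/0", "0/1", "1/1")[dosage + 1L]
    out[is.na(dosage)] <- "./."
    out
  }
}

#' Write a VCF file
#'
#' Inverse of [read_vcf()]: internal 0-based spans become 1-based `POS` and
#' `INFO/END`. When `panel` is supplied, phased `a|b` genotypes are written;
#' with `geno` only, unphased `a/b` genotypes (missing as `./.`).
#'
#' @param variants a [variant_table()] sorted by (chrom, start); unsorted
#'   input is an error.
#' @param path output file path.
#' @param geno optional dosage matrix (variants x samples).
#' @param panel optional [haplotype_panel()] over the same variants.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, geno = NULL, panel = NULL) {
  key <- order(variants$chrom, variants$start)
  if (!identical(key, seq_len(nrow(variants)))) {
    stop("variants must be sorted by (chrom, start) before writing")
  }
  if (!is.null(panel)) {
    samples <- panel$samples
  } else if (!is.null(geno)) {
    samples <- colnames(geno)
  } else {
    samples <- character(0)
  }
  lines <- vcf_header_lines(samples)
  if (nrow(variants) > 0L) {
    info <- ifelse(
      variants$vtype == "SNP", ".",
      ifelse(
        variants$vtype == "BND",
        sprintf(
          "SVTYPE=BND;CIPOS=-%d,%d;CIEND=-%d,%d",
          variants$ci_start, variants$ci_start,
          variants$ci_end, variants$ci_end
        ),
        sprintf(
          "SVTYPE=%s;END=%d;CIPOS=-%d,%d;CIEND=-%d,%d",
          variants$vtype, variants$end,
          variants$ci_start, variants$ci_start,
          variants$ci_end, variants$ci_end
        )
      )
    )
    body <- paste(
      variants$chrom, variants$start + 1L, variants$id,
      variants$ref, variants$alt, ".", ".", info,
      sep = "\t"
    )
    if (length(samples) > 0L) {
      gt <- character(nrow(variants))
      for (i in seq_len(nrow(variants))) {
        gt[i] <- paste(
          if (!is.null(panel)) {
            format_gt(NULL, matrix(panel$alleles[, variants$id[i]], nrow = 2L))
          } else {
            format_gt(geno[variants$id[i], ])
          },
          collapse = "\t"
        )
      }
      body <- paste(body, "GT", gt, sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
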