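# File interchange: the tagged FASTQ dialect, TSV writers with commented
# headers, SAM/BAM input with barcode tags, and the VCF-like call export.

#' Write reads in the tagged FASTQ dialect
#'
#' Read names encode the cell barcode, UMI, transcript and 0-based start:
#' `@<readid>|CB:<barcode>|UMI:<umi>|TX:<transcript_id>|POS:<start0>`.
#'
#' @param reads A read tibble as produced by [sim_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_tagged_fastq <- function(reads, path) {
  hdr <- paste0("@", reads$read_id,
                "|CB:", reads$cell_barcode,
                "|UMI:", reads$umi,
                "|TX:", reads$transcript_id,
                "|POS:", reads$start)
  lines <- as.vector(rbind(hdr, reads$sequence, "+", reads$qualities))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a tagged FASTQ file into a read tibble
#'
#' Parses FASTQ via Biostrings when available (falling back to a line
#' reader) and decodes the tagged read-name dialect written by
#' [write_tagged_fastq()]. Reads whose names lack the barcode or UMI tags
#' are dropped with a tally message.
#'
#' @param path FASTQ path.
#' @return A read tibble (`read_id`, `cell_barcode`, `umi`, `transcript_id`,
#'   `start`, `sequence`, `qualities`), with a `dropped` attribute counting
#'   discarded untagged reads.
#' @export
read_tagged_fastq <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    # Biostrings warns about dropping its own metadata columns here; the
    # columns carry nothing we use
    fq <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    nm <- names(fq)
    seqv <- suppressWarnings(as.character(fq))
    qualv <- suppressWarnings(as.character(Biostrings::quality(fq)))
  } else {
    lines <- readr::read_lines(path)
    nm <- sub("^@", "", lines[seq(1, length(lines), by = 4L)])
    seqv <- lines[seq(2, length(lines), by = 4L)]
    qualv <- lines[seq(4, length(lines), by = 4L)]
  }
  m <- stringr::str_match(
    nm, "^([^|]+)\\|CB:([^|]+)\\|UMI:([^|]+)\\|TX:([^|]+)\\|POS:(\\d+)$")
  ok <- !is.na(m[, 1])
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    inform(sprintf("read_tagged_fastq: dropped %d read(s) without CB/UMI tags",
                   n_drop))
  }
  out <- tibble::tibble(
    read_id = m[ok, 2], cell_barcode = m[ok, 3], umi = m[ok, 4],
    transcript_id = m[ok, 5], start = as.integer(m[ok, 6]),
    sequence = unname(seqv[ok]), qualities = unname(qualv[ok])
  )
  attr(out, "dropped") <- n_drop
  out
}

#' Read aligned reads with barcode tags from SAM/BAM
#'
#' Thin wrapper over Rsamtools for externally aligned data carrying cell
#' barcode and UMI tags (10x-style `CB`/`UB` by default; tag names are
#' configurable). Alignment positions are converted to the package's
#' 0-based convention; only primary, mapped records are kept. Reads missing
#' either tag are dropped with a tally message.
#'
#' @param path BAM (or SAM, converted via `Rsamtools::asBam`) file path.
#' @param cb_tag,umi_tag Names of the barcode and UMI tags.
#' @return A read tibble as for [read_tagged_fastq()].
#' @export
read_tagged_bam <- function(path, cb_tag = "CB", umi_tag = "UB") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Reading BAM input requires the Rsamtools package.")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, sub("\\.sam$", "", path),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "seq", "qual"),
    tag = c(cb_tag, umi_tag),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  cb <- b$tag[[cb_tag]] %||% rep(NA_character_, length(b$qname))
  ub <- b$tag[[umi_tag]] %||% rep(NA_character_, length(b$qname))
  ok <- !is.na(cb) & !is.na(ub)
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    inform(sprintf("read_tagged_bam: dropped %d read(s) without %s/%s tags",
                   n_drop, cb_tag, umi_tag))
  }
  out <- tibble::tibble(
    read_id = b$qname[ok],
    cell_barcode = cb[ok],
    umi = ub[ok],
    transcript_id = as.character(b$rname)[ok],
    start = b$pos[ok] - 1L,
    sequence = as.character(b$seq)[ok],
    qualities = as.character(b$qual)[ok]
  )
  attr(out, "dropped") <- n_drop
  out
}

# TSV with a commented header block; readable back with read_tm_tsv()
write_tm_tsv <- function(x, path, comment = NULL) {
  hdr <- c(paste0("# ", format(Sys.time(), "%Y-%m-%d")),
           if (!is.null(comment)) paste0("# ", comment))
  readr::write_lines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a package TSV (commented header) back into a tibble
#'
#' @param path TSV path written by the pipeline.
#' @return A tibble.
#' @export
read_tm_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Export discrepancy calls as a VCF-like TSV
#'
#' One record per (cell, site, alternate base). Positions are converted to
#' 1-based, as flagged in the header; everything else in the package is
#' 0-based half-open.
#'
#' @param calls A discrepancy-call tibble (see [call_discrepancies()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c(
    "##fileformat=VCF-like-TSVv1",
    "##convention=positions are 1-based in this export (0-based elsewhere)",
    "##INFO=NMUT mutant molecule count;NWT wild-type molecule count;CB cell barcode;CLASS site classification",
    "#CHROM\tPOS\tID\tREF\tALT\tINFO"
  )
  info <- paste0("NMUT=", calls$n_mut, ";NWT=", calls$n_wt,
                 ";CB=", calls$cell_barcode,
                 if (!is.null(calls$classification))
                   paste0(";CLASS=", calls$classification) else "")
  body <- paste(calls$transcript_id, calls$position + 1L, ".",
                calls$ref_base, calls$alt_base, info, sep = "\t")
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Remove calls at blacklisted sites
#'
#' Optional hook for masking recurrent artifact sites (for example known
#' RNA-editing-like positions). The blacklist is BED-format: 0-based,
#' half-open intervals on transcript coordinates. The package ships no
#' default blacklist.
#'
#' @param calls A discrepancy-call tibble.
#' @param bed_path Path to a 3+ column BED file (`transcript_id`, `start`,
#'   `end`); comment lines starting with `#` are ignored.
#' @return `calls` with blacklisted records removed.
#' @export
filter_blacklist <- function(calls, bed_path) {
  bed <- readr::read_tsv(bed_path, comment = "#", col_names = FALSE,
                         show_col_types = FALSE, progress = FALSE)
  if (nrow(bed) == 0L) return(calls)
  bad <- purrr::pmap(list(bed[[1]], bed[[2]], bed[[3]]), function(tx, s, e) {
    which(calls$transcript_id == tx & calls$position >= s & calls$position < e)
  })
  drop <- unique(unlist(bad))
  if (length(drop)) calls[-drop, ] else calls
}
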