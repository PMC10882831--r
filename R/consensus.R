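# UMI family grouping and consensus collapsing. Sequencing errors are
# private to one read and vanish under the (default) unanimity rule; PCR
# errors from the first duplication are shared by the whole family and
# survive as an irreducible floor quantified in the tests.

RAW_BASES <- charToRaw("ACGT")
RAW_N <- charToRaw("N")

#' Group reads into UMI families
#'
#' A family is the set of reads sharing one exact (cell barcode, UMI,
#' transcript) key; UMIs are not network-collapsed, so reads whose UMI
#' carries a sequencing error form their own (typically singleton) family.
#' Reads with a missing or empty barcode/UMI are dropped with a tally.
#'
#' @param reads A read tibble (see [read_tagged_fastq()]).
#' @return A nested tibble with one row per family: `cell_barcode`, `umi`,
#'   `transcript_id`, `n_reads` and a `reads` list-column; the number of
#'   dropped reads is attached as attribute `dropped`.
#' @export
group_families <- function(reads) {
  ok <- !is.na(reads$cell_barcode) & reads$cell_barcode != "" &
    !is.na(reads$umi) & reads$umi != ""
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    inform(sprintf("group_families: dropped %d read(s) missing barcode/UMI",
                   n_drop))
  }
  out <- reads[ok, ] |>
    tidyr::nest(reads = !dplyr::all_of(c("cell_barcode", "umi",
                                         "transcript_id"))) |>
    dplyr::mutate(n_reads = vapply(.data$reads, nrow, integer(1)),
                  .before = "reads")
  attr(out, "dropped") <- n_drop
  out
}

#' Collapse one UMI family into a molecule consensus
#'
#' Reference implementation for a single family; [collapse_families()] is
#' the vectorised equivalent used by the pipeline. Positions not covered by
#' every read are trimmed (intersection of read extents), then each column
#' takes the majority base among the reads; a column whose top base fraction
#' is below `min_agreement`, or that is tied, is masked `N` and excluded
#' from every downstream denominator.
#'
#' @param family Tibble of reads sharing one family key.
#' @param min_reads Minimum family size; smaller families are rejected.
#' @param min_agreement Minimum fraction of reads that must carry the top
#'   base (default 1: unanimity).
#' @return A list of class `tm_consensus` with fields `cell_barcode`, `umi`,
#'   `transcript_id`, `start`, `consensus`, `family_size`, `n_agree`
#'   (per-position agreeing reads) and `n_total`; or a `tm_rejected` with a
#'   `reason` (`small_family`, `chimeric_family`, `no_overlap`).
#' @export
build_consensus <- function(family, min_reads = 2, min_agreement = 1) {
  if (nrow(family) < min_reads) {
    return(rejected("small_family"))
  }
  if (length(unique(family$transcript_id)) != 1L) {
    return(rejected("chimeric_family"))
  }
  s <- max(family$start)
  e <- min(family$start + nchar(family$sequence))
  if (e <= s) {
    return(rejected("no_overlap"))
  }
  L <- e - s
  k <- nrow(family)
  mat <- matrix(as.raw(0), nrow = L, ncol = k)
  for (i in seq_len(k)) {
    off <- s - family$start[i]
    mat[, i] <- charToRaw(substr(family$sequence[i], off + 1L, off + L))
  }
  cnt <- vapply(RAW_BASES, function(b) rowSums(mat == b), numeric(L))
  cnt <- matrix(cnt, nrow = L)           # L x 4, robust to L == 1
  top_idx <- max.col(cnt, ties.method = "first")
  top <- cnt[cbind(seq_len(L), top_idx)]
  tied <- rowSums(cnt == top) > 1L
  cons <- DNA_BASES[top_idx]
  masked <- tied | top < min_agreement * k
  cons[masked] <- "N"
  structure(
    list(cell_barcode = family$cell_barcode[1], umi = family$umi[1],
         transcript_id = family$transcript_id[1], start = s,
         consensus = paste(cons, collapse = ""),
         family_size = k,
         n_agree = as.integer(top), n_total = k),
    class = "tm_consensus"
  )
}

rejected <- function(reason) {
  structure(list(reason = reason), class = "tm_rejected")
}

#' @export
print.tm_consensus <- function(x, ...) {
  cat(sprintf("<tm_consensus> %s/%s %s:%d (%d reads)\n%s\n",
              x$cell_barcode, x$umi, x$transcript_id, x$start,
              x$family_size, x$consensus))
  invisible(x)
}

#' Collapse all UMI families into molecule consensus sequences
#'
#' Vectorised consensus over every (cell barcode, UMI, transcript) family.
#' Families smaller than `min_reads` are rejected and tallied; the majority
#' / masking rules are those of [build_consensus()]. Column order of the
#' input does not affect the result.
#'
#' @param reads A read tibble.
#' @inheritParams build_consensus
#' @return A molecule tibble with one row per accepted family:
#'   `cell_barcode`, `umi`, `transcript_id`, `start` (0-based), `length`,
#'   `consensus` (masked positions as `N`), `family_size`, `n_masked`.
#'   Rejection tallies are attached as attribute `rejections` and reported
#'   via a message.
#' @export
collapse_families <- function(reads, min_reads = 2, min_agreement = 1) {
  rej <- c(small_family = 0L, chimeric_family = 0L, no_overlap = 0L,
           missing_tags = 0L)
  ok <- !is.na(reads$cell_barcode) & reads$cell_barcode != "" &
    !is.na(reads$umi) & reads$umi != ""
  rej[["missing_tags"]] <- sum(!ok)
  reads <- reads[ok, ]
  if (nrow(reads) == 0L) {
    out <- empty_molecules()
    attr(out, "rejections") <- rej
    return(out)
  }

  fid <- vctrs::vec_group_id(
    reads[c("cell_barcode", "umi", "transcript_id")])
  ord <- order(fid)
  reads <- reads[ord, ]
  fid <- fid[ord]
  sizes <- tabulate(fid)

  small <- sizes[fid] < min_reads
  rej[["small_family"]] <- sum(sizes < min_reads)
  reads <- reads[!small, ]
  fid <- fid[!small]
  if (nrow(reads) == 0L) {
    out <- empty_molecules()
    attr(out, "rejections") <- rej
    return(out)
  }
  fid <- match(fid, unique(fid))         # compact ids, order preserved
  sizes <- tabulate(fid)
  first <- cumsum(sizes) - sizes + 1L

  len <- nchar(reads$sequence)
  same_prev <- c(FALSE, fid[-1] == fid[-length(fid)])
  uneven <- same_prev &
    (reads$start != c(0L, reads$start[-nrow(reads)]) |
       len != c(0L, len[-length(len)]))
  bad_fam <- unique(fid[uneven])         # mixed extents: scalar fallback

  res_slow <- list()
  if (length(bad_fam)) {
    in_bad <- fid %in% bad_fam
    res_slow <- lapply(split(which(in_bad), fid[in_bad]), function(i) {
      build_consensus(reads[i, ], min_reads = min_reads,
                      min_agreement = min_agreement)
    })
    is_rej <- vapply(res_slow, inherits, logical(1), "tm_rejected")
    for (r in res_slow[is_rej]) rej[[r$reason]] <- rej[[r$reason]] + 1L
    res_slow <- res_slow[!is_rej]
    reads <- reads[!in_bad, ]
    fid <- fid[!in_bad]
    fid <- match(fid, unique(fid))
    sizes <- tabulate(fid)
    first <- cumsum(sizes) - sizes + 1L
    len <- nchar(reads$sequence)
    same_prev <- c(FALSE, fid[-1] == fid[-length(fid)])
  }

  out_fast <- NULL
  if (length(sizes)) {
    if (min_agreement >= 1) {
      v <- cpp_unanimity_consensus(reads$sequence, first, sizes)
      cons <- v$consensus
      n_masked <- v$n_masked
    } else {
      # families whose reads are byte-identical need no column vote
      differ <- same_prev &
        reads$sequence != c("", reads$sequence[-nrow(reads)])
      n_diff <- tabulate(fid[differ], nbins = length(sizes))
      uniform <- n_diff == 0L

      cons <- character(length(sizes))
      n_masked <- integer(length(sizes))
      cons[uniform] <- reads$sequence[first[uniform]]

      vote_fams <- which(!uniform)
      if (length(vote_fams)) {
        key <- paste0(len[first[vote_fams]], "_", sizes[vote_fams])
        for (grp in split(vote_fams, key)) {
          L <- len[first[grp[1]]]
          k <- sizes[grp[1]]
          ridx <- sequence(rep.int(k, length(grp)), from = first[grp])
          bytes <- charToRaw(paste0(reads$sequence[ridx], collapse = ""))
          dim(bytes) <- c(L, k * length(grp))
          v <- vote_columns(bytes, k, length(grp), min_agreement)
          cons[grp] <- v$consensus
          n_masked[grp] <- v$n_masked
        }
      }
    }
    out_fast <- tibble::tibble(
      cell_barcode = reads$cell_barcode[first],
      umi = reads$umi[first],
      transcript_id = reads$transcript_id[first],
      start = reads$start[first],
      length = len[first],
      consensus = cons,
      family_size = sizes,
      n_masked = n_masked
    )
  }

  out_slow <- if (length(res_slow)) {
    tibble::tibble(
      cell_barcode = vapply(res_slow, `[[`, character(1), "cell_barcode"),
      umi = vapply(res_slow, `[[`, character(1), "umi"),
      transcript_id = vapply(res_slow, `[[`, character(1), "transcript_id"),
      start = vapply(res_slow, `[[`, integer(1), "start"),
      length = nchar(vapply(res_slow, `[[`, character(1), "consensus")),
      consensus = vapply(res_slow, `[[`, character(1), "consensus"),
      family_size = vapply(res_slow, `[[`, integer(1), "family_size"),
      n_masked = vapply(res_slow, function(x)
        sum(strsplit(x$consensus, "")[[1]] == "N"), integer(1))
    )
  }

  out <- dplyr::bind_rows(out_fast, out_slow)
  if (sum(rej) > 0) {
    inform(paste0("collapse_families: rejected ",
                  paste0(names(rej)[rej > 0], "=", rej[rej > 0],
                         collapse = ", ")))
  }
  attr(out, "rejections") <- rej
  out
}

# Majority vote over columns for a block of same-length, same-size families.
# bytes: L x (k * nf) raw matrix, family-major columns.
vote_columns <- function(bytes, k, nf, min_agreement) {
  L <- nrow(bytes)
  cnt <- vector("list", 4L)
  for (b in 1:4) {
    acc <- matrix(0L, nrow = L, ncol = nf)
    eq <- bytes == RAW_BASES[b]
    dim(eq) <- c(L, k * nf)
    for (j in seq_len(k)) {
      acc <- acc + eq[, seq.int(j, by = k, length.out = nf), drop = FALSE]
    }
    cnt[[b]] <- acc
  }
  top <- cnt[[1]]
  idx <- matrix(1L, nrow = L, ncol = nf)
  for (b in 2:4) {
    better <- cnt[[b]] > top
    top[better] <- cnt[[b]][better]
    idx[better] <- b
  }
  runner <- matrix(-1L, nrow = L, ncol = nf)
  for (b in 1:4) {
    cand <- cnt[[b]]
    cand[idx == b] <- -1L
    runner <- pmax(runner, cand)
  }
  mask <- (runner == top) | (top < min_agreement * k)
  cons_bytes <- RAW_BASES[idx]
  cons_bytes[mask] <- RAW_N
  dim(cons_bytes) <- dim(idx)
  all_str <- rawToChar(as.vector(cons_bytes))
  list(
    consensus = substring(all_str, (seq_len(nf) - 1L) * L + 1L,
                          seq_len(nf) * L),
    n_masked = as.integer(colSums(mask))
  )
}

empty_molecules <- function() {
  tibble::tibble(cell_barcode = character(), umi = character(),
                 transcript_id = character(), start = integer(),
                 length = integer(), consensus = character(),
                 family_size = integer(), n_masked = integer())
}
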