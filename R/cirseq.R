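# Rolling-circle consensus sequencing (CirSeq) support: simulate tandem-
# repeat reads, detect the repeat period, fold repeats into an intra-read
# consensus, and estimate bulk error rates. Errors made during transcription
# precede circularisation, so they are shared by all repeats of a read;
# sequencing errors hit single copies and are suppressed by folding.

#' Simulate rolling-circle (CirSeq) reads
#'
#' Each read is `repeat_count` tandem copies of one RNA fragment.
#' Transcription-level errors (`background_tx_error_rate` and
#' `molecule_error_rates`; in bulk data lesion-driven miscoding is expressed
#' through the latter, since cells are not resolved) are applied to the
#' fragment before circularisation and therefore appear in every repeat;
#' sequencing errors are drawn independently per repeat copy.
#'
#' @inheritParams sim_reads
#' @param repeat_count Number of tandem copies per read (>= 2).
#' @param fragment_length RNA fragment length (>= 1, at most the shortest
#'   transcript).
#' @param n_fragments Number of fragments; defaults to
#'   `n_cells * molecules_per_cell_per_transcript * nrow(reference)`.
#' @return A list of class `tm_cirseq_sim`: `reads` (read tibble in the
#'   tagged dialect, `cell_barcode = "bulk"`), `variants` (the
#'   transcription-level ground truth: `fragment`, `transcript_id`,
#'   `position`, `alt_base`, `origin`), `config`.
#' @export
sim_cirseq_reads <- function(reference, config, repeat_count = 3,
                             fragment_length = 100, n_fragments = NULL) {
  reference <- validate_reference(reference)
  config <- validate_sim_config(config)
  if (repeat_count < 2) abort("`repeat_count` must be at least 2.")
  if (fragment_length < 1) abort("`fragment_length` must be at least 1.")
  if (any(reference$length < fragment_length)) {
    abort("`fragment_length` exceeds the shortest reference transcript.")
  }
  set.seed(config$seed)
  n_frag <- n_fragments %||%
    (config$n_cells * config$molecules_per_cell_per_transcript *
       nrow(reference))
  n_frag <- as.integer(n_frag)
  seqs <- reference$sequence
  tx_len <- reference$length
  frag <- as.integer(fragment_length)

  w <- (tx_len - frag + 1)
  tx <- sample.int(nrow(reference), n_frag, replace = TRUE, prob = w)
  start <- as.integer(floor(runif(n_frag) * w[tx]))

  frag_seq <- substring(seqs[tx], start + 1L, start + frag)

  ## transcription-level (pre-circularisation) errors --------------------
  ev <- list()
  mer <- config$molecule_error_rates
  if (!is.null(mer) && nrow(mer) > 0L) {
    tx_off <- cumsum(c(0L, tx_len + 1L))
    for (i in seq_len(nrow(mer))) {
      b <- mer$ref_base[i]
      cb <- unlist(lapply(seqs, function(s)
        c(0L, cumsum(charToRaw(s) == charToRaw(b)))), use.names = FALSE)
      before <- cb[tx_off[tx] + start + 1L]
      n_b <- cb[tx_off[tx] + start + frag + 1L] - before
      total <- sum(as.numeric(n_b))
      if (total == 0) next
      n_ev <- rbinom(1L, total, mer$rate[i])
      if (n_ev == 0L) next
      g <- sample.int(total, n_ev)
      cs <- cumsum(as.numeric(n_b))
      f <- findInterval(g - 0.5, c(0, cs))
      j <- g - c(0, cs)[f]
      pb <- lapply(seqs, base_positions0, b)
      off <- cumsum(c(0L, lengths(pb)))
      posv <- unlist(pb, use.names = FALSE)[off[tx[f]] + before[f] + j]
      ev[[paste0("mer", i)]] <- tibble::tibble(
        fragment = f, position = posv, alt_base = mer$alt_base[i],
        origin = "molecule_error")
    }
  }
  if (config$background_tx_error_rate > 0) {
    total <- as.numeric(n_frag) * frag
    n_ev <- rbinom(1L, total, config$background_tx_error_rate)
    if (n_ev > 0L) {
      g <- sample.int(total, n_ev)
      f <- as.integer((g - 1) %/% frag) + 1L
      posv <- start[f] + as.integer((g - 1) %% frag)
      refb <- substr(seqs[tx[f]], posv + 1L, posv + 1L)
      ev[["background"]] <- tibble::tibble(
        fragment = f, position = posv,
        alt_base = OTHER_BASES[cbind(base_index(refb),
                                     sample.int(3L, n_ev, TRUE))],
        origin = "background")
    }
  }
  ev <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(fragment = integer(), position = integer(),
                   alt_base = character(), origin = character())
  if (nrow(ev)) {
    key <- (ev$fragment - 1) * (max(tx_len) + 1) + ev$position
    ev <- ev[!duplicated(key), ]
    frag_seq <- apply_substitutions(frag_seq, ev$fragment,
                                    ev$position - start[ev$fragment] + 1L,
                                    ev$alt_base)
  }

  ## circularise and sequence --------------------------------------------
  read_seq <- strrep(frag_seq, repeat_count)
  if (config$seq_error_rate > 0) {
    rl <- frag * repeat_count
    total <- as.numeric(n_frag) * rl
    n_ev <- rbinom(1L, total, config$seq_error_rate)
    if (n_ev > 0L) {
      g <- sample.int(total, n_ev)
      f <- as.integer((g - 1) %/% rl) + 1L
      posr <- as.integer((g - 1) %% rl) + 1L          # 1-based within read
      cur <- substr(frag_seq[f], (posr - 1L) %% frag + 1L,
                    (posr - 1L) %% frag + 1L)
      altv <- OTHER_BASES[cbind(base_index(cur), sample.int(3L, n_ev, TRUE))]
      read_seq <- apply_substitutions(read_seq, f, posr, altv)
    }
  }

  qual <- strrep(phred_char(config$quality_phred), frag * repeat_count)
  reads <- tibble::tibble(
    read_id = paste0("cr", seq_len(n_frag)),
    cell_barcode = "bulk",
    umi = paste0("f", seq_len(n_frag)),
    transcript_id = reference$transcript_id[tx],
    start = start,
    sequence = read_seq,
    qualities = qual
  )
  variants <- tibble::tibble(
    fragment = ev$fragment,
    transcript_id = reference$transcript_id[tx[ev$fragment]],
    position = as.integer(ev$position),
    alt_base = ev$alt_base,
    origin = ev$origin
  )
  structure(list(reads = reads, variants = variants, config = config),
            class = "tm_cirseq_sim")
}

#' @rdname sim_cirseq_reads
#' @param out_dir Output directory for FASTQ + truth TSV.
#' @param prefix File name prefix.
#' @return For `simulate_cirseq()`: invisibly, a list with `fastq`,
#'   `truth_path` and the simulation object.
#' @export
simulate_cirseq <- function(reference, config, repeat_count = 3,
                            fragment_length = 100, n_fragments = NULL,
                            out_dir = tempdir(), prefix = "cirseq") {
  sim <- sim_cirseq_reads(reference, config, repeat_count, fragment_length,
                          n_fragments)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fastq <- file.path(out_dir, paste0(prefix, ".fastq"))
  truth_path <- file.path(out_dir, paste0(prefix, "_truth.tsv"))
  write_tagged_fastq(sim$reads, fastq)
  write_tm_tsv(sim$variants, truth_path,
               comment = "pre-circularisation errors; position is 0-based")
  invisible(list(fastq = fastq, truth_path = truth_path, sim = sim))
}

#' Detect the tandem-repeat period of a rolling-circle read
#'
#' Finds the period `p` minimising the fraction of mismatches between the
#' read and itself shifted by `p` (compared over `length - p` bases),
#' among candidates in `[min_period, max_period]` that satisfy a mismatch
#' fraction of at most `max_mismatch_frac` and at least `min_repeats` full
#' repeats. Self-offset minimisation is transparent and directly checkable
#' against a brute-force scan. Ties go to the smallest period.
#'
#' @param sequence A read sequence.
#' @param min_period,max_period Candidate period range in bases.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction (default
#'   0.1).
#' @param min_repeats Minimum number of (full) repeats (default 3).
#' @return The period as an integer, or `NA_integer_` if no candidate
#'   qualifies.
#' @export
detect_period <- function(sequence, min_period, max_period,
                          max_mismatch_frac = 0.1, min_repeats = 3) {
  L <- nchar(sequence)
  if (L < 2 * min_period) return(NA_integer_)
  x <- charToRaw(sequence)
  best_p <- NA_integer_
  best_f <- Inf
  for (p in seq.int(min_period, min(max_period, L - 1L))) {
    if (L %/% p < min_repeats) next
    f <- sum(x[seq_len(L - p)] != x[seq.int(p + 1L, L)]) / (L - p)
    if (f <= max_mismatch_frac && f < best_f) {
      best_f <- f
      best_p <- p
    }
  }
  best_p
}

# Vectorised period detection for a block of equal-length reads.
detect_periods <- function(sequences, min_period, max_period,
                           max_mismatch_frac = 0.1, min_repeats = 3) {
  if (length(sequences) == 0L) return(integer(0))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    return(vapply(sequences, detect_period, integer(1),
                  min_period = min_period, max_period = max_period,
                  max_mismatch_frac = max_mismatch_frac,
                  min_repeats = min_repeats, USE.NAMES = FALSE))
  }
  L <- lens[1]
  if (L < 2 * min_period) return(rep(NA_integer_, length(sequences)))
  bytes <- charToRaw(paste0(sequences, collapse = ""))
  dim(bytes) <- c(L, length(sequences))
  best_p <- rep(NA_integer_, length(sequences))
  best_f <- rep(Inf, length(sequences))
  for (p in seq.int(min_period, min(max_period, L - 1L))) {
    if (L %/% p < min_repeats) next
    f <- colSums(bytes[seq_len(L - p), , drop = FALSE] !=
                   bytes[seq.int(p + 1L, L), , drop = FALSE]) / (L - p)
    upd <- f <= max_mismatch_frac & f < best_f
    best_f[upd] <- f[upd]
    best_p[upd] <- p
  }
  best_p
}

#' Fold a rolling-circle read into its repeat consensus
#'
#' Column `j` of the consensus is the quality-weighted plurality over read
#' positions `j, j + p, j + 2p, ...` (a partial trailing repeat contributes
#' to the columns it covers). A column is masked `N` when the winning
#' base's summed quality is below twice the runner-up's; the read is
#' rejected when more than `max_masked_frac` of columns are masked, or when
#' it holds fewer than `min_repeats` full repeats.
#'
#' @param sequence Read sequence.
#' @param qualities FASTQ quality string of the same length.
#' @param period Repeat period from [detect_period()] (must be positive).
#' @param min_repeats Minimum full repeats (default 3).
#' @param max_masked_frac Maximum masked-column fraction (default 0.2).
#' @return A list of class `tm_repeat_consensus`: `period`, `n_repeats`,
#'   `consensus` (length `period`), `n_agree`, `n_total` per column; or a
#'   `tm_rejected` with reason `too_few_repeats` / `too_masked`.
#' @export
fold_consensus <- function(sequence, qualities, period, min_repeats = 3,
                           max_masked_frac = 0.2) {
  if (is.na(period) || period <= 0) abort("`period` must be positive.")
  L <- nchar(sequence)
  period <- as.integer(period)
  if (L %/% period < min_repeats) return(rejected("too_few_repeats"))
  x <- charToRaw(sequence)
  q <- as.integer(charToRaw(qualities)) - 33L
  if (length(q) != L) abort("`qualities` must match the sequence length.")
  n_copies <- ceiling(L / period)
  wt <- matrix(0, nrow = period, ncol = 4L)
  n_total <- integer(period)
  cnt <- matrix(0L, nrow = period, ncol = 4L)
  for (cp in seq_len(n_copies) - 1L) {
    j <- seq_len(min(period, L - cp * period))
    pos <- cp * period + j
    for (b in 1:4) {
      hit <- x[pos] == RAW_BASES[b]
      wt[j, b] <- wt[j, b] + ifelse(hit, q[pos], 0)
      cnt[j, b] <- cnt[j, b] + hit
    }
    n_total[j] <- n_total[j] + 1L
  }
  top_idx <- max.col(wt, ties.method = "first")
  top <- wt[cbind(seq_len(period), top_idx)]
  runner <- vapply(seq_len(period), function(i) {
    max(wt[i, -top_idx[i]])
  }, numeric(1))
  mask <- top < 2 * runner
  cons <- DNA_BASES[top_idx]
  cons[mask] <- "N"
  if (mean(mask) > max_masked_frac) return(rejected("too_masked"))
  structure(
    list(period = period, n_repeats = L %/% period,
         consensus = paste(cons, collapse = ""),
         n_agree = cnt[cbind(seq_len(period), top_idx)],
         n_total = n_total),
    class = "tm_repeat_consensus"
  )
}

#' Fold a set of rolling-circle reads
#'
#' Detects periods ([detect_period()]) and folds every read
#' ([fold_consensus()]); reads of equal length, exact repeat multiple and
#' constant quality go through a vectorised vote. Reads with no detectable
#' period or failing the fold filters are tallied.
#'
#' @param reads A read tibble (tagged dialect).
#' @inheritParams detect_period
#' @inheritParams fold_consensus
#' @return A folded tibble: `read_id`, `cell_barcode`, `umi`,
#'   `transcript_id`, `start`, `period`, `n_repeats`, `consensus`,
#'   `n_masked`; attribute `rejections` tallies dropped reads.
#' @export
fold_reads <- function(reads, min_period, max_period,
                       max_mismatch_frac = 0.1, min_repeats = 3,
                       max_masked_frac = 0.2) {
  rej <- c(no_period = 0L, too_few_repeats = 0L, too_masked = 0L)
  out <- empty_folded()
  if (nrow(reads) == 0L) {
    attr(out, "rejections") <- rej
    return(out)
  }
  period <- detect_periods(reads$sequence, min_period, max_period,
                           max_mismatch_frac, min_repeats)
  rej[["no_period"]] <- sum(is.na(period))
  keep <- !is.na(period)
  reads <- reads[keep, ]
  period <- period[keep]

  lens <- nchar(reads$sequence)
  const_q <- vapply(seq_len(nrow(reads)), function(i) {
    qs <- reads$qualities[i]
    qs == strrep(substr(qs, 1, 1), nchar(qs))
  }, logical(1))
  fastable <- lens %% period == 0L & const_q

  res <- vector("list", 2L)
  if (any(fastable)) {
    fr <- reads[fastable, ]
    fp <- period[fastable]
    blocks <- split(seq_len(nrow(fr)), paste0(nchar(fr$sequence), "_", fp))
    parts <- lapply(blocks, function(i) {
      L <- nchar(fr$sequence[i[1]])
      p <- fp[i[1]]
      r <- L %/% p
      bytes <- charToRaw(paste0(fr$sequence[i], collapse = ""))
      dim(bytes) <- c(p, r * length(i))
      v <- fold_columns(bytes, r, length(i))
      tibble::tibble(row = i, period = p, n_repeats = r,
                     consensus = v$consensus, n_masked = v$n_masked)
    })
    fa <- dplyr::bind_rows(parts)
    drop <- fa$n_masked / fa$period > max_masked_frac
    rej[["too_masked"]] <- rej[["too_masked"]] + sum(drop)
    fa <- fa[!drop, ]
    res[[1]] <- tibble::tibble(
      read_id = fr$read_id[fa$row], cell_barcode = fr$cell_barcode[fa$row],
      umi = fr$umi[fa$row], transcript_id = fr$transcript_id[fa$row],
      start = fr$start[fa$row], period = fa$period,
      n_repeats = fa$n_repeats, consensus = fa$consensus,
      n_masked = fa$n_masked)
  }
  if (any(!fastable)) {
    sr <- reads[!fastable, ]
    sp <- period[!fastable]
    fc <- lapply(seq_len(nrow(sr)), function(i) {
      fold_consensus(sr$sequence[i], sr$qualities[i], sp[i],
                     min_repeats = min_repeats,
                     max_masked_frac = max_masked_frac)
    })
    is_rej <- vapply(fc, inherits, logical(1), "tm_rejected")
    for (r in fc[is_rej]) rej[[r$reason]] <- rej[[r$reason]] + 1L
    ok <- which(!is_rej)
    if (length(ok)) {
      res[[2]] <- tibble::tibble(
        read_id = sr$read_id[ok], cell_barcode = sr$cell_barcode[ok],
        umi = sr$umi[ok], transcript_id = sr$transcript_id[ok],
        start = sr$start[ok],
        period = vapply(fc[ok], `[[`, integer(1), "period"),
        n_repeats = vapply(fc[ok], `[[`, integer(1), "n_repeats"),
        consensus = vapply(fc[ok], `[[`, character(1), "consensus"),
        n_masked = vapply(fc[ok], function(x)
          sum(strsplit(x$consensus, "")[[1]] == "N"), integer(1)))
    }
  }
  out <- dplyr::bind_rows(res)
  if (sum(rej) > 0) {
    inform(paste0("fold_reads: rejected ",
                  paste0(names(rej)[rej > 0], "=", rej[rej > 0],
                         collapse = ", ")))
  }
  attr(out, "rejections") <- rej
  out
}

# Count-based plurality for exact-multiple, constant-quality reads: with a
# constant Phred weight the quality-weighted vote reduces to counts, and the
# mask rule top*q < 2*runner*q to top < 2*runner.
fold_columns <- function(bytes, r, nf) {
  p <- nrow(bytes)
  cnt <- vector("list", 4L)
  for (b in 1:4) {
    acc <- matrix(0L, nrow = p, ncol = nf)
    eq <- bytes == RAW_BASES[b]
    dim(eq) <- c(p, r * nf)
    for (j in seq_len(r)) {
      acc <- acc + eq[, seq.int(j, by = r, length.out = nf), drop = FALSE]
    }
    cnt[[b]] <- acc
  }
  top <- cnt[[1]]
  idx <- matrix(1L, nrow = p, ncol = nf)
  for (b in 2:4) {
    better <- cnt[[b]] > top
    top[better] <- cnt[[b]][better]
    idx[better] <- b
  }
  runner <- matrix(-1L, nrow = p, ncol = nf)
  for (b in 1:4) {
    cand <- cnt[[b]]
    cand[idx == b] <- -1L
    runner <- pmax(runner, cand)
  }
  mask <- top < 2L * runner
  cons_bytes <- RAW_BASES[idx]
  cons_bytes[mask] <- RAW_N
  dim(cons_bytes) <- dim(idx)
  all_str <- rawToChar(as.vector(cons_bytes))
  list(consensus = substring(all_str, (seq_len(nf) - 1L) * p + 1L,
                             seq_len(nf) * p),
       n_masked = as.integer(colSums(mask)))
}

empty_folded <- function() {
  tibble::tibble(read_id = character(), cell_barcode = character(),
                 umi = character(), transcript_id = character(),
                 start = integer(), period = integer(),
                 n_repeats = integer(), consensus = character(),
                 n_masked = integer())
}

#' Bulk error rates from folded CirSeq consensi
#'
#' Compares repeat consensi to the reference (the simulator dialect carries
#' the fragment mapping; externally aligned data would enter through the
#' same columns) and estimates the overall N>N error rate plus the 12-type
#' breakdown. Bulk data has no cell structure, so the DNA-mutation
#' exclusion uses the pooled >= `mut_frac_threshold` fraction rule per site.
#'
#' @param folded Folded tibble from [fold_reads()].
#' @param reference Reference tibble.
#' @param sample_id Sample label.
#' @param mut_frac_threshold,min_mut_coverage Passed to [classify_sites()].
#' @return A `tm_spectrum` (see [error_spectrum()]); the overall rate is
#'   available via [overall_error_rate()] / [glance()].
#' @export
cirseq_error_rate <- function(folded, reference, sample_id = "cirseq",
                              mut_frac_threshold = 0.95,
                              min_mut_coverage = 10) {
  mols <- tibble::tibble(
    cell_barcode = folded$cell_barcode,
    umi = folded$umi,
    transcript_id = folded$transcript_id,
    start = folded$start,
    length = folded$period,
    consensus = folded$consensus,
    family_size = folded$n_repeats,
    n_masked = folded$n_masked
  )
  calls <- call_discrepancies(mols, reference)
  calls <- classify_sites(calls, mut_frac_threshold, min_mut_coverage)
  error_spectrum(calls, mols, reference, sample_id = sample_id)
}
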