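# Brute-force oracles, written independently of the package internals:
# everything here works on character matrices via strsplit and explicit
# loops, so agreement with the vectorised implementations is meaningful.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Column-wise majority vote over same-extent reads; unanimity/majority and
# tie-masking semantics as documented for build_consensus().
oracle_consensus <- function(sequences, min_agreement = 1) {
  m <- do.call(rbind, lapply(sequences, chars))
  k <- nrow(m)
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    votes <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    top <- max(votes)
    winners <- names(votes)[votes == top]
    out[j] <- if (length(winners) > 1L || top < min_agreement * k) {
      "N"
    } else {
      winners
    }
  }
  paste(out, collapse = "")
}

# Exhaustive per-cell, per-position tally of mutant and reference-matching
# molecules, skipping masked (N) bases.
oracle_tally <- function(molecules, reference) {
  ref_chars <- lapply(setNames(reference$sequence, reference$transcript_id),
                      chars)
  rows <- list()
  for (i in seq_len(nrow(molecules))) {
    cc <- chars(molecules$consensus[i])
    rc <- ref_chars[[molecules$transcript_id[i]]]
    for (j in seq_along(cc)) {
      pos <- molecules$start[i] + j - 1L
      rb <- rc[pos + 1L]
      if (cc[j] == "N" || cc[j] == rb) next
      key <- paste(molecules$cell_barcode[i], molecules$transcript_id[i],
                   pos, cc[j], sep = "|")
      rows[[key]] <- (rows[[key]] %||% 0L) + 1L
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(cell_barcode = character(),
                          transcript_id = character(), position = integer(),
                          ref_base = character(), alt_base = character(),
                          n_mut = integer(), n_wt = integer()))
  }
  parts <- strsplit(names(rows), "|", fixed = TRUE)
  out <- tibble::tibble(
    cell_barcode = vapply(parts, `[`, "", 1),
    transcript_id = vapply(parts, `[`, "", 2),
    position = as.integer(vapply(parts, `[`, "", 3)),
    alt_base = vapply(parts, `[`, "", 4),
    n_mut = unname(unlist(rows))
  )
  out$ref_base <- vapply(seq_len(nrow(out)), function(i) {
    ref_chars[[out$transcript_id[i]]][out$position[i] + 1L]
  }, character(1))
  out$n_wt <- vapply(seq_len(nrow(out)), function(i) {
    n <- 0L
    for (m in seq_len(nrow(molecules))) {
      if (molecules$cell_barcode[m] != out$cell_barcode[i]) next
      if (molecules$transcript_id[m] != out$transcript_id[i]) next
      j <- out$position[i] - molecules$start[m] + 1L
      if (j < 1L || j > nchar(molecules$consensus[m])) next
      if (chars(molecules$consensus[m])[j] == out$ref_base[i]) n <- n + 1L
    }
    n
  }, integer(1))
  out[order(out$cell_barcode, out$transcript_id, out$position,
            out$alt_base), c("cell_barcode", "transcript_id", "position",
                             "ref_base", "alt_base", "n_mut", "n_wt")]
}

# Brute-force scan over every candidate period.
oracle_period <- function(sequence, min_period, max_period,
                          max_mismatch_frac = 0.1, min_repeats = 3) {
  x <- chars(sequence)
  L <- length(x)
  if (L < 2 * min_period) return(NA_integer_)
  best <- NA_integer_
  best_f <- Inf
  for (p in min_period:min(max_period, L - 1L)) {
    if (L %/% p < min_repeats) next
    f <- mean(x[1:(L - p)] != x[(p + 1):L])
    if (f <= max_mismatch_frac && f < best_f) {
      best <- p
      best_f <- f
    }
  }
  best
}

# Column-by-column quality-weighted vote for repeat folding.
oracle_fold <- function(sequence, qualities, period) {
  x <- chars(sequence)
  q <- as.integer(charToRaw(qualities)) - 33L
  out <- character(period)
  for (j in seq_len(period)) {
    pos <- seq(j, length(x), by = period)
    w <- tapply(q[pos], factor(x[pos], levels = c("A", "C", "G", "T")), sum)
    w[is.na(w)] <- 0
    top <- names(w)[which.max(w)]
    runner <- max(w[names(w) != top])
    out[j] <- if (w[top] < 2 * runner) "N" else top
  }
  paste(out, collapse = "")
}

# Textbook pooled-variance two-sample t, two-tailed.
oracle_pooled_t <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * pt(-abs(t), df = nx + ny - 2)
  list(statistic = t, p_value = p)
}

# Exact per-column outcome distribution for folding r copies with per-copy
# error e (wrong base uniform over the other three), constant qualities:
# returns P(consensus base is wrong | column unmasked) and P(masked).
oracle_fold_column_probs <- function(e, r = 3) {
  states <- as.matrix(expand.grid(rep(list(0:3), r)))  # 0 correct, 1:3 wrong
  p_wrong <- 0
  p_mask <- 0
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    pr <- prod(ifelse(s == 0, 1 - e, e / 3))
    votes <- tabulate(s + 1L, nbins = 4L)
    top <- max(votes)
    winners <- which(votes == top)
    runner <- if (length(winners) > 1L) top else max(votes[-winners[1]], 0L)
    if (length(winners) > 1L || top < 2 * runner) {
      p_mask <- p_mask + pr
    } else if (winners[1] != 1L) {
      p_wrong <- p_wrong + pr
    }
  }
  list(p_wrong_given_unmasked = p_wrong / (1 - p_mask), p_mask = p_mask)
}

# Shared chain used by recovery-style tests: the package's standard
# simulate -> collapse -> call -> classify -> spectrum route.
run_spectrum <- function(reference, config, sample_id = "s",
                         min_reads = 2, min_agreement = 1) {
  sim <- sim_reads(reference, config)
  mols <- suppressMessages(collapse_families(sim$reads,
                                             min_reads = min_reads,
                                             min_agreement = min_agreement))
  calls <- classify_sites(call_discrepancies(mols, reference))
  error_spectrum(calls, mols, reference, sample_id = sample_id)
}

rate_of <- function(spectrum, label = "C>U") {
  spectrum$rate[spectrum$substitution == label]
}

random_reference <- function(n = 3, len = 40, seed = NULL) {
  make_reference(n, len, seed = seed)
}
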