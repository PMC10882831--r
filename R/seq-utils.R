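# Internal byte/string helpers shared by the simulator, consensus and calling
# stages. Sequences are plain character strings over {A,C,G,T,N}; U is stored
# as T and only rendered as U in substitution labels.

DNA_BASES <- c("A", "C", "G", "T")

# 4 x 3 matrix: row i = the three bases other than DNA_BASES[i]
OTHER_BASES <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b),
                        character(3)))

base_index <- function(base) match(base, DNA_BASES)

#' Render a substitution in RNA space
#'
#' Transcripts are stored in DNA letters (U as T); reporting renders T as U so
#' a C-to-T discrepancy reads as the C-to-U transcription error it represents.
#'
#' @param ref_base,alt_base Character vectors of single bases.
#' @return Character vector of labels such as `"C>U"`.
#' @export
substitution_label <- function(ref_base, alt_base) {
  paste0(chartr("T", "U", ref_base), ">", chartr("T", "U", alt_base))
}

# The 12 ordered substitution types, as a tibble skeleton
substitution_types <- function() {
  grid <- expand.grid(ref_base = DNA_BASES, alt_base = DNA_BASES,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref_base != grid$alt_base, , drop = FALSE]
  grid <- grid[order(grid$ref_base, grid$alt_base), , drop = FALSE]
  tibble::tibble(
    ref_base = grid$ref_base,
    alt_base = grid$alt_base,
    substitution = substitution_label(grid$ref_base, grid$alt_base)
  )
}

# Random DNA strings, vectorised: n strings of length len
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
}

# Unique random DNA strings (barcodes); resamples collisions deterministically
random_dna_unique <- function(n, len) {
  if (4^len < n) {
    abort(sprintf("Cannot draw %d unique barcodes of length %d", n, len))
  }
  out <- random_dna(n, len)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- random_dna(length(dup), len)
  }
  out
}

# Apply single-base substitutions to strings[idx] at 1-based position pos.
# Multiple edits per string are applied in successive vectorised rounds.
apply_substitutions <- function(strings, idx, pos, alt) {
  if (length(idx) == 0L) return(strings)
  ord <- order(idx, pos)
  idx <- idx[ord]; pos <- pos[ord]; alt <- alt[ord]
  round_no <- stats::ave(idx, idx, FUN = seq_along)
  for (r in seq_len(max(round_no))) {
    sel <- round_no == r
    i <- idx[sel]
    s <- strings[i]
    substr(s, pos[sel], pos[sel]) <- alt[sel]
    strings[i] <- s
  }
  strings
}

# Per-transcript cumulative base counts. Returns, for one sequence, a list of
# four integer vectors c0..cL where c[p+1] = count of that base in seq[1..p].
base_prefix_counts <- function(sequence) {
  bytes <- charToRaw(sequence)
  lapply(DNA_BASES, function(b) {
    c(0L, cumsum(bytes == charToRaw(b)))
  })
}

# 0-based positions of a given base within a sequence
base_positions0 <- function(sequence, base) {
  which(charToRaw(sequence) == charToRaw(base)) - 1L
}

# Phred score (integer) to the FASTQ quality character
phred_char <- function(q) rawToChar(as.raw(q + 33L))
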