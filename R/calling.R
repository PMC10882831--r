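# RNA-DNA discrepancy calling against reference transcripts, DNA-mutation
# exclusion, and the 12-type substitution error spectrum.
#
# All counts are molecule (UMI-family) counts, never raw reads. Substitution
# types are kept in transcript space: transcripts are single-stranded, so
# C>U and G>A are distinct signals and are never collapsed by complement --
# that asymmetry is exactly what separates a lesion from a DNA mutation.

# Scan consensus molecules against the reference. Returns every position
# where the consensus differs from the reference, including masked (N)
# positions. Memory-bounded by chunking the minority of differing molecules.
scan_mismatches <- function(molecules, reference) {
  ref <- validate_reference(reference)
  ti <- match(molecules$transcript_id, ref$transcript_id)
  if (anyNA(ti)) {
    abort("Molecule names a transcript absent from the reference.")
  }
  if (any(molecules$start < 0L |
          molecules$start + molecules$length > ref$length[ti])) {
    abort("Molecule extends past the reference end (coordinate bug).")
  }
  empty <- tibble::tibble(molecule_row = integer(), position = integer(),
                          ref_base = character(), alt_base = character())
  if (nrow(molecules) == 0L) return(empty)

  full <- molecules$start == 0L & molecules$length == ref$length[ti]
  refs <- character(nrow(molecules))
  refs[full] <- ref$sequence[ti[full]]
  if (any(!full)) {
    refs[!full] <- substring(ref$sequence[ti[!full]],
                             molecules$start[!full] + 1L,
                             molecules$start[!full] + molecules$length[!full])
  }
  mm <- cpp_mismatch_scan(molecules$consensus, refs)
  tibble::tibble(
    molecule_row = mm$row,
    position = as.integer(molecules$start[mm$row] + mm$pos - 1L),
    ref_base = mm$ref_base,
    alt_base = mm$alt_base
  )
}

# Number of molecules covering each site (including masked molecules).
# sites: tibble with transcript_id, position and, if by_cell, cell_barcode.
site_coverage <- function(molecules, sites, by_cell = TRUE) {
  if (nrow(sites) == 0L) return(integer(0))
  grp <- if (by_cell) c("cell_barcode", "transcript_id") else "transcript_id"
  mg <- molecules |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      .starts = list(sort(.data$start)),
      .ends = list(sort(.data$start + .data$length)),
      .groups = "drop")
  s2 <- dplyr::left_join(sites, mg, by = grp)
  vapply(seq_len(nrow(s2)), function(i) {
    st <- s2$.starts[[i]]
    if (is.null(st)) return(0L)
    p <- s2$position[i]
    findInterval(p, st) - findInterval(p, s2$.ends[[i]])
  }, integer(1))
}

#' Call per-cell RNA-DNA discrepancies
#'
#' Compares every consensus molecule to its reference transcript and emits
#' one record per (cell, transcript, position, alternate base) observed in
#' at least one molecule. `n_mut` counts mutant molecules; `n_wt` counts the
#' co-located molecules of the same cell that match the reference at that
#' position (masked molecules are excluded from both). Molecules from
#' different cells are never merged. Masked (`N`) consensus positions are
#' skipped and returned as the `masked` attribute for denominator
#' bookkeeping.
#'
#' @param molecules Molecule tibble from [collapse_families()].
#' @param reference A reference tibble.
#' @return A call tibble: `cell_barcode`, `transcript_id`, `position`
#'   (0-based), `ref_base`, `alt_base`, `n_mut`, `n_wt`, with attribute
#'   `masked` (per-molecule masked positions and their reference base).
#' @examples
#' ref <- reference_set("tx1", "ACGT")
#' mols <- tibble::tibble(
#'   cell_barcode = "c1", umi = c("u1", "u2", "u3"), transcript_id = "tx1",
#'   start = 0L, length = 4L, consensus = c("ACGT", "ACGT", "ACTT"),
#'   family_size = 2L, n_masked = 0L)
#' call_discrepancies(mols, ref)   # one call: position 2, G>T, 1 vs 2
#' @export
call_discrepancies <- function(molecules, reference) {
  mm <- scan_mismatches(molecules, reference)
  mk <- mm[mm$alt_base == "N", ]
  masked <- tibble::tibble(
    cell_barcode = molecules$cell_barcode[mk$molecule_row],
    transcript_id = molecules$transcript_id[mk$molecule_row],
    position = mk$position,
    ref_base = mk$ref_base
  )
  mut <- mm[mm$alt_base != "N", ]
  calls <- tibble::tibble(
    cell_barcode = molecules$cell_barcode[mut$molecule_row],
    transcript_id = molecules$transcript_id[mut$molecule_row],
    position = mut$position,
    ref_base = mut$ref_base,
    alt_base = mut$alt_base
  ) |>
    dplyr::count(.data$cell_barcode, .data$transcript_id, .data$position,
                 .data$ref_base, .data$alt_base, name = "n_mut")

  if (nrow(calls)) {
    sites <- dplyr::distinct(calls, .data$cell_barcode, .data$transcript_id,
                             .data$position)
    sites$coverage <- site_coverage(molecules, sites, by_cell = TRUE)
    masked_n <- masked |>
      dplyr::count(.data$cell_barcode, .data$transcript_id, .data$position,
                   name = "n_masked_mol")
    mut_n <- calls |>
      dplyr::group_by(.data$cell_barcode, .data$transcript_id,
                      .data$position) |>
      dplyr::summarise(total_mut = sum(.data$n_mut), .groups = "drop")
    sites <- sites |>
      dplyr::left_join(masked_n,
                       by = c("cell_barcode", "transcript_id", "position")) |>
      dplyr::left_join(mut_n,
                       by = c("cell_barcode", "transcript_id", "position")) |>
      dplyr::mutate(
        n_wt = .data$coverage -
          dplyr::coalesce(.data$n_masked_mol, 0L) - .data$total_mut)
    calls <- dplyr::left_join(
      calls, sites[c("cell_barcode", "transcript_id", "position", "n_wt")],
      by = c("cell_barcode", "transcript_id", "position"))
  } else {
    calls$n_wt <- integer(0)
  }
  attr(calls, "masked") <- masked
  calls
}

#' Classify called sites as transcription errors or candidate DNA mutations
#'
#' Pools each (transcript, position, alternate base) site across cells: a
#' site whose pooled mutant fraction reaches `mut_frac_threshold` with
#' pooled coverage of at least `min_mut_coverage` molecules is a
#' `candidate_dna_mutation` (in quiescent cells a true DNA mutation yields
#' ~100 percent mutant transcripts); everything else is a `transcription_error`.
#' Candidate mutations are later removed entirely -- numerator and
#' denominator -- from the error spectrum.
#'
#' @param calls A call tibble from [call_discrepancies()].
#' @param mut_frac_threshold Pooled mutant fraction at or above which a site
#'   is a candidate DNA mutation (default 0.95).
#' @param min_mut_coverage Minimum pooled coverage (mutant + wild-type
#'   molecules) to support a mutation call (default 10).
#' @return `calls` with a `classification` column (attributes preserved).
#' @export
classify_sites <- function(calls, mut_frac_threshold = 0.95,
                           min_mut_coverage = 10) {
  masked <- attr(calls, "masked")
  if (nrow(calls) == 0L) {
    calls$classification <- character(0)
    attr(calls, "masked") <- masked
    return(calls)
  }
  pooled <- calls |>
    dplyr::group_by(.data$transcript_id, .data$position, .data$alt_base) |>
    dplyr::summarise(pooled_mut = sum(.data$n_mut),
                     pooled_cov = sum(.data$n_mut + .data$n_wt),
                     .groups = "drop") |>
    dplyr::mutate(
      classification = dplyr::if_else(
        .data$pooled_mut / .data$pooled_cov >= mut_frac_threshold &
          .data$pooled_cov >= min_mut_coverage,
        "candidate_dna_mutation", "transcription_error"))
  out <- dplyr::left_join(
    calls, pooled[c("transcript_id", "position", "alt_base",
                    "classification")],
    by = c("transcript_id", "position", "alt_base"))
  attr(out, "masked") <- masked
  out
}

#' Estimate the 12-type substitution error spectrum
#'
#' For each ordered substitution X>Y the rate is the number of erroneous
#' molecule bases (the `n_mut` sum over transcription-error calls with that
#' type) divided by the number of surveyed consensus-molecule bases whose
#' reference base is X. Masked positions and candidate-DNA-mutation sites
#' are excluded from numerator and denominator. A type whose denominator is
#' zero gets rate `NA` (undefined, distinct from 0) with a warning.
#'
#' @param calls Classified call tibble (see [classify_sites()]).
#' @param molecules The molecule tibble the calls were derived from.
#' @param reference The reference tibble.
#' @param sample_id Sample label stored in the output.
#' @param unit `"molecule"` (default) counts erroneous molecules in the
#'   numerator -- an estimate of errors per transcription event;
#'   `"site"` counts distinct error records instead.
#' @return A tibble of class `tm_spectrum` with 12 rows: `sample_id`,
#'   `ref_base`, `alt_base`, `substitution` (RNA-space label), `n_errors`,
#'   `n_surveyed`, `rate`. Attributes `total_bases`, `masked_bases` and
#'   `excluded_bases` support conservation checks.
#' @export
error_spectrum <- function(calls, molecules, reference,
                           sample_id = "sample",
                           unit = c("molecule", "site")) {
  unit <- match.arg(unit)
  if (nrow(calls) > 0L && is.null(calls$classification)) {
    abort("Calls must be classified first; see `classify_sites()`.")
  }
  ref <- validate_reference(reference)
  ti <- match(molecules$transcript_id, ref$transcript_id)

  # per-ref-base totals over all unmasked consensus bases
  total_x <- setNames(numeric(4), DNA_BASES)
  if (nrow(molecules)) {
    tx_off <- cumsum(c(0L, ref$length + 1L))
    for (b in DNA_BASES) {
      cb <- unlist(lapply(ref$sequence, function(s) {
        c(0L, cumsum(charToRaw(s) == charToRaw(b)))
      }), use.names = FALSE)
      total_x[b] <- sum(as.numeric(
        cb[tx_off[ti] + molecules$start + molecules$length + 1L] -
          cb[tx_off[ti] + molecules$start + 1L]))
    }
  }

  masked <- attr(calls, "masked")
  if (is.null(masked)) {
    mm <- scan_mismatches(molecules, reference)
    masked <- mm[mm$alt_base == "N", ]
    masked$cell_barcode <- molecules$cell_barcode[masked$molecule_row]
    masked$transcript_id <- molecules$transcript_id[masked$molecule_row]
  }
  masked_x <- setNames(numeric(4), DNA_BASES)
  if (nrow(masked)) {
    tb <- table(masked$ref_base)
    masked_x[names(tb)] <- as.numeric(tb)
  }

  excluded_x <- setNames(numeric(4), DNA_BASES)
  excluded_bases <- 0
  if (nrow(calls)) {
    excl <- calls |>
      dplyr::filter(.data$classification == "candidate_dna_mutation") |>
      dplyr::distinct(.data$transcript_id, .data$position, .data$ref_base)
    if (nrow(excl)) {
      cov <- site_coverage(molecules, excl, by_cell = FALSE)
      masked_at <- vapply(seq_len(nrow(excl)), function(i) {
        sum(masked$transcript_id == excl$transcript_id[i] &
              masked$position == excl$position[i])
      }, numeric(1))
      unmasked_cov <- cov - masked_at
      for (b in DNA_BASES) {
        excluded_x[b] <- sum(unmasked_cov[excl$ref_base == b])
      }
      excluded_bases <- sum(unmasked_cov)
    }
  }

  surveyed_x <- total_x - masked_x - excluded_x

  num <- substitution_types()
  if (nrow(calls)) {
    te <- calls[calls$classification == "transcription_error", ]
    agg <- te |>
      dplyr::group_by(.data$ref_base, .data$alt_base) |>
      dplyr::summarise(
        n_errors = if (unit == "molecule") sum(.data$n_mut) else dplyr::n(),
        .groups = "drop")
    num <- dplyr::left_join(num, agg, by = c("ref_base", "alt_base"))
    num$n_errors <- dplyr::coalesce(num$n_errors, 0L)
  } else {
    num$n_errors <- 0L
  }
  num$n_surveyed <- unname(surveyed_x[num$ref_base])
  num$rate <- ifelse(num$n_surveyed > 0, num$n_errors / num$n_surveyed,
                     NA_real_)
  if (any(num$n_surveyed == 0)) {
    warn(paste0("error_spectrum: no surveyed bases for reference base(s) ",
                paste(unique(num$ref_base[num$n_surveyed == 0]),
                      collapse = ", "),
                "; their rates are undefined (NA)."))
  }
  out <- tibble::tibble(sample_id = sample_id, num)
  class(out) <- c("tm_spectrum", class(out))
  attr(out, "total_bases") <- sum(total_x)
  attr(out, "masked_bases") <- sum(masked_x)
  attr(out, "excluded_bases") <- excluded_bases
  out
}

#' Overall error rate of a spectrum
#'
#' The overall (N>N) rate: all erroneous molecule bases over all surveyed
#' bases, regardless of substitution type.
#'
#' @param spectrum A `tm_spectrum`.
#' @return A single rate (errors per surveyed base).
#' @export
overall_error_rate <- function(spectrum) {
  per_ref <- spectrum[!duplicated(spectrum$ref_base), ]
  sum(spectrum$n_errors) / sum(per_ref$n_surveyed)
}

#' @export
glance.tm_spectrum <- function(x, ...) {
  per_ref <- x[!duplicated(x$ref_base), ]
  tibble::tibble(
    sample_id = x$sample_id[1],
    n_errors = sum(x$n_errors),
    n_surveyed = sum(per_ref$n_surveyed),
    overall_rate = overall_error_rate(x)
  )
}

#' @export
tidy.tm_spectrum <- function(x, ...) {
  tibble::as_tibble(x)
}
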