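#' Pseudo-allele detection from per-cell mutant:WT molecule ratios
#'
#' A pseudo-allele is a site in one cell whose transcript pool contains both
#' wild-type and identically mutant molecules: an unrepaired lesion on one
#' allele produces recurrent miscoding, mimicking a heterozygous DNA
#' mutation. Following the convention of reporting only alleles with more
#' than 10 percent mutant mRNAs, a (cell, site, alternate base) is included iff
#' its mutant fraction strictly exceeds `min_fraction`, it has at least
#' `min_mut_molecules` mutant molecules (a lone molecule cannot establish
#' recurrence), and total coverage is at least `min_total_molecules` so the
#' fraction is meaningful.
#'
#' @param calls Classified call tibble restricted to transcription errors
#'   (rows classified `candidate_dna_mutation` are dropped; unclassified
#'   calls are accepted as-is).
#' @param min_fraction Strict lower bound on the mutant fraction
#'   (default 0.10, i.e. "more than 10 percent mutant mRNAs").
#' @param min_mut_molecules Minimum mutant molecule count (default 2).
#' @param min_total_molecules Minimum coverage `n_mut + n_wt` (default 10).
#' @return A tibble sorted by decreasing `mutant_fraction`: `cell_barcode`,
#'   `transcript_id`, `position`, `ref_base`, `alt_base`, `n_mut`, `n_wt`,
#'   `mutant_fraction`.
#' @examples
#' calls <- tibble::tibble(
#'   cell_barcode = "c1", transcript_id = "tx1", position = c(5L, 9L),
#'   ref_base = "C", alt_base = "T", n_mut = c(6L, 1L), n_wt = c(6L, 19L))
#' compute_pseudo_alleles(calls)   # 6/6 kept at 0.5; 1/19 excluded
#' @export
compute_pseudo_alleles <- function(calls, min_fraction = 0.10,
                                   min_mut_molecules = 2,
                                   min_total_molecules = 10) {
  if (!is.null(calls$classification)) {
    calls <- calls[calls$classification == "transcription_error", ]
  }
  out <- calls |>
    dplyr::mutate(mutant_fraction =
                    .data$n_mut / (.data$n_mut + .data$n_wt)) |>
    dplyr::filter(.data$mutant_fraction > min_fraction,
                  .data$n_mut >= min_mut_molecules,
                  .data$n_mut + .data$n_wt >= min_total_molecules) |>
    dplyr::arrange(dplyr::desc(.data$mutant_fraction))
  out[c("cell_barcode", "transcript_id", "position", "ref_base", "alt_base",
        "n_mut", "n_wt", "mutant_fraction")]
}

#' Histogram of pseudo-allele mutant:WT ratios
#'
#' Bins mutant fractions into fixed width-0.05 bins over (0.10, 1.00],
#' mirroring the mutant:WT ratio plot of the single-cell analysis.
#'
#' @param pseudo_alleles Output of [compute_pseudo_alleles()].
#' @return A tibble with one row per bin: `bin_low`, `bin_high`, `bin`
#'   (label) and `n`; counts sum to the number of pseudo-alleles.
#' @export
ratio_histogram <- function(pseudo_alleles) {
  breaks <- seq(0.10, 1.00, by = 0.05)
  lo <- head(breaks, -1)
  hi <- tail(breaks, -1)
  idx <- findInterval(pseudo_alleles$mutant_fraction, breaks,
                      left.open = TRUE, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= length(lo)]
  tibble::tibble(
    bin_low = lo,
    bin_high = hi,
    bin = sprintf("(%.2f,%.2f]", lo, hi),
    n = tabulate(idx, nbins = length(lo))
  )
}
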