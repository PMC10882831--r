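#' Reference transcript sets
#'
#' A reference set is a tibble with columns `transcript_id` and `sequence`
#' (DNA letters `A`, `C`, `G`, `T`; RNA `U` is stored as `T`). All
#' RNA-DNA discrepancies are defined against these sequences. Coordinates are
#' 0-based, half-open throughout the package.
#'
#' @param transcript_id Character vector of unique transcript names.
#' @param sequence Character vector of non-empty `ACGT` sequences.
#' @return A validated reference tibble with columns `transcript_id`,
#'   `sequence` and `length`.
#' @examples
#' reference_set(c("tx1", "tx2"), c("ACGTACGT", "GGGCCCAA"))
#' @export
reference_set <- function(transcript_id, sequence) {
  ref <- tibble::tibble(
    transcript_id = as.character(transcript_id),
    sequence = toupper(as.character(sequence))
  )
  validate_reference(ref)
}

#' @rdname reference_set
#' @param reference A reference tibble (or named character vector of
#'   sequences) to validate.
#' @export
validate_reference <- function(reference) {
  if (is.character(reference)) {
    reference <- tibble::tibble(
      transcript_id = names(reference) %||% paste0("tx", seq_along(reference)),
      sequence = unname(reference)
    )
  }
  if (!all(c("transcript_id", "sequence") %in% names(reference))) {
    abort("A reference set needs `transcript_id` and `sequence` columns.")
  }
  if (nrow(reference) == 0L) abort("Reference set is empty.")
  if (anyDuplicated(reference$transcript_id)) {
    abort("Reference transcript ids must be unique.")
  }
  if (any(is.na(reference$sequence)) || any(nchar(reference$sequence) == 0L)) {
    abort("Reference sequences must be non-empty.")
  }
  if (any(grepl("[^ACGT]", reference$sequence))) {
    abort("Reference sequences may only contain A, C, G, T (store U as T).")
  }
  dplyr::mutate(tibble::as_tibble(reference)[c("transcript_id", "sequence")],
                length = nchar(.data$sequence))
}

#' Generate a random reference transcriptome
#'
#' Draws transcript sequences with independent uniform base composition
#' (25 percent C, close to the mammalian transcriptome average), giving the
#' simulator a neutral substrate with a known C content.
#'
#' @param n_transcripts Number of transcripts.
#' @param length Length of each transcript in bases (recycled).
#' @param seed Optional integer seed for reproducibility.
#' @return A reference tibble (see [reference_set()]).
#' @export
make_reference <- function(n_transcripts = 30, length = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- rep_len(as.integer(length), n_transcripts)
  seqs <- vapply(len, function(L) rawToChar(as.raw(
    sample(utf8ToInt("A") + c(0L, 2L, 6L, 19L), L, replace = TRUE))),
    character(1))
  reference_set(sprintf("tx%03d", seq_len(n_transcripts)), seqs)
}

#' Read a reference set from a FASTA file
#'
#' @param path Path to a (possibly multi-line) FASTA file.
#' @return A reference tibble (see [reference_set()]).
#' @export
read_reference_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readDNAStringSet(path)
    return(reference_set(names(s), as.character(s)))
  }
  lines <- readr::read_lines(path)
  hdr <- grepl("^>", lines)
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)[!hdr]
  seqs <- vapply(split(lines[!hdr], grp), paste0, character(1), collapse = "")
  reference_set(id, seqs)
}

#' Write a reference set to FASTA
#'
#' @param reference A reference tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  reference <- validate_reference(reference)
  readr::write_lines(
    paste0(">", reference$transcript_id, "\n", reference$sequence), path)
  invisible(path)
}
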