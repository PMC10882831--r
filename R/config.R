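#' Simulation configuration
#'
#' Bundles every parameter of the forward simulator. The generative model,
#' per cell: each transcript yields a Poisson number of mRNA molecules; a
#' molecule is a fragment of the reference transcript (the whole transcript
#' when `fragment_length` is `NULL`). Molecule sequences then accumulate, in
#' order: DNA mutations (always penetrant in the carrier cell), lesion-driven
#' miscoding (recurrent per cell at lesion sites on one allele),
#' substitution-specific molecule-level errors (`molecule_error_rates`), and
#' uniform background transcription errors. Each molecule is amplified
#' through a binary PCR duplication tree and sequenced as a UMI-sharing read
#' family with independent per-read sequencing errors.
#'
#' @param n_cells Number of cells (must be >= 1).
#' @param molecules_per_cell_per_transcript Poisson mean number of molecules
#'   each cell produces per transcript.
#' @param reads_per_molecule Mean reads per molecule; family sizes are drawn
#'   as `reads_min + Poisson(reads_per_molecule - reads_min)`.
#' @param reads_min Minimum reads per molecule (default 2, the smallest
#'   family that supports a consensus).
#' @param fragment_length Molecule fragment length in bases; `NULL` means
#'   every molecule spans its whole transcript.
#' @param lesion_site_rate Per-cell probability that a transcript base whose
#'   reference base is `lesion_ref_base` carries a DNA lesion on one allele.
#' @param lesion_miscoding_prob Probability that a transcript drawn from the
#'   lesioned allele carries the cognate error at the lesion site.
#' @param lesion_ref_base,lesion_alt_base The substitution a lesion induces
#'   on the transcript; default C>T, i.e. the C>U miscoding of
#'   O6-methylguanine on the template strand.
#' @param lesioned_allele_fraction Fraction of a lesion site's transcripts
#'   drawn from the lesioned allele (default 0.5: diploid, one allele hit).
#' @param dna_mutation_sites Data frame of true DNA mutations with columns
#'   `cell` (1-based cell index), `transcript_id`, `position` (0-based) and
#'   `alt_base`; every transcript of that cell covering the site carries the
#'   alternate base.
#' @param molecule_error_rates Data frame with columns `ref_base`, `alt_base`
#'   and `rate`: substitution-specific transcription-error probabilities per
#'   matching reference base per molecule, independent across molecules.
#'   Models the aggregate molecule-level miscoding rate of a condition
#'   without imposing per-cell site structure.
#' @param background_tx_error_rate Per-base probability of a stochastic
#'   transcription error on a molecule; the alternate base is uniform over
#'   the three non-template bases.
#' @param pcr_error_rate Per-base, per-duplication polymerase error
#'   probability (high-fidelity default 1e-7).
#' @param pcr_cycles Depth of the binary PCR duplication tree.
#' @param seq_error_rate Per-base, per-read sequencing error probability.
#' @param umi_length,barcode_length Lengths of the UMI and cell barcode.
#' @param quality_phred Constant Phred score written for every base.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `tm_sim_config`.
#' @export
sim_config <- function(n_cells = 50,
                       molecules_per_cell_per_transcript = 10,
                       reads_per_molecule = 2.2,
                       reads_min = 2,
                       fragment_length = NULL,
                       lesion_site_rate = 0,
                       lesion_miscoding_prob = 1,
                       lesion_ref_base = "C",
                       lesion_alt_base = "T",
                       lesioned_allele_fraction = 0.5,
                       dna_mutation_sites = NULL,
                       molecule_error_rates = NULL,
                       background_tx_error_rate = 0,
                       pcr_error_rate = 1e-7,
                       pcr_cycles = 12,
                       seq_error_rate = 1e-3,
                       umi_length = 10,
                       barcode_length = 16,
                       quality_phred = 37,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells),
    molecules_per_cell_per_transcript = molecules_per_cell_per_transcript,
    reads_per_molecule = reads_per_molecule,
    reads_min = as.integer(reads_min),
    fragment_length = if (!is.null(fragment_length)) as.integer(fragment_length),
    lesion_site_rate = lesion_site_rate,
    lesion_miscoding_prob = lesion_miscoding_prob,
    lesion_ref_base = lesion_ref_base,
    lesion_alt_base = lesion_alt_base,
    lesioned_allele_fraction = lesioned_allele_fraction,
    dna_mutation_sites = if (!is.null(dna_mutation_sites))
      tibble::as_tibble(dna_mutation_sites),
    molecule_error_rates = if (!is.null(molecule_error_rates))
      tibble::as_tibble(molecule_error_rates),
    background_tx_error_rate = background_tx_error_rate,
    pcr_error_rate = pcr_error_rate,
    pcr_cycles = as.integer(pcr_cycles),
    seq_error_rate = seq_error_rate,
    umi_length = as.integer(umi_length),
    barcode_length = as.integer(barcode_length),
    quality_phred = as.integer(quality_phred),
    seed = as.integer(seed)
  )
  class(cfg) <- "tm_sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config A `tm_sim_config` to validate.
#' @export
validate_sim_config <- function(config) {
  probs <- c("lesion_site_rate", "lesion_miscoding_prob",
             "lesioned_allele_fraction", "background_tx_error_rate",
             "pcr_error_rate", "seq_error_rate")
  for (p in probs) {
    v <- config[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single probability in [0, 1].", p))
    }
  }
  if (config$n_cells < 1L) abort("`n_cells` must be at least 1.")
  if (config$reads_min < 1L) abort("`reads_min` must be at least 1.")
  if (config$reads_per_molecule < config$reads_min) {
    abort("`reads_per_molecule` must be >= `reads_min`.")
  }
  if (!config$lesion_ref_base %in% DNA_BASES ||
      !config$lesion_alt_base %in% DNA_BASES) {
    abort("Lesion bases must be one of A, C, G, T.")
  }
  if (config$lesion_ref_base == config$lesion_alt_base) {
    abort("`lesion_alt_base` must differ from `lesion_ref_base`.")
  }
  mer <- config$molecule_error_rates
  if (!is.null(mer)) {
    stopifnot(all(c("ref_base", "alt_base", "rate") %in% names(mer)))
    if (any(mer$rate < 0 | mer$rate > 1)) {
      abort("`molecule_error_rates$rate` must lie in [0, 1].")
    }
    if (any(mer$ref_base == mer$alt_base)) {
      abort("`molecule_error_rates` must have ref_base != alt_base.")
    }
  }
  dms <- config$dna_mutation_sites
  if (!is.null(dms) && nrow(dms) > 0) {
    stopifnot(all(c("cell", "transcript_id", "position", "alt_base")
                  %in% names(dms)))
  }
  config
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A `tm_sim_config`.
#' @param path File path.
#' @return `path` (write) or a validated `tm_sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$dna_mutation_sites <- if (!is.null(x$dna_mutation_sites))
    as.list(as.data.frame(x$dna_mutation_sites))
  x$molecule_error_rates <- if (!is.null(x$molecule_error_rates))
    as.list(as.data.frame(x$molecule_error_rates))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$dna_mutation_sites)) {
    x$dna_mutation_sites <- tibble::as_tibble(x$dna_mutation_sites)
  }
  if (!is.null(x$molecule_error_rates)) {
    x$molecule_error_rates <- tibble::as_tibble(x$molecule_error_rates)
  }
  do.call(sim_config, x)
}

#' @export
print.tm_sim_config <- function(x, ...) {
  cat("<tm_sim_config>\n")
  flat <- x[!vapply(x, is.data.frame, logical(1))]
  flat <- flat[!vapply(flat, is.null, logical(1))]
  cat(paste0("  ", names(flat), ": ", unlist(lapply(flat, format)),
             collapse = "\n"), "\n")
  if (!is.null(x$dna_mutation_sites)) {
    cat("  dna_mutation_sites:", nrow(x$dna_mutation_sites), "site(s)\n")
  }
  if (!is.null(x$molecule_error_rates)) {
    cat("  molecule_error_rates:", nrow(x$molecule_error_rates), "type(s)\n")
  }
  invisible(x)
}
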