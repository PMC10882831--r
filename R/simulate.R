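# Forward simulator for UMI+barcode-tagged single-cell reads.
#
# Errors are applied sparsely: a molecule or read sequence is only
# materialised as a new string when an event actually touches it, so
# error-free reads share the reference string in memory. Event positions are
# sampled by drawing a binomial count over the total base space and placing
# events uniformly, which is equivalent to independent per-base Bernoulli
# draws.

#' Simulate barcoded, UMI-tagged single-cell reads
#'
#' Forward-simulates the full observation chain: per-cell Poisson molecule
#' counts per transcript, DNA mutations (fully penetrant in quiescent cells),
#' recurrent lesion-driven miscoding on one allele, substitution-specific and
#' uniform background transcription errors, PCR errors on a binary
#' duplication tree, and independent per-read sequencing errors. Reads from
#' one molecule share a UMI and extent.
#'
#' @param reference A reference tibble (see [reference_set()]).
#' @param config A [sim_config()].
#' @return A list of class `tm_simulation` with elements
#'   \describe{
#'     \item{reads}{tibble: `read_id`, `cell_barcode`, `umi`,
#'       `transcript_id`, `start` (0-based), `sequence`, `qualities`.}
#'     \item{truth}{ground-truth tibble: `cell_id`, `transcript_id`,
#'       `position` (0-based), `kind` (`lesion` / `dna_mutation`),
#'       `ref_base`, `alt_base`, `expected_mutant_fraction`.}
#'     \item{molecules}{tibble of simulated molecules with `n_reads`, for
#'       conservation checks.}
#'     \item{variants}{molecule-level variant events actually applied
#'       (`molecule`, `transcript_id`, `position`, `alt_base`, `origin`).}
#'   }
#' @examples
#' ref <- make_reference(2, 60, seed = 1)
#' sim <- sim_reads(ref, sim_config(n_cells = 3, seed = 1,
#'                                  seq_error_rate = 0, pcr_error_rate = 0))
#' sim$reads
#' @export
sim_reads <- function(reference, config) {
  reference <- validate_reference(reference)
  config <- validate_sim_config(config)
  set.seed(config$seed)

  n_tx <- nrow(reference)
  tx_len <- reference$length
  tx_ids <- reference$transcript_id
  seqs <- reference$sequence

  barcodes <- random_dna_unique(config$n_cells, config$barcode_length)

  ## molecules ----------------------------------------------------------
  n_ct <- rpois(config$n_cells * n_tx, config$molecules_per_cell_per_transcript)
  mol_cell <- rep(rep(seq_len(config$n_cells), each = n_tx), n_ct)
  mol_tx <- rep(rep.int(seq_len(n_tx), config$n_cells), n_ct)
  n_mol <- length(mol_cell)
  if (n_mol == 0L) {
    return(empty_simulation(config))
  }
  frag <- config$fragment_length
  if (is.null(frag)) {
    mol_start <- integer(n_mol)
    mol_len <- tx_len[mol_tx]
  } else {
    if (any(tx_len < frag)) {
      abort("`fragment_length` exceeds the shortest reference transcript.")
    }
    mol_start <- as.integer(floor(runif(n_mol) * (tx_len[mol_tx] - frag + 1L)))
    mol_len <- rep.int(as.integer(frag), n_mol)
  }
  umi <- random_dna(n_mol, config$umi_length)

  mol_tbl <- tibble::tibble(
    molecule = seq_len(n_mol), cell = mol_cell, tx = mol_tx,
    start = mol_start, len = mol_len
  )

  ## molecule-level variants --------------------------------------------
  mv <- list()   # each: tibble(molecule, position (0-based, transcript), alt_base, origin)
  truth <- list()

  dms <- config$dna_mutation_sites
  if (!is.null(dms) && nrow(dms) > 0L) {
    dms_tx <- match(dms$transcript_id, tx_ids)
    if (anyNA(dms_tx)) abort("dna_mutation_sites names an unknown transcript.")
    if (any(dms$position < 0L | dms$position >= tx_len[dms_tx])) {
      abort("dna_mutation_sites position outside transcript bounds.")
    }
    ref_at <- substr(seqs[dms_tx], dms$position + 1L, dms$position + 1L)
    truth[["dna"]] <- tibble::tibble(
      cell_id = barcodes[dms$cell], transcript_id = dms$transcript_id,
      position = as.integer(dms$position), kind = "dna_mutation",
      ref_base = ref_at, alt_base = dms$alt_base,
      expected_mutant_fraction = 1
    )
    hit <- dplyr::inner_join(
      mol_tbl,
      tibble::tibble(cell = as.integer(dms$cell), tx = dms_tx,
                     position = as.integer(dms$position), alt_base = dms$alt_base),
      by = c("cell", "tx"), relationship = "many-to-many"
    )
    hit <- hit[hit$position >= hit$start & hit$position < hit$start + hit$len, ]
    if (nrow(hit)) {
      mv[["dna"]] <- tibble::tibble(
        molecule = hit$molecule, position = hit$position,
        alt_base = hit$alt_base, origin = "dna_mutation"
      )
    }
  }

  if (config$lesion_site_rate > 0) {
    lrb <- config$lesion_ref_base
    pos_by_tx <- lapply(seqs, base_positions0, lrb)
    pos_flat <- unlist(pos_by_tx, use.names = FALSE)
    n_pos <- lengths(pos_by_tx)
    per_cell <- sum(n_pos)
    n_les <- rbinom(1L, config$n_cells * per_cell, config$lesion_site_rate)
    if (n_les > 0L) {
      pick <- sample.int(config$n_cells * per_cell, n_les)
      cellv <- (pick - 1L) %/% per_cell + 1L
      w <- (pick - 1L) %% per_cell + 1L
      cum <- cumsum(n_pos)
      txv <- findInterval(w - 0.5, c(0L, cum))
      posv <- pos_flat[w]
      emf <- config$lesioned_allele_fraction * config$lesion_miscoding_prob
      truth[["lesion"]] <- tibble::tibble(
        cell_id = barcodes[cellv], transcript_id = tx_ids[txv],
        position = posv, kind = "lesion",
        ref_base = lrb, alt_base = config$lesion_alt_base,
        expected_mutant_fraction = emf
      )
      hit <- dplyr::inner_join(
        mol_tbl,
        tibble::tibble(cell = cellv, tx = txv, position = posv),
        by = c("cell", "tx"), relationship = "many-to-many"
      )
      hit <- hit[hit$position >= hit$start & hit$position < hit$start + hit$len, ]
      if (nrow(hit)) {
        # a molecule comes from the lesioned allele w.p. lesioned_allele_fraction
        # and then miscodes w.p. lesion_miscoding_prob
        mut <- runif(nrow(hit)) < emf
        hit <- hit[mut, ]
      }
      if (nrow(hit)) {
        mv[["lesion"]] <- tibble::tibble(
          molecule = hit$molecule, position = hit$position,
          alt_base = config$lesion_alt_base, origin = "lesion"
        )
      }
    }
  }

  # flattened per-base prefix-count tables, built lazily per ref base
  cum_cache <- new.env(parent = emptyenv())
  tx_off <- cumsum(c(0L, tx_len + 1L))   # offsets into flattened (L+1) cumsums
  flat_cum <- function(b) {
    if (is.null(cum_cache[[b]])) {
      cum_cache[[b]] <- unlist(lapply(seqs, function(s) {
        c(0L, cumsum(charToRaw(s) == charToRaw(b)))
      }), use.names = FALSE)
    }
    cum_cache[[b]]
  }
  pos_cache <- new.env(parent = emptyenv())
  flat_pos <- function(b) {   # 0-based positions of base b, flattened
    if (is.null(pos_cache[[b]])) {
      pb <- lapply(seqs, base_positions0, b)
      pos_cache[[b]] <- list(pos = unlist(pb, use.names = FALSE),
                             off = cumsum(c(0L, lengths(pb))))
    }
    pos_cache[[b]]
  }

  mer <- config$molecule_error_rates
  if (!is.null(mer) && nrow(mer) > 0L) {
    for (i in seq_len(nrow(mer))) {
      b <- mer$ref_base[i]
      cb <- flat_cum(b)
      before <- cb[tx_off[mol_tx] + mol_start + 1L]
      n_b <- cb[tx_off[mol_tx] + mol_start + mol_len + 1L] - before
      total <- sum(as.numeric(n_b))
      if (total == 0) next
      n_ev <- rbinom(1L, total, mer$rate[i])
      if (n_ev == 0L) next
      g <- sample.int(total, n_ev)
      cs <- cumsum(as.numeric(n_b))
      m <- findInterval(g - 0.5, c(0, cs))
      j <- g - c(0, cs)[m]
      fp <- flat_pos(b)
      posv <- fp$pos[fp$off[mol_tx[m]] + before[m] + j]
      mv[[paste0("mer", i)]] <- tibble::tibble(
        molecule = m, position = posv,
        alt_base = mer$alt_base[i], origin = "molecule_error"
      )
    }
  }

  if (config$background_tx_error_rate > 0) {
    total <- sum(as.numeric(mol_len))
    n_ev <- rbinom(1L, total, config$background_tx_error_rate)
    if (n_ev > 0L) {
      g <- sample.int(total, n_ev)
      cs <- cumsum(as.numeric(mol_len))
      m <- findInterval(g - 0.5, c(0, cs))
      posv <- mol_start[m] + (g - c(0, cs)[m]) - 1L
      refb <- substr(seqs[mol_tx[m]], posv + 1L, posv + 1L)
      altv <- OTHER_BASES[cbind(base_index(refb), sample.int(3L, n_ev, TRUE))]
      mv[["background"]] <- tibble::tibble(
        molecule = m, position = as.integer(posv),
        alt_base = altv, origin = "background"
      )
    }
  }

  mv <- if (length(mv)) dplyr::bind_rows(mv) else
    tibble::tibble(molecule = integer(), position = integer(),
                   alt_base = character(), origin = character())
  if (nrow(mv)) {
    # precedence at a coinciding (molecule, position): DNA mutation, then
    # lesion, then injected/background transcription error
    pri <- match(mv$origin,
                 c("dna_mutation", "lesion", "molecule_error", "background"))
    key <- (mv$molecule - 1) * (max(tx_len) + 1) + mv$position
    ord <- order(pri)
    mv <- mv[ord, ][!duplicated(key[ord]), ]
  }

  ## reads ---------------------------------------------------------------
  k <- config$reads_min +
    rpois(n_mol, config$reads_per_molecule - config$reads_min)
  n_reads <- sum(k)
  read_mol <- rep.int(seq_len(n_mol), k)
  read_first <- cumsum(k) - k + 1L   # first read index of each molecule

  mv_key <- (mv$molecule - 1) * (max(tx_len) + 1) + mv$position

  pcr <- tibble::tibble(read = integer(), position = integer(),
                        alt_base = character())
  if (config$pcr_error_rate > 0 && config$pcr_cycles > 0L) {
    leaf <- floor(runif(n_reads) * 2^config$pcr_cycles)
    slots <- as.numeric(config$pcr_cycles) * as.numeric(mol_len[read_mol])
    total <- sum(slots)
    n_ev <- rbinom(1L, total, config$pcr_error_rate)
    if (n_ev > 0L) {
      g <- sample(total, n_ev)
      cs <- cumsum(slots)
      rd <- findInterval(g - 0.5, c(0, cs))
      w <- g - c(0, cs)[rd]
      len_rd <- mol_len[read_mol[rd]]
      depth <- as.integer((w - 1) %/% len_rd) + 1L
      posr <- as.integer((w - 1) %% len_rd) + 1L   # 1-based within molecule
      out <- vector("list", n_ev)
      for (e in seq_len(n_ev)) {
        m <- read_mol[rd[e]]
        fam <- seq.int(read_first[m], length.out = k[m])
        shift <- 2^(config$pcr_cycles - depth[e])
        anc <- leaf[rd[e]] %/% shift
        sharers <- fam[leaf[fam] %/% shift == anc]
        # thinning: the same tree edge can be reached through each sharing
        # read's path slots, so accept with probability 1/n_sharers to
        # recover the per-edge error rate exactly
        if (runif(1) > 1 / length(sharers)) next
        pos0 <- mol_start[m] + posr[e] - 1L
        cur <- substr(seqs[mol_tx[m]], pos0 + 1L, pos0 + 1L)
        hit <- match((m - 1) * (max(tx_len) + 1) + pos0, mv_key)
        if (!is.na(hit)) cur <- mv$alt_base[hit]
        altv <- OTHER_BASES[base_index(cur), sample.int(3L, 1L)]
        out[[e]] <- tibble::tibble(read = sharers, position = posr[e],
                                   alt_base = altv)
      }
      pcr <- dplyr::bind_rows(out)
    }
  }

  se <- tibble::tibble(read = integer(), position = integer(),
                       alt_base = character())
  if (config$seq_error_rate > 0) {
    len_rd_all <- mol_len[read_mol]
    total <- sum(as.numeric(len_rd_all))
    n_ev <- rbinom(1L, total, config$seq_error_rate)
    if (n_ev > 0L) {
      g <- sample.int(total, n_ev)
      cs <- cumsum(as.numeric(len_rd_all))
      rd <- findInterval(g - 0.5, c(0, cs))
      posr <- as.integer(g - c(0, cs)[rd])         # 1-based within molecule
      m <- read_mol[rd]
      pos0 <- mol_start[m] + posr - 1L
      cur <- substr(seqs[mol_tx[m]], pos0 + 1L, pos0 + 1L)
      hit <- match((m - 1) * (max(tx_len) + 1) + pos0, mv_key)
      cur[!is.na(hit)] <- mv$alt_base[hit[!is.na(hit)]]
      if (nrow(pcr)) {
        pk <- match(paste0(rd, "_", posr),
                    paste0(pcr$read, "_", pcr$position))
        cur[!is.na(pk)] <- pcr$alt_base[pk[!is.na(pk)]]
      }
      se <- tibble::tibble(
        read = rd, position = posr,
        alt_base = OTHER_BASES[cbind(base_index(cur),
                                     sample.int(3L, n_ev, TRUE))]
      )
    }
  }

  ## materialise strings --------------------------------------------------
  if (is.null(frag)) {
    mol_seq <- seqs[mol_tx]            # shared, copy-on-write
  } else {
    mol_seq <- substring(seqs[mol_tx], mol_start + 1L, mol_start + mol_len)
  }
  if (nrow(mv)) {
    mol_seq <- apply_substitutions(
      mol_seq, mv$molecule, mv$position - mol_start[mv$molecule] + 1L,
      mv$alt_base)
  }
  read_seq <- mol_seq[read_mol]
  rv <- dplyr::bind_rows(pcr, se)
  if (nrow(rv)) {
    read_seq <- apply_substitutions(read_seq, rv$read, rv$position,
                                    rv$alt_base)
  }

  qch <- phred_char(config$quality_phred)
  ulen <- sort(unique(mol_len))
  qual_by_len <- strrep(qch, ulen)
  qualities <- qual_by_len[match(mol_len[read_mol], ulen)]

  reads <- tibble::tibble(
    read_id = paste0("r", seq_len(n_reads)),
    cell_barcode = barcodes[mol_cell[read_mol]],
    umi = umi[read_mol],
    transcript_id = tx_ids[mol_tx[read_mol]],
    start = mol_start[read_mol],
    sequence = read_seq,
    qualities = qualities
  )

  truth <- if (length(truth)) {
    dplyr::arrange(dplyr::bind_rows(truth), .data$cell_id,
                   .data$transcript_id, .data$position)
  } else {
    tibble::tibble(cell_id = character(), transcript_id = character(),
                   position = integer(), kind = character(),
                   ref_base = character(), alt_base = character(),
                   expected_mutant_fraction = numeric())
  }

  molecules <- tibble::tibble(
    molecule = seq_len(n_mol),
    cell_barcode = barcodes[mol_cell],
    umi = umi,
    transcript_id = tx_ids[mol_tx],
    start = mol_start,
    length = mol_len,
    n_reads = k
  )

  variants <- tibble::tibble(
    molecule = mv$molecule,
    cell_barcode = barcodes[mol_cell[mv$molecule]],
    transcript_id = tx_ids[mol_tx[mv$molecule]],
    position = as.integer(mv$position),
    alt_base = mv$alt_base,
    origin = mv$origin
  )

  structure(
    list(reads = reads, truth = truth, molecules = molecules,
         variants = variants, config = config),
    class = "tm_simulation"
  )
}

empty_simulation <- function(config) {
  structure(
    list(
      reads = tibble::tibble(read_id = character(), cell_barcode = character(),
                             umi = character(), transcript_id = character(),
                             start = integer(), sequence = character(),
                             qualities = character()),
      truth = tibble::tibble(cell_id = character(), transcript_id = character(),
                             position = integer(), kind = character(),
                             ref_base = character(), alt_base = character(),
                             expected_mutant_fraction = numeric()),
      molecules = tibble::tibble(molecule = integer(),
                                 cell_barcode = character(), umi = character(),
                                 transcript_id = character(), start = integer(),
                                 length = integer(), n_reads = integer()),
      variants = tibble::tibble(molecule = integer(), cell_barcode = character(),
                                transcript_id = character(),
                                position = integer(), alt_base = character(),
                                origin = character()),
      config = config),
    class = "tm_simulation"
  )
}

#' @export
print.tm_simulation <- function(x, ...) {
  cat("<tm_simulation>\n")
  cat("  reads:    ", nrow(x$reads), "\n")
  cat("  molecules:", nrow(x$molecules), "\n")
  cat("  truth:    ", nrow(x$truth), "event(s)\n")
  invisible(x)
}

#' Simulate single-cell reads and write them to FASTQ
#'
#' Runs [sim_reads()] and writes the reads in the package's tagged FASTQ
#' dialect plus the ground-truth table as TSV.
#'
#' @inheritParams sim_reads
#' @param out_dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, a list with `fastq`, `truth_path` and the
#'   `tm_simulation` object.
#' @export
simulate_cells <- function(reference, config, out_dir = tempdir(),
                           prefix = "sim") {
  sim <- sim_reads(reference, config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fastq <- file.path(out_dir, paste0(prefix, ".fastq"))
  truth_path <- file.path(out_dir, paste0(prefix, "_truth.tsv"))
  write_tagged_fastq(sim$reads, fastq)
  write_tm_tsv(sim$truth, truth_path,
               comment = "ground truth; position is 0-based")
  invisible(list(fastq = fastq, truth_path = truth_path, sim = sim))
}
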