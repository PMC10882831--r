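mk_mols <- function(consensus, cb = "c1", tx = "tx1", start = 0L,
                    fam = 2L) {
  tibble::tibble(
    cell_barcode = rep_len(cb, length(consensus)),
    umi = paste0("u", seq_along(consensus)),
    transcript_id = rep_len(tx, length(consensus)),
    start = rep_len(as.integer(start), length(consensus)),
    length = nchar(consensus),
    consensus = consensus,
    family_size = rep_len(fam, length(consensus)),
    n_masked = vapply(strsplit(consensus, ""), function(x)
      sum(x == "N"), integer(1))
  )
}

test_that("reference-matching molecules produce no calls", {
  ref <- reference_set("tx1", "ACGTACGT")
  calls <- call_discrepancies(mk_mols(rep("ACGTACGT", 5)), ref)
  expect_equal(nrow(calls), 0L)
})

test_that("a hand-counted site tallies mutant and wild-type molecules", {
  ref <- reference_set("tx1", "ACCGT")
  calls <- call_discrepancies(mk_mols(c("ACCGT", "ACCGT", "ATCGT")), ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 1L)
  expect_equal(calls$ref_base, "C")
  expect_equal(calls$alt_base, "T")
  expect_equal(calls$n_mut, 1L)
  expect_equal(calls$n_wt, 2L)
})

test_that("masked positions are skipped and excluded from n_wt", {
  ref <- reference_set("tx1", "ACCGT")
  calls <- call_discrepancies(mk_mols(c("ACCGT", "ANCGT", "ATCGT")), ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_mut, 1L)
  expect_equal(calls$n_wt, 1L)       # the N molecule counts for neither side
  expect_equal(nrow(attr(calls, "masked")), 1L)
})

test_that("a molecule past the reference end is a hard error", {
  ref <- reference_set("tx1", "ACGT")
  bad <- mk_mols("ACGTA")
  expect_error(call_discrepancies(bad, ref), "coordinate")
  expect_error(call_discrepancies(mk_mols("ACGT", tx = "zzz"), ref),
               "absent")
})

test_that("calls equal the brute-force tally on randomized molecule sets", {
  set.seed(4415)
  for (case in 1:100) {
    ref <- random_reference(2, 25)
    n <- 20
    tx <- sample(ref$transcript_id, n, TRUE)
    start <- sample(0:10, n, TRUE)
    len <- sample(5:15, n, TRUE)
    consensus <- vapply(seq_len(n), function(i) {
      s <- substr(ref$sequence[ref$transcript_id == tx[i]], start[i] + 1L,
                  start[i] + len[i])
      x <- strsplit(s, "")[[1]]
      hits <- which(runif(length(x)) < 0.1)
      x[hits] <- sample(c("A", "C", "G", "T", "N"), length(hits), TRUE)
      paste(x, collapse = "")
    }, character(1))
    mols <- tibble::tibble(
      cell_barcode = sample(c("c1", "c2"), n, TRUE),
      umi = paste0("u", seq_len(n)),
      transcript_id = tx, start = start, length = len,
      consensus = consensus, family_size = 2L,
      n_masked = vapply(strsplit(consensus, ""), function(x)
        sum(x == "N"), integer(1)))
    got <- call_discrepancies(mols, ref) |>
      dplyr::arrange(.data$cell_barcode, .data$transcript_id,
                     .data$position, .data$alt_base)
    attr(got, "masked") <- NULL
    want <- oracle_tally(mols, ref)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("site classification separates mutations from lesion-like sites", {
  base <- tibble::tibble(
    cell_barcode = c("c1", "c2"), transcript_id = "tx1", position = 5L,
    ref_base = "G", alt_base = "A")
  # pooled 12/12 mutant molecules -> candidate DNA mutation
  full <- dplyr::mutate(base, n_mut = c(7L, 5L), n_wt = 0L)
  expect_equal(unique(classify_sites(full)$classification),
               "candidate_dna_mutation")
  # 50:50 lesion regime stays a transcription error
  half <- dplyr::mutate(base, n_mut = c(3L, 3L), n_wt = c(3L, 3L))
  expect_equal(unique(classify_sites(half)$classification),
               "transcription_error")
  # full mutant fraction but below the coverage floor: not enough evidence
  thin <- dplyr::mutate(base[1, ], n_mut = 3L, n_wt = 0L)
  expect_equal(classify_sites(thin)$classification, "transcription_error")
})

test_that("spectrum arithmetic matches the defining ratio", {
  ref <- reference_set("tx1", strrep("C", 100))
  mols <- mk_mols(rep(strrep("C", 100), 100))   # 10,000 surveyed C bases
  mols$consensus[1] <- paste0("T", strrep("C", 99))
  calls <- classify_sites(call_discrepancies(mols, ref))
  spec <- suppressWarnings(error_spectrum(calls, mols, ref))
  expect_equal(spec$rate[spec$substitution == "C>U"], 1e-4)
  expect_equal(spec$n_surveyed[spec$substitution == "C>U"], 1e4)
  # no A/G/T bases were surveyed: undefined, not zero
  expect_true(is.na(spec$rate[spec$substitution == "A>C"]))
  expect_warning(error_spectrum(calls, mols, ref), "undefined")
})

test_that("candidate DNA mutations contribute nothing to the spectrum", {
  # a clonal mutation: every molecule of every cell carries the alternate
  ref <- reference_set("tx1", "GGGGGGGGGG")
  mut <- paste0("A", strrep("G", 9))
  mols <- dplyr::bind_rows(mk_mols(rep(mut, 12), cb = "c1"),
                           mk_mols(rep(mut, 8), cb = "c2"))
  calls <- classify_sites(call_discrepancies(mols, ref))
  expect_equal(unique(calls$classification), "candidate_dna_mutation")
  spec <- suppressWarnings(error_spectrum(calls, mols, ref))
  expect_equal(sum(spec$n_errors), 0L)
  # the whole site leaves the denominator too
  expect_equal(spec$n_surveyed[spec$ref_base == "G"][1],
               20 * 10 - 20)
})

test_that("denominator bookkeeping conserves every consensus base", {
  ref <- make_reference(4, 120, seed = 31)
  cfg <- sim_config(n_cells = 8, molecules_per_cell_per_transcript = 12,
                    seq_error_rate = 5e-3,
                    background_tx_error_rate = 1e-3,
                    dna_mutation_sites = data.frame(
                      cell = 1:2, transcript_id = "tx001",
                      position = c(30, 60), alt_base = "A"),
                    seed = 41)
  sim <- sim_reads(ref, cfg)
  mols <- suppressMessages(collapse_families(sim$reads))
  calls <- classify_sites(call_discrepancies(mols, ref))
  spec <- error_spectrum(calls, mols, ref)
  per_ref <- spec[!duplicated(spec$ref_base), ]
  expect_equal(
    sum(per_ref$n_surveyed) + attr(spec, "masked_bases") +
      attr(spec, "excluded_bases"),
    sum(mols$length))
  expect_equal(attr(spec, "total_bases"), sum(mols$length))
})

test_that("injected C>U errors are recovered without bias at both study scales", {
  ref <- make_reference(10, 400, seed = 51)
  for (target in c(6.9e-5, 6.7e-6)) {
    rates <- vapply(1:10, function(s) {
      cfg <- sim_config(n_cells = 10,
                        molecules_per_cell_per_transcript = 100,
                        molecule_error_rates = data.frame(
                          ref_base = "C", alt_base = "T", rate = target),
                        seed = s)
      rate_of(run_spectrum(ref, cfg), "C>U")
    }, numeric(1))
    # analytic standard error of the mean over 10 seeds of ~1e6 C bases
    c_bases <- 10 * 100 * 10 * 400 * 0.25
    se <- sqrt(target / (10 * c_bases))
    expect_lt(abs(mean(rates) - target), 3 * se)
  }
})
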