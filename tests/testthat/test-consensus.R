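mk_reads <- function(seqs, cb = "c1", umi = "u1", tx = "tx1", start = 0L) {
  tibble::tibble(
    read_id = paste0("r", seq_along(seqs)),
    cell_barcode = rep_len(cb, length(seqs)),
    umi = rep_len(umi, length(seqs)),
    transcript_id = rep_len(tx, length(seqs)),
    start = rep_len(start, length(seqs)),
    sequence = seqs,
    qualities = strrep("F", nchar(seqs))
  )
}

test_that("family grouping partitions reads on the exact (CB, UMI, TX) key", {
  reads <- dplyr::bind_rows(
    mk_reads(rep("ACGT", 4), cb = "c1", umi = "u1"),
    mk_reads(rep("ACGT", 2), cb = "c2", umi = "u1"))
  fams <- group_families(reads)
  expect_equal(nrow(fams), 2L)             # same UMI, two cells: two families
  expect_equal(sum(fams$n_reads), 6L)

  empty <- group_families(mk_reads(character(0)))
  expect_equal(nrow(empty), 0L)

  reads$umi[1] <- NA
  expect_message(fams2 <- group_families(reads), "dropped 1")
  expect_equal(sum(fams2$n_reads), 5L)
})

test_that("unanimity consensus masks disagreements and keeps support counts", {
  fam <- mk_reads(rep("ACGTACGT", 3))
  cons <- build_consensus(fam)
  expect_equal(cons$consensus, "ACGTACGT")
  expect_equal(cons$n_agree, rep(3L, 8))
  expect_equal(cons$n_total, 3L)

  fam2 <- mk_reads(c("ACGTACGT", "ACGAACGT"))
  cons2 <- build_consensus(fam2)
  expect_equal(cons2$consensus, "ACGNACGT")

  expect_equal(build_consensus(fam2[1, ])$reason, "small_family")
  fam3 <- fam2
  fam3$transcript_id <- c("tx1", "tx2")
  expect_equal(build_consensus(fam3)$reason, "chimeric_family")
})

test_that("mixed-extent families are trimmed to the covered intersection", {
  fam <- mk_reads(c("AACCGGTT", "ACCGGTTA"), start = c(0L, 1L))
  cons <- build_consensus(fam)
  expect_equal(cons$start, 1L)
  expect_equal(cons$consensus, "ACCGGTT")

  apart <- mk_reads(c("AAAA", "CCCC"), start = c(0L, 100L))
  expect_equal(build_consensus(apart)$reason, "no_overlap")
})

test_that("collapse matches the brute-force column vote on random families", {
  set.seed(1203)
  for (case in 1:100) {
    k <- sample(2:5, 1)
    L <- sample(5:30, 1)
    base <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    seqs <- rep(base, k)
    # inject per-read errors at rate 0.05 to force disagreements
    for (i in seq_len(k)) {
      hits <- which(runif(L) < 0.05)
      if (length(hits)) {
        s <- strsplit(seqs[i], "")[[1]]
        s[hits] <- sample(c("A", "C", "G", "T"), length(hits), TRUE)
        seqs[i] <- paste(s, collapse = "")
      }
    }
    agreement <- sample(c(1, 0.6, 0.5), 1)
    expected <- oracle_consensus(seqs, min_agreement = agreement)
    got <- build_consensus(mk_reads(seqs), min_agreement = agreement)
    expect_equal(got$consensus, expected)
    bulk <- suppressMessages(
      collapse_families(mk_reads(seqs), min_agreement = agreement))
    expect_equal(bulk$consensus, expected)
    expect_equal(bulk$n_masked,
                 sum(strsplit(expected, "")[[1]] == "N"))
  }
})

test_that("collapse is invariant to read order and rejects small families", {
  ref <- make_reference(3, 60, seed = 8)
  sim <- sim_reads(ref, sim_config(n_cells = 6,
                                   molecules_per_cell_per_transcript = 5,
                                   seq_error_rate = 0.01, seed = 13))
  mols <- suppressMessages(collapse_families(sim$reads))
  perm <- sim$reads[sample.int(nrow(sim$reads)), ]
  mols_perm <- suppressMessages(collapse_families(perm))
  key <- function(m) dplyr::arrange(m, .data$cell_barcode, .data$umi,
                                    .data$transcript_id)
  expect_equal(key(mols), key(mols_perm))

  # singleton families are rejected and tallied
  one <- mk_reads("ACGT")
  out <- collapse_families(one)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "rejections")[["small_family"]], 1L)
})

test_that("two independent sequencing errors must coincide to survive collapse", {
  # with unanimity over >=2 reads a miscalled consensus base needs the same
  # wrong base at the same position in every read: expectation e^2/3 per
  # 2-read family base; at this scale the expected count is < 1
  ref <- make_reference(10, 400, seed = 15)
  cfg <- sim_config(n_cells = 10, molecules_per_cell_per_transcript = 50,
                    reads_per_molecule = 2, reads_min = 2,
                    background_tx_error_rate = 0, pcr_error_rate = 0,
                    seq_error_rate = 1e-3, seed = 77)
  sim <- sim_reads(ref, cfg)
  mols <- suppressMessages(collapse_families(sim$reads))
  calls <- call_discrepancies(mols, ref)
  lambda <- sum(mols$length) * (1e-3)^2 / 3
  expect_lt(lambda, 1)
  # P(X > 4 | lambda < 1) < 0.004: a real artifact leak would blow past this
  expect_lte(sum(calls$n_mut), 4)
})
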