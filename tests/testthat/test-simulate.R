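quiet_cfg <- function(...) {
  sim_config(background_tx_error_rate = 0, pcr_error_rate = 0,
             seq_error_rate = 0, ...)
}

test_that("with all rates zero every read is an exact reference substring", {
  ref <- make_reference(3, 80, seed = 1)
  sim <- sim_reads(ref, quiet_cfg(n_cells = 5,
                                  molecules_per_cell_per_transcript = 4,
                                  fragment_length = 30, seed = 2))
  expect_gt(nrow(sim$reads), 0)
  hits <- vapply(seq_len(nrow(sim$reads)), function(i) {
    tx <- ref$sequence[ref$transcript_id == sim$reads$transcript_id[i]]
    substr(tx, sim$reads$start[i] + 1L, sim$reads$start[i] + 30L) ==
      sim$reads$sequence[i]
  }, logical(1))
  expect_true(all(hits))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("a DNA mutation is fully penetrant in its carrier cell", {
  ref <- make_reference(2, 60, seed = 3)
  cfg <- quiet_cfg(
    n_cells = 4, molecules_per_cell_per_transcript = 10, seed = 5,
    dna_mutation_sites = data.frame(cell = 2, transcript_id = "tx001",
                                    position = 10, alt_base = "A"))
  sim <- sim_reads(ref, cfg)
  expect_equal(sim$truth$kind, "dna_mutation")
  expect_equal(sim$truth$expected_mutant_fraction, 1)
  carrier <- sim$truth$cell_id
  covering <- sim$reads$transcript_id == "tx001"
  base_at <- substr(sim$reads$sequence[covering],
                    11 - sim$reads$start[covering],
                    11 - sim$reads$start[covering])
  in_carrier <- sim$reads$cell_barcode[covering] == carrier
  expect_true(all(base_at[in_carrier] == "A"))
  expect_true(all(base_at[!in_carrier] != "A"))
})

test_that("simulation is byte-identical under a fixed seed", {
  ref <- make_reference(3, 60, seed = 1)
  cfg <- sim_config(n_cells = 6, molecules_per_cell_per_transcript = 5,
                    background_tx_error_rate = 1e-3, seq_error_rate = 1e-3,
                    lesion_site_rate = 1e-3, pcr_error_rate = 1e-4,
                    seed = 11)
  s1 <- sim_reads(ref, cfg)
  s2 <- sim_reads(ref, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- simulate_cells(ref, cfg, out_dir = d1)$fastq
  f2 <- simulate_cells(ref, cfg, out_dir = d2)$fastq
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("read counts are conserved across molecules", {
  ref <- make_reference(2, 50, seed = 2)
  sim <- sim_reads(ref, sim_config(n_cells = 10,
                                   molecules_per_cell_per_transcript = 7,
                                   seed = 9))
  expect_equal(nrow(sim$reads), sum(sim$molecules$n_reads))
  # every molecule's reads share one UMI and extent
  fam <- dplyr::count(sim$reads, .data$cell_barcode, .data$umi,
                      .data$transcript_id)
  expect_equal(sort(fam$n), sort(sim$molecules$n_reads))
})

test_that("lesion sites yield mutant molecules at the configured fraction", {
  # deep coverage of a handful of per-cell lesion sites; the empirical
  # mutant-molecule fraction must sit inside the binomial 99% CI of 0.5
  ref <- make_reference(1, 300, seed = 4)
  cfg <- quiet_cfg(n_cells = 3, molecules_per_cell_per_transcript = 250,
                   lesion_site_rate = 0.02, lesion_miscoding_prob = 1,
                   lesioned_allele_fraction = 0.5, seed = 21)
  sim <- sim_reads(ref, cfg)
  lesions <- sim$truth[sim$truth$kind == "lesion", ]
  expect_gt(nrow(lesions), 0)
  expect_equal(unique(lesions$expected_mutant_fraction), 0.5)
  for (i in seq_len(nrow(lesions))) {
    cell_mols <- sim$molecules$cell_barcode == lesions$cell_id[i]
    n <- sum(cell_mols)   # full-length molecules: all cover the site
    expect_gte(n, 200)
    hits <- sum(sim$variants$origin == "lesion" &
                  sim$variants$cell_barcode == lesions$cell_id[i] &
                  sim$variants$position == lesions$position[i])
    # 99.9 percent band per site keeps the family-wise rate low across the
    # handful of sites checked
    ci <- qbinom(c(5e-4, 1 - 5e-4), n, 0.5)
    expect_gte(hits, ci[1])
    expect_lte(hits, ci[2])
  }
})

test_that("molecule-level injection rates are recovered in the variants table", {
  # law-of-large-numbers check straight from the generator's own bookkeeping
  ref <- make_reference(5, 400, seed = 6)
  n_c <- sum(vapply(ref$sequence,
                    function(s) sum(charToRaw(s) == charToRaw("C")),
                    numeric(1)))
  cfg <- quiet_cfg(n_cells = 10, molecules_per_cell_per_transcript = 40,
                   molecule_error_rates = data.frame(
                     ref_base = "C", alt_base = "T", rate = 2e-3),
                   seed = 31)
  sim <- sim_reads(ref, cfg)
  n_mol <- nrow(sim$molecules)
  observed <- sum(sim$variants$origin == "molecule_error")
  # 4-sigma Poisson band around the expected event count
  c_per_mol <- n_c / 5
  lambda <- n_mol * c_per_mol * 2e-3
  expect_gt(observed, lambda - 4 * sqrt(lambda))
  expect_lt(observed, lambda + 4 * sqrt(lambda))
  expect_true(all(sim$variants$alt_base[
    sim$variants$origin == "molecule_error"] == "T"))
})

test_that("degenerate configurations are rejected", {
  ref <- make_reference(2, 40, seed = 7)
  expect_error(sim_config(n_cells = 0))
  expect_error(sim_reads(ref, quiet_cfg(fragment_length = 100, seed = 1)),
               "fragment_length")
  cfg <- quiet_cfg(seed = 1, dna_mutation_sites = data.frame(
    cell = 1, transcript_id = "nope", position = 1, alt_base = "A"))
  expect_error(sim_reads(ref, cfg), "unknown transcript")
  cfg2 <- quiet_cfg(seed = 1, dna_mutation_sites = data.frame(
    cell = 1, transcript_id = "tx001", position = 40, alt_base = "A"))
  expect_error(sim_reads(ref, cfg2), "bounds")
})
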