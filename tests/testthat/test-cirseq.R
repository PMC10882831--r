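test_that("error-free rolling-circle reads are exact tandem repeats", {
  ref <- make_reference(2, 120, seed = 71)
  cfg <- sim_config(background_tx_error_rate = 0, seq_error_rate = 0,
                    pcr_error_rate = 0, seed = 72)
  sim <- sim_cirseq_reads(ref, cfg, repeat_count = 3, fragment_length = 40,
                          n_fragments = 50)
  expect_equal(nrow(sim$reads), 50L)
  unit <- substr(sim$reads$sequence, 1, 40)
  expect_equal(sim$reads$sequence, strrep(unit, 3))
  # and the unit is the reference fragment
  refseq <- vapply(seq_len(50), function(i) {
    s <- ref$sequence[ref$transcript_id == sim$reads$transcript_id[i]]
    substr(s, sim$reads$start[i] + 1L, sim$reads$start[i] + 40L)
  }, character(1))
  expect_equal(unit, refseq)
})

test_that("transcription errors precede circularisation and recur in every repeat", {
  ref <- make_reference(1, 200, seed = 73)
  cfg <- sim_config(background_tx_error_rate = 5e-3, seq_error_rate = 0,
                    pcr_error_rate = 0, seed = 74)
  sim <- sim_cirseq_reads(ref, cfg, repeat_count = 3, fragment_length = 50,
                          n_fragments = 200)
  expect_gt(nrow(sim$variants), 0)
  for (i in seq_len(nrow(sim$reads))) {
    copies <- substring(sim$reads$sequence[i], c(1, 51, 101),
                        c(50, 100, 150))
    expect_equal(copies[1], copies[2])
    expect_equal(copies[1], copies[3])
  }
})

test_that("repeat-discordant positions match the analytic expectation", {
  e <- 0.01
  ref <- make_reference(1, 300, seed = 75)
  cfg <- sim_config(background_tx_error_rate = 0, seq_error_rate = e,
                    pcr_error_rate = 0, seed = 76)
  sim <- sim_cirseq_reads(ref, cfg, repeat_count = 3, fragment_length = 50,
                          n_fragments = 1000)
  # brute-force per-position enumeration: a column is discordant unless all
  # 3 copies agree, i.e. all correct or all the same wrong base
  p_concord <- (1 - e)^3 + 3 * (e / 3)^3
  discord <- vapply(seq_len(nrow(sim$reads)), function(i) {
    m <- do.call(rbind, strsplit(substring(sim$reads$sequence[i],
                                           c(1, 51, 101), c(50, 100, 150)),
                                 ""))
    sum(m[1, ] != m[2, ] | m[1, ] != m[3, ])
  }, numeric(1))
  n_cols <- 1000 * 50
  lambda <- n_cols * (1 - p_concord)
  expect_lt(abs(sum(discord) - lambda), 3 * sqrt(lambda))
})

test_that("period detection matches the exhaustive scan and its gates", {
  set.seed(770)
  # exact triple repeat
  s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  expect_equal(detect_period(strrep(s, 3), 20, 80), 50L)
  # two repeats with 2 mismatches: passes the mismatch gate but fails the
  # repeat-count gate under the default min_repeats = 3
  s2 <- s
  substr(s2, 10, 10) <- if (substr(s2, 10, 10) == "A") "C" else "A"
  substr(s2, 20, 20) <- if (substr(s2, 20, 20) == "G") "T" else "G"
  expect_true(is.na(detect_period(paste0(s, s2), 20, 80)))
  expect_equal(detect_period(paste0(s, s2), 20, 80, min_repeats = 2), 50L)

  # 200 random rolling reads with sequencing errors: >= 99 percent exact
  # recovery, with every result equal to the brute-force scan
  set.seed(771)
  hits <- 0L
  for (i in 1:200) {
    p <- sample(30:60, 1)
    unit <- paste(sample(c("A", "C", "G", "T"), p, TRUE), collapse = "")
    r <- sample(3:5, 1)
    x <- strsplit(strrep(unit, r), "")[[1]]
    err <- which(runif(length(x)) < 0.01)
    x[err] <- sample(c("A", "C", "G", "T"), length(err), TRUE)
    read <- paste(x, collapse = "")
    got <- detect_period(read, 25, 70)
    expect_equal(got, oracle_period(read, 25, 70))
    if (!is.na(got) && got == p) hits <- hits + 1L
  }
  expect_gte(hits, 198L)
})

test_that("period detection ignores trailing partial repeats", {
  set.seed(81)
  for (i in 1:25) {
    p <- sample(20:40, 1)
    unit <- paste(sample(c("A", "C", "G", "T"), p, TRUE), collapse = "")
    full <- strrep(unit, 3)
    tail_len <- sample(0:(p - 1), 1)
    padded <- paste0(full, substr(unit, 1, tail_len))
    expect_equal(detect_period(padded, 15, 50), detect_period(full, 15, 50))
  }
})

test_that("repeat folding matches the column-vote oracle", {
  unit <- "ACGTTGCA"
  exact <- fold_consensus(strrep(unit, 3), strrep("F", 24), 8)
  expect_equal(exact$consensus, unit)
  expect_equal(exact$n_agree, rep(3L, 8))
  expect_equal(exact$n_total, rep(3L, 8))

  # one erroneous copy with equal qualities: 2-vs-1 majority wins
  bad <- paste0("CCGTTGCA", unit, unit)
  expect_equal(fold_consensus(bad, strrep("F", 24), 8)$consensus, unit)

  expect_error(fold_consensus(strrep(unit, 3), strrep("F", 24), 0),
               "positive")
  expect_equal(fold_consensus(strrep(unit, 2), strrep("F", 16), 8)$reason,
               "too_few_repeats")

  set.seed(881)
  for (i in 1:100) {
    p <- sample(5:15, 1)
    r <- sample(3:4, 1)
    tail_len <- sample(0:(p - 1), 1)      # partial trailing repeat
    L <- p * r + tail_len
    x <- sample(c("A", "C", "G", "T"), L, TRUE)
    q <- paste(sample(c("5", "A", "F", "I"), L, TRUE), collapse = "")
    read <- paste(x, collapse = "")
    got <- fold_consensus(read, q, p, max_masked_frac = 1)
    expect_equal(got$consensus, oracle_fold(read, q, p))
  }
})

test_that("bulk folding agrees with the scalar fold and suppresses errors", {
  ref <- make_reference(2, 200, seed = 83)
  cfg <- sim_config(background_tx_error_rate = 1e-3, seq_error_rate = 5e-3,
                    pcr_error_rate = 0, seed = 84)
  sim <- sim_cirseq_reads(ref, cfg, repeat_count = 3, fragment_length = 60,
                          n_fragments = 300)
  folded <- suppressMessages(fold_reads(sim$reads, 40, 80))
  scalar <- vapply(seq_len(nrow(sim$reads)), function(i) {
    r <- fold_consensus(sim$reads$sequence[i], sim$reads$qualities[i],
                        detect_period(sim$reads$sequence[i], 40, 80))
    if (inherits(r, "tm_rejected")) NA_character_ else r$consensus
  }, character(1))
  m <- match(folded$read_id, sim$reads$read_id)
  expect_equal(folded$consensus, scalar[m])
})

test_that("folded consensi recover the transcription error rate", {
  ref <- make_reference(2, 300, seed = 85)
  tx_rate <- 1e-4
  cfg <- sim_config(background_tx_error_rate = tx_rate,
                    seq_error_rate = 1e-3, pcr_error_rate = 0, seed = 86)
  sim <- sim_cirseq_reads(ref, cfg, repeat_count = 3, fragment_length = 100,
                          n_fragments = 20000)
  folded <- suppressMessages(fold_reads(sim$reads, 90, 110))
  spec <- cirseq_error_rate(folded, ref)
  overall <- overall_error_rate(spec)
  n_cols <- glance(spec)$n_surveyed
  se <- sqrt(tx_rate / n_cols)
  expect_lt(abs(overall - tx_rate), 3 * se + tx_rate * 0.1)
})
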