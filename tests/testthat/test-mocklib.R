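test_that("k-mer enumeration matches the closed form L - k + 1", {
  ds <- gen_dsrna(876, 0.5, seed = 1)
  sense21 <- enumerate_kmers(ds, 21, 21, both_strands = FALSE)
  expect_equal(nrow(sense21), 856)
  all_k <- enumerate_kmers(ds, 21, 24, both_strands = TRUE)
  expect_equal(nrow(all_k), 6836)   # 2 * sum_{k=21..24} (876 - k + 1)
  for (k in 21:24) {
    expect_equal(sum(all_k$k == k & all_k$strand == "sense"), 876 - k + 1)
    expect_equal(sum(all_k$k == k & all_k$strand == "antisense"), 876 - k + 1)
  }
  # k-mers are the right substrings; antisense are positioned revcomps
  i <- which(all_k$k == 22 & all_k$strand == "sense" & all_k$start == 10)
  expect_equal(all_k$sequence[i], substr(ds$sequence, 11, 32))
  j <- which(all_k$k == 22 & all_k$strand == "antisense" & all_k$start == 10)
  expect_equal(all_k$sequence[j], revcomp(substr(ds$sequence, 11, 32)))

  one <- dsrna_construct("x", "ACGTACGT")
  whole <- enumerate_kmers(one, 8, 8)
  expect_equal(nrow(whole), 2)
  expect_error(enumerate_kmers(one, 4, 9), "length")
})

test_that("seed-and-extend scan equals the brute-force oracle on random instances", {
  ds <- gen_dsrna(120, 0.5, seed = 3)
  cases <- expand.grid(rep = 1:12, mm = 0:2)
  for (i in seq_len(nrow(cases))) {
    tx <- random_transcripts(4, c(40, 90), seed = 100 + i)
    km <- enumerate_kmers(ds, 21, 21, both_strands = TRUE)
    # thin the library so chance matches at mm=2 stay plausible but cheap
    km <- km[seq(1, nrow(km), by = 7), , drop = FALSE]
    got <- hamming_search(km, tx, max_mm = cases$mm[i])
    oracle <- brute_force_scan(unique(km$sequence), tx, cases$mm[i])
    expect_setequal(
      hit_keys(as.data.frame(got), "sequence", "transcript_id", "t_start",
               "mismatches"),
      hit_keys(oracle, "kmer", "transcript", "start", "mismatches"))
  }
})

test_that("pure-R index path, C++ path and Biostrings agree", {
  ds <- gen_dsrna(90, 0.5, seed = 8)
  tx <- random_transcripts(5, c(50, 80), seed = 42)
  km <- enumerate_kmers(ds, 21, 22, both_strands = TRUE)
  km <- km[seq(1, nrow(km), by = 5), , drop = FALSE]
  for (mm in 0:2) {
    a <- hamming_search(km, tx, max_mm = mm, method = "seed")
    b <- hamming_search(km, tx, max_mm = mm, method = "rseed")
    expect_identical(as.data.frame(a), as.data.frame(b))
    # independent library cross-check on the unique sequences
    bs_keys <- character(0)
    for (s in unique(km$sequence)) {
      m <- Biostrings::vmatchPattern(s, Biostrings::DNAStringSet(tx),
                                     max.mismatch = mm, with.indels = FALSE)
      for (t in seq_along(tx)) {
        for (st in BiocGenerics::start(m[[t]])) {
          win <- substr(tx[[t]], st, st + nchar(s) - 1)
          d <- sum(strsplit(win, "")[[1]] != strsplit(s, "")[[1]])
          bs_keys <- c(bs_keys, paste(s, names(tx)[t], st - 1, d))
        }
      }
    }
    expect_setequal(hit_keys(as.data.frame(a), "sequence", "transcript_id",
                             "t_start", "mismatches"),
                    unique(bs_keys))
  }
})

test_that("scan recovers planted sites within budget and not beyond", {
  ds <- gen_dsrna(876, 0.5, seed = 13)
  km <- enumerate_kmers(ds, 21, 24, both_strands = TRUE)
  out <- gen_transcriptome(6, c(150, 250), ds,
                           planted = list(c(21, 0), c(21, 1), c(21, 2),
                                          c(22, 3)),
                           seed = 21)
  hits <- hamming_search(km, out$transcripts, max_mm = 2)
  df <- as.data.frame(hits)
  for (i in seq_len(nrow(out$truth))) {
    tr <- out$truth[i, ]
    at_site <- df$transcript_id == tr$transcript_id &
      df$t_start == tr$position & df$mismatches == tr$hamming
    if (tr$hamming <= 2) {
      expect_true(any(at_site),
                  info = sprintf("distance-%d site must be found", tr$hamming))
    } else {
      expect_false(any(df$transcript_id == tr$transcript_id &
                         df$t_start == tr$position &
                         df$k == tr$k &
                         df$mismatches <= 2 &
                         df$kmer_start == tr$kmer_start))
    }
  }
})

test_that("hit sets are monotone in the mismatch budget and recheck on emit", {
  ds <- gen_dsrna(100, 0.5, seed = 4)
  tx <- random_transcripts(6, c(60, 120), seed = 7)
  km <- enumerate_kmers(ds, 21, 21)
  keysets <- lapply(0:2, function(mm) {
    df <- as.data.frame(hamming_search(km, tx, max_mm = mm))
    # stored mismatch counts equal a recomputed Hamming distance
    if (nrow(df)) {
      recomputed <- mapply(function(tid, st, s) {
        hamming_distance(s, substr(tx[[tid]], st + 1, st + nchar(s)))
      }, df$transcript_id, df$t_start, df$sequence)
      expect_equal(unname(recomputed), df$mismatches)
    }
    hit_keys(df, "sequence", "transcript_id", "t_start", "mismatches")
  })
  expect_true(all(keysets[[1]] %in% keysets[[2]]))
  expect_true(all(keysets[[2]] %in% keysets[[3]]))
})

test_that("scanning reverse-complemented transcripts mirrors coordinates", {
  ds <- gen_dsrna(80, 0.5, seed = 6)
  tx <- random_transcripts(3, c(50, 70), seed = 9)
  km <- enumerate_kmers(ds, 21, 21, both_strands = TRUE)
  fwd <- as.data.frame(hamming_search(km, tx, max_mm = 1))
  rc_tx <- setNames(revcomp(tx), names(tx))
  rev <- as.data.frame(hamming_search(km, rc_tx, max_mm = 1))
  # a sense k-mer hit at offset s maps to its revcomp partner k-mer hit at
  # L - s - k on the reverse-complemented transcript
  flip <- function(df) {
    L <- nchar(tx)[df$transcript_id]
    paste(revcomp(df$sequence), df$transcript_id,
          L - df$t_start - df$k, df$mismatches)
  }
  expect_setequal(flip(fwd),
                  paste(rev$sequence, rev$transcript_id, rev$t_start,
                        rev$mismatches))
})

test_that("seed index handles boundaries and empty input", {
  idx <- build_seed_index(c(t1 = "ACGTACGTAC"), 4)
  occ <- idx$table[["ACGT"]]
  expect_equal(occ[, 2], c(0, 4))
  # seed longer than the shortest transcript: no seeds, no crash
  idx2 <- build_seed_index(c(short = "ACG", long = "ACGTACGTACGT"), 5)
  expect_null(idx2$table[["ACG"]])
  expect_equal(nrow(hamming_search(character(0), c(t1 = "ACGT"))), 0)
  expect_equal(nrow(hamming_search("ACGTACGTACGTACGTACGTA", character(0))), 0)
  expect_warning(
    hamming_search("ACGTACGTACGTACGTACGTA", c(bad = "NNNNN-...")),
    "skipping")
})

test_that("off-target combination tiers and evidence modes behave as defined", {
  hits <- data.frame(
    transcript_id = c("tx1", "tx2", "tx2"),
    sequence = c("AAA", "CCC", "GGG"), k = 3L,
    strand = "sense", kmer_start = 0L, t_start = c(0L, 0L, 5L),
    t_end = c(3L, 3L, 8L), mismatches = c(1L, 2L, 2L),
    stringsAsFactors = FALSE)
  rep_all <- combine_offtargets(hits, mode = "all_mock")
  expect_equal(unname(rep_all$tier_counts), c(0L, 1L, 2L))
  expect_equal(names(rep_all$tier_counts), c("<=0", "<=1", "<=2"))

  # expressed-only restriction, matching also by reverse complement
  rep_e <- combine_offtargets(hits, expressed_sirnas = "TTT",
                              mode = "expressed_only")
  expect_equal(rep_e$per_transcript$transcript_id, "tx1")
  rep_none <- combine_offtargets(hits, expressed_sirnas = character(0),
                                 mode = "expressed_only")
  expect_equal(nrow(rep_none$per_transcript), 0)
  expect_error(combine_offtargets(hits, mode = "bogus"))
})
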