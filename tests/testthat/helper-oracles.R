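# Independent reference implementations used to cross-check the package.
# Deliberately naive: direct definitions, no shared code with the package
# internals they validate.

# All-offsets Hamming scan: every (kmer, transcript, offset) within max_mm.
brute_force_scan <- function(kmers, transcripts, max_mm) {
  rows <- list()
  for (q in seq_along(kmers)) {
    kc <- strsplit(kmers[[q]], "")[[1]]
    k <- length(kc)
    for (t in seq_along(transcripts)) {
      tc <- strsplit(transcripts[[t]], "")[[1]]
      L <- length(tc)
      if (L < k) next
      for (start in 0:(L - k)) {
        win <- tc[(start + 1):(start + k)]
        if (any(!win %in% c("A", "C", "G", "T"))) next
        mm <- sum(win != kc)
        if (mm <= max_mm) {
          rows[[length(rows) + 1L]] <- data.frame(
            kmer = kmers[[q]], transcript = names(transcripts)[t],
            start = start, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(kmer = character(0), transcript = character(0),
                      start = integer(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$transcript, out$start, out$kmer), , drop = FALSE]
}

# Canonical key set of a scan result for set comparison.
hit_keys <- function(df, kmer_col, tx_col, start_col, mm_col) {
  unique(paste(df[[kmer_col]], df[[tx_col]], df[[start_col]], df[[mm_col]]))
}

# Classical BH step-up computed from the sorted definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# Upper-tail hypergeometric P(X >= k) by direct summation of choose() terms.
hyper_upper <- function(k, pop_hits, pop_total, draws) {
  ks <- k:min(pop_hits, draws)
  sum(choose(pop_hits, ks) * choose(pop_total - pop_hits, draws - ks)) /
    choose(pop_total, draws)
}

random_transcripts <- function(n, len_range, seed) {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("rt%03d", seq_len(n))
  seqs
}
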