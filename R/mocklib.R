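## Mock siRNA library construction and off-target scanning -------------------

#' dsRNA construct
#'
#' The inverted-repeat dsRNA sequence all mock k-mers are cut from. Input `U`
#' is normalized to `T`; the alphabet is checked.
#'
#' @param id construct identifier.
#' @param sequence DNA/RNA string over A/C/G/T/U.
#' @return an object of class `dsrna_construct` with fields `id`, `sequence`
#'   (DNA upper case) and `length`.
#' @export
dsrna_construct <- function(id, sequence) {
  sequence <- normalize_dna(sequence, "dsRNA sequence")
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "dsrna_construct")
}

#' @export
print.dsrna_construct <- function(x, ...) {
  cat(sprintf("dsRNA construct '%s': %d nt, GC %.1f%%\n", x$id, x$length,
              100 * gc_fraction_of(x$sequence)))
  invisible(x)
}

#' Enumerate the mock siRNA k-mer library
#'
#' Cuts every k-mer, for `k` in `k_min..k_max`, from each strand of the
#' dsRNA: the exhaustive set of sequences Dicer processing could in principle
#' produce. Antisense k-mers are reverse complements of the sense windows and
#' are positioned on sense coordinates (`start` is always the 0-based offset
#' of the window on the sense strand). Duplicate sequences are retained with
#' their positions; a deduplicated set is available via `unique()` on the
#' `sequence` column.
#'
#' @param dsrna a [dsrna_construct()].
#' @param k_min,k_max k-mer length range, default 21..24.
#' @param both_strands cut from both strands (default) or the sense strand
#'   only.
#' @return data.frame of class `mock_kmers` with columns `sequence`, `k`,
#'   `strand` (`"sense"`/`"antisense"`), `start` (0-based, sense
#'   coordinates).
#' @examples
#' ds <- gen_dsrna(100, 0.5, seed = 1)
#' km <- enumerate_kmers(ds, 21, 21, both_strands = FALSE)
#' nrow(km)  # 100 - 21 + 1 = 80
#' @export
enumerate_kmers <- function(dsrna, k_min = 21L, k_max = 24L,
                            both_strands = TRUE) {
  stopifnot(inherits(dsrna, "dsrna_construct"))
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_min > k_max) {
    stop("need 1 <= k_min <= k_max", call. = FALSE)
  }
  if (k_max > dsrna$length) {
    stop("k_max exceeds the construct length", call. = FALSE)
  }
  out <- list()
  for (k in seq(k_min, k_max)) {
    starts <- 0:(dsrna$length - k)                      # 0-based
    sense <- substring(dsrna$sequence, starts + 1L, starts + k)
    out[[length(out) + 1L]] <- data.frame(sequence = sense, k = k,
                                          strand = "sense", start = starts,
                                          stringsAsFactors = FALSE)
    if (both_strands) {
      out[[length(out) + 1L]] <- data.frame(sequence = revcomp(sense), k = k,
                                            strand = "antisense",
                                            start = starts,
                                            stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("mock_kmers", "data.frame")
  res
}

#' Build an exact-seed index over a transcript set
#'
#' Hash of every `seed_length`-mer occurrence across the transcripts, the
#' structure behind the pigeonhole search: any Hamming match of a k-mer with
#' at most `m` substitutions contains an exact seed of length
#' `floor(k / (m + 1))` at one of `m + 1` fixed offsets. Transcripts shorter
#' than the seed contribute no seeds (and cannot contain a k-mer match, since
#' the seed is never longer than the k-mer).
#'
#' @param transcripts named character vector of transcript sequences.
#' @param seed_length integer >= 1.
#' @return object of class `seed_index`: a list with `seed_length`,
#'   `transcripts`, and `table` (environment mapping seed sequence to an
#'   integer matrix with rows `transcript`, `pos` \[0-based\]).
#' @export
build_seed_index <- function(transcripts, seed_length) {
  seed_length <- as.integer(seed_length)
  if (seed_length < 1L) stop("seed_length must be >= 1", call. = FALSE)
  tab <- new.env(parent = emptyenv(), hash = TRUE)
  for (t in seq_along(transcripts)) {
    s <- transcripts[[t]]
    L <- nchar(s)
    if (L < seed_length) next
    starts <- 0:(L - seed_length)
    seeds <- substring(s, starts + 1L, starts + seed_length)
    keep <- !grepl("[^ACGT]", seeds)
    for (i in which(keep)) {
      cur <- get0(seeds[i], envir = tab)
      tab[[seeds[i]]] <- rbind(cur, c(t, starts[i]))
    }
  }
  structure(list(seed_length = seed_length, transcripts = transcripts,
                 table = tab),
            class = "seed_index")
}

## Pure-R seeded search against a prebuilt index; reference construction of
## the same algorithm the C++ hot path implements. Used for small inputs and
## cross-validation.
search_seed_index <- function(index, kmers, max_mm) {
  stopifnot(inherits(index, "seed_index"))
  sl <- index$seed_length
  tx <- index$transcripts
  hits <- list()
  for (q in seq_along(kmers)) {
    km <- kmers[[q]]
    k <- nchar(km)
    seen <- character(0)
    for (chunk in 0:max_mm) {
      off <- chunk * sl
      if (off + sl > k) break
      seed <- substr(km, off + 1L, off + sl)
      occ <- get0(seed, envir = index$table)
      if (is.null(occ)) next
      for (r in seq_len(nrow(occ))) {
        t <- occ[r, 1]; start <- occ[r, 2] - off
        if (start < 0 || start + k > nchar(tx[[t]])) next
        key <- paste(t, start)
        if (key %in% seen) next
        seen <- c(seen, key)
        win <- substr(tx[[t]], start + 1L, start + k)
        if (grepl("[^ACGT]", win)) next
        mm <- sum(strsplit(km, "")[[1]] != strsplit(win, "")[[1]])
        if (mm <= max_mm) {
          hits[[length(hits) + 1L]] <- data.frame(kmer_index = q,
                                                  transcript_index = t,
                                                  start = start,
                                                  mismatches = mm)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(kmer_index = integer(0), transcript_index = integer(0),
                      start = integer(0), mismatches = integer(0)))
  }
  do.call(rbind, hits)
}

#' Hamming-bounded scan of mock k-mers against transcripts
#'
#' Reports every (k-mer, transcript, offset) whose ungapped Hamming distance
#' is at most `max_mm` — the mismatch-tolerant off-target scan. No gaps are
#' considered. Duplicate k-mer sequences are matched once and the hits
#' attributed to all source positions. Every emitted hit's distance is
#' recomputed before return.
#'
#' @param kmers a `mock_kmers` data.frame from [enumerate_kmers()], or a
#'   character vector of k-mer sequences.
#' @param transcripts named character vector of transcript sequences
#'   (records containing characters outside A/C/G/T are scanned over their
#'   valid stretches; fully invalid records are skipped with a warning).
#' @param max_mm maximum substitutions, >= 0 (the motivating study used 2).
#' @param method `"seed"` (default, seed-and-extend hot path) or `"rseed"`
#'   (pure-R reference of the same index algorithm).
#' @return data.frame of class `transcript_hits` with columns
#'   `transcript_id`, `sequence` (k-mer), `k`, `strand`, `kmer_start`,
#'   `t_start` (0-based), `t_end` (0-based half-open), `mismatches`. For a
#'   plain character `kmers` input, `strand` is `NA` and `kmer_start` the
#'   index into the input vector.
#' @export
hamming_search <- function(kmers, transcripts, max_mm = 2L,
                           method = c("seed", "rseed")) {
  method <- match.arg(method)
  max_mm <- as.integer(max_mm)
  if (max_mm < 0L) stop("max_mm must be >= 0", call. = FALSE)
  if (length(transcripts) == 0) {
    return(empty_hits())
  }
  if (is.null(names(transcripts))) {
    names(transcripts) <- sprintf("tx%03d", seq_along(transcripts))
  }
  transcripts <- chartr("u", "t", transcripts)
  transcripts <- chartr("U", "T", toupper(transcripts))
  fully_bad <- !grepl("[ACGT]", transcripts)
  if (any(fully_bad)) {
    warning("skipping transcript record(s) with no valid DNA: ",
            paste(names(transcripts)[fully_bad], collapse = ", "))
    transcripts <- transcripts[!fully_bad]
    if (length(transcripts) == 0) return(empty_hits())
  }

  if (is.character(kmers)) {
    ktab <- data.frame(sequence = kmers, k = nchar(kmers),
                       strand = rep(NA_character_, length(kmers)),
                       start = seq_along(kmers) - 1L,
                       stringsAsFactors = FALSE)
  } else {
    ktab <- as.data.frame(kmers)
  }
  if (nrow(ktab) == 0) return(empty_hits())
  uniq <- unique(ktab$sequence)

  raw <- if (method == "seed") {
    .hamming_scan_cpp(uniq, unname(transcripts), names(transcripts), max_mm)
  } else {
    sl <- max(1L, min(nchar(uniq)) %/% (max_mm + 1L))
    search_seed_index(build_seed_index(transcripts, sl), uniq, max_mm)
  }
  if (nrow(raw) == 0) return(empty_hits())

  out <- list()
  for (i in seq_len(nrow(raw))) {
    seqn <- uniq[raw$kmer_index[i]]
    src <- ktab[ktab$sequence == seqn, , drop = FALSE]
    tid <- names(transcripts)[raw$transcript_index[i]]
    k <- nchar(seqn)
    ## recheck on emit
    win <- substr(transcripts[[raw$transcript_index[i]]],
                  raw$start[i] + 1L, raw$start[i] + k)
    mm <- hamming_distance(seqn, win)
    stopifnot(mm == raw$mismatches[i])
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = tid, sequence = seqn, k = k,
      strand = src$strand, kmer_start = src$start,
      t_start = raw$start[i], t_end = raw$start[i] + k,
      mismatches = mm, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$t_start, res$sequence,
                   res$strand, res$kmer_start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("transcript_hits", "data.frame")
  res
}

empty_hits <- function() {
  res <- data.frame(transcript_id = character(0), sequence = character(0),
                    k = integer(0), strand = character(0),
                    kmer_start = integer(0), t_start = integer(0),
                    t_end = integer(0), mismatches = integer(0),
                    stringsAsFactors = FALSE)
  class(res) <- c("transcript_hits", "data.frame")
  res
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b strings of equal length.
#' @return integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length",
                                 call. = FALSE)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Combine mock-library hits with expressed-siRNA evidence
#'
#' Aggregates scan hits into a per-transcript off-target report, tiered by
#' minimum mismatch count. In `"expressed_only"` mode only hits whose k-mer
#' sequence (or its reverse complement) occurs in the expressed small-RNA
#' set are counted, combining the transcript scan with the sequencing
#' evidence; `"all_mock"` uses every mock hit.
#'
#' @param mock_hits a `transcript_hits` data.frame from [hamming_search()].
#' @param expressed_sirnas character vector of expressed siRNA sequences
#'   (DNA alphabet; only needed in `"expressed_only"` mode).
#' @param mode `"all_mock"` or `"expressed_only"`.
#' @return object of class `offtarget_report`: list with `per_transcript`
#'   (data.frame transcript_id, min_mismatch) and `tier_counts` (named
#'   integer vector, cumulative gene counts at `<=0`, `<=1`, ... mismatches)
#'   and `mode`.
#' @export
combine_offtargets <- function(mock_hits, expressed_sirnas = character(0),
                               mode = c("all_mock", "expressed_only")) {
  mode <- match.arg(mode)
  hits <- as.data.frame(mock_hits)
  if (mode == "expressed_only") {
    expressed <- unique(c(toupper(chartr("U", "T", expressed_sirnas)),
                          revcomp(expressed_sirnas)))
    hits <- hits[hits$sequence %in% expressed, , drop = FALSE]
  }
  max_tier <- if (nrow(hits)) max(hits$mismatches) else 0L
  if (nrow(hits) == 0) {
    per <- data.frame(transcript_id = character(0), min_mismatch = integer(0))
    tiers <- setNames(integer(max_tier + 1L),
                      paste0("<=", 0:max_tier))
  } else {
    mins <- tapply(hits$mismatches, hits$transcript_id, min)
    per <- data.frame(transcript_id = names(mins),
                      min_mismatch = as.integer(mins),
                      stringsAsFactors = FALSE)
    per <- per[order(per$transcript_id), , drop = FALSE]
    rownames(per) <- NULL
    tiers <- vapply(0:max_tier, function(m) sum(per$min_mismatch <= m),
                    integer(1))
    names(tiers) <- paste0("<=", 0:max_tier)
  }
  structure(list(per_transcript = per, tier_counts = tiers, mode = mode),
            class = "offtarget_report")
}

#' @export
print.offtarget_report <- function(x, ...) {
  cat("Off-target report (mode:", x$mode, ")\n")
  cat("  transcripts hit:", nrow(x$per_transcript), "\n")
  for (i in seq_along(x$tier_counts)) {
    cat(sprintf("  genes at %s mismatches: %d\n", names(x$tier_counts)[i],
                x$tier_counts[i]))
  }
  invisible(x)
}
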