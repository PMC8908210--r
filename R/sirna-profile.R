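## Expressed small-RNA profiling ---------------------------------------------
##
## Reads are length-filtered (18-30 nt), collapsed to unique sequences with
## multiplicities, mapped exactly (no gaps, no mismatches) to either strand
## of the dsRNA so that everything profiled demonstrably derives from the
## construct, and summarised: size distribution, first-base coverage along
## the construct, per-position base frequencies with information content, GC
## fraction, and 5' A/U content.

#' Filter reads by length
#'
#' @param reads data.frame with at least `sequence` (and optionally `count`)
#'   columns, e.g. from [gen_srna_reads()] or [read_fastq()].
#' @param min_len,max_len inclusive length bounds (defaults 18 and 30 nt,
#'   the reliable small-RNA size window).
#' @return the reads whose length lies in `[min_len, max_len]`, counts
#'   preserved.
#' @export
filter_by_length <- function(reads, min_len = 18L, max_len = 30L) {
  len <- nchar(reads$sequence)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Collapse identical read sequences
#'
#' @param reads data.frame with a `sequence` column; an existing `count`
#'   column is summed.
#' @return data.frame with unique `sequence` and summed `count`.
#' @export
collapse_reads <- function(reads) {
  count <- if ("count" %in% names(reads)) reads$count else rep(1L, nrow(reads))
  agg <- tapply(count, reads$sequence, sum)
  data.frame(sequence = names(agg), count = as.integer(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map reads exactly to the dsRNA construct
#'
#' A read maps iff it is an exact substring of the sense or antisense strand
#' (zero gaps and zero mismatches). All occurrences are reported;
#' multi-mapping reads are flagged. Positions are 0-based 5' start positions
#' on the matched strand's own coordinates.
#'
#' @param reads data.frame with `sequence` (+ optional `count`); collapsed
#'   internally via [collapse_reads()]. Sequences are U->T normalized.
#' @param dsrna a [dsrna_construct()].
#' @return data.frame of class `sirna_alignments`: `sequence`, `count`,
#'   `length`, `strand`, `first_base` (0-based), `n_occurrences`.
#' @export
map_exact_to_dsrna <- function(reads, dsrna) {
  stopifnot(inherits(dsrna, "dsrna_construct"))
  reads$sequence <- toupper(chartr("Uu", "Tt", reads$sequence))
  reads <- collapse_reads(reads)
  strands <- list(sense = Biostrings::DNAString(dsrna$sequence),
                  antisense = Biostrings::DNAString(revcomp(dsrna$sequence)))
  out <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    occ <- list()
    for (strand in names(strands)) {
      ## matchPattern reports overlapping occurrences, unlike gregexpr
      m <- BiocGenerics::start(Biostrings::matchPattern(s, strands[[strand]]))
      if (length(m)) {
        for (pos in as.integer(m)) {
          occ[[length(occ) + 1L]] <- data.frame(
            sequence = s, count = reads$count[i], length = nchar(s),
            strand = strand, first_base = pos - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(occ)) {
      block <- do.call(rbind, occ)
      block$n_occurrences <- nrow(block)
      out[[length(out) + 1L]] <- block
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sequence = character(0), count = integer(0),
               length = integer(0), strand = character(0),
               first_base = integer(0), n_occurrences = integer(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dsrna_length") <- dsrna$length
  class(res) <- c("sirna_alignments", "data.frame")
  res
}

#' Size distribution of mapped reads
#'
#' @param alignments a `sirna_alignments` data.frame.
#' @return named integer vector, read count per length. Multi-mapping reads
#'   are counted once per read (not per occurrence).
#' @export
size_distribution <- function(alignments) {
  a <- as.data.frame(alignments)
  if (nrow(a) == 0) return(setNames(integer(0), character(0)))
  ## one row per unique read, counted once regardless of occurrences
  u <- a[!duplicated(a$sequence), , drop = FALSE]
  tab <- tapply(u$count, u$length, sum)
  setNames(as.integer(tab), names(tab))
}

#' First-base coverage along the dsRNA, per strand
#'
#' @param alignments a `sirna_alignments` data.frame.
#' @return list with `sense` and `antisense` integer vectors indexed by
#'   0-based position (length = dsRNA length); entry p is the number of
#'   (read, occurrence) pairs whose 5' base maps at p, weighted by read
#'   count.
#' @export
first_base_coverage <- function(alignments) {
  L <- attr(alignments, "dsrna_length")
  a <- as.data.frame(alignments)
  out <- list()
  for (strand in c("sense", "antisense")) {
    v <- integer(L)
    sel <- a[a$strand == strand, , drop = FALSE]
    if (nrow(sel)) {
      agg <- tapply(sel$count, sel$first_base, sum)
      v[as.integer(names(agg)) + 1L] <- as.integer(agg)
    }
    out[[strand]] <- v
  }
  out
}

#' Base-preference matrix of k-length mapped reads
#'
#' Position frequency matrix over the reads of length `k` (weighted by
#' count), with per-position Shannon information content, overall GC
#' fraction, and the A/U share over the first five 5' positions — the
#' features used to characterise functional siRNA populations (21-mers with
#' elevated 5' A/U content).
#'
#' @param alignments a `sirna_alignments` data.frame.
#' @param k read length used for the matrix (default 21).
#' @param min_count minimum per-read count to enter the profile (default 1).
#' @param rna display the matrix with RNA rows (U instead of T).
#' @return object of class `base_preference`: list with `pfm` (k x 4 matrix,
#'   rows positions, columns A/C/G/T or A/C/G/U; each row sums to 1),
#'   `information` (bits per position, in \[0, 2\]), `gc_fraction`,
#'   `au5_fraction`, `n_reads` (weighted count used). Returns an empty
#'   profile (`n_reads = 0`) when no k-length reads pass.
#' @export
base_preference <- function(alignments, k = 21L, min_count = 1L, rna = FALSE) {
  a <- as.data.frame(alignments)
  u <- a[!duplicated(a$sequence), , drop = FALSE]
  u <- u[u$length == k & u$count >= min_count, , drop = FALSE]
  bases <- DNA_BASES
  if (nrow(u) == 0) {
    out <- list(pfm = matrix(NA_real_, 0, 4, dimnames = list(NULL, bases)),
                information = numeric(0), gc_fraction = NA_real_,
                au5_fraction = NA_real_, n_reads = 0L)
    class(out) <- "base_preference"
    return(out)
  }
  mat <- matrix(0, nrow = k, ncol = 4, dimnames = list(NULL, bases))
  chars <- strsplit(u$sequence, "", fixed = TRUE)
  for (i in seq_len(nrow(u))) {
    for (pos in seq_len(k)) {
      mat[pos, chars[[i]][pos]] <- mat[pos, chars[[i]][pos]] + u$count[i]
    }
  }
  total <- sum(u$count)
  pfm <- mat / total
  ent <- apply(pfm, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  info <- 2 - ent
  gc <- sum(mat[, c("C", "G")]) / (total * k)
  au5 <- sum(mat[1:5, c("A", "T")]) / (total * 5)
  if (rna) colnames(pfm)[colnames(pfm) == "T"] <- "U"
  out <- list(pfm = pfm, information = info, gc_fraction = gc,
              au5_fraction = au5, n_reads = total)
  class(out) <- "base_preference"
  out
}

#' @export
print.base_preference <- function(x, ...) {
  cat(sprintf("Base preference over %d weighted reads (%d positions)\n",
              x$n_reads, nrow(x$pfm)))
  if (x$n_reads > 0) {
    cat(sprintf("  GC fraction %.4f; 5' A/U fraction %.4f\n",
                x$gc_fraction, x$au5_fraction))
  }
  invisible(x)
}

#' Full siRNA profile of a read library
#'
#' Convenience wrapper: length filter, exact mapping, and all summaries.
#'
#' @param reads data.frame with `sequence` (+ optional `count`).
#' @param dsrna a [dsrna_construct()].
#' @param k length used for the base-preference matrix.
#' @param min_count minimum collapsed count for the base-preference matrix.
#' @return object of class `sirna_profile`: list with `alignments`,
#'   `size_distribution`, `first_base_coverage`, `base_preference`,
#'   `total_mapped` (weighted reads with >= 1 exact occurrence).
#' @export
sirna_profile <- function(reads, dsrna, k = 21L, min_count = 1L) {
  reads <- filter_by_length(reads)
  aln <- map_exact_to_dsrna(reads, dsrna)
  u <- as.data.frame(aln)
  u <- u[!duplicated(u$sequence), , drop = FALSE]
  out <- list(alignments = aln,
              size_distribution = size_distribution(aln),
              first_base_coverage = first_base_coverage(aln),
              base_preference = base_preference(aln, k = k,
                                                min_count = min_count),
              total_mapped = sum(u$count))
  class(out) <- "sirna_profile"
  out
}

#' @export
print.sirna_profile <- function(x, ...) {
  cat("siRNA profile:", x$total_mapped, "mapped reads\n")
  sd <- x$size_distribution
  if (length(sd)) {
    top <- names(sd)[which.max(sd)]
    cat(sprintf("  modal length %s nt (%.1f%% of mapped)\n", top,
                100 * max(sd) / sum(sd)))
  }
  if (x$base_preference$n_reads > 0) {
    cat(sprintf("  GC %.4f, 5' A/U %.4f over %d nt reads\n",
                x$base_preference$gc_fraction,
                x$base_preference$au5_fraction, nrow(x$base_preference$pfm)))
  }
  invisible(x)
}

#' Abundance ratio of two profiles
#'
#' Ratio of total mapped read counts, e.g. a GE line's construct-derived
#' siRNA abundance over a non-GE line's.
#'
#' @param profile_a,profile_b `sirna_profile` objects (or numbers, taken as
#'   totals).
#' @param pseudocount added to both totals when the denominator is zero
#'   (default 0: a zero denominator with zero pseudocount is an error).
#' @return numeric ratio.
#' @export
abundance_ratio <- function(profile_a, profile_b, pseudocount = 0) {
  a <- if (inherits(profile_a, "sirna_profile")) profile_a$total_mapped else profile_a
  b <- if (inherits(profile_b, "sirna_profile")) profile_b$total_mapped else profile_b
  if (a < 0 || b < 0) stop("totals must be >= 0", call. = FALSE)
  if (a == 0 && b == 0) stop("undefined ratio: both totals are zero",
                             call. = FALSE)
  if (b == 0) {
    if (pseudocount <= 0) {
      stop("zero denominator; supply a positive pseudocount", call. = FALSE)
    }
    return((a + pseudocount) / pseudocount)
  }
  a / b
}
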