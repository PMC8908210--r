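## Synthetic-data generators -------------------------------------------------
##
## Every input the pipeline consumes can be generated here with known planted
## truth: a dsRNA construct, a transcript set with planted near-match sites,
## small-RNA read sets with controlled length and position structure,
## replicate expression/metabolite matrices with planted differential
## features, and a pathway annotation with one over-represented term. All
## generators are deterministic given their seed.

#' Generate a random dsRNA construct
#'
#' Emulates the inverted-repeat dsRNA transcribed from an RNAi transgene; the
#' construct studied in the motivating maize system is 876 bp long, the
#' default here.
#'
#' @param length construct length in nt, >= 24 (the longest mock k-mer).
#' @param gc_fraction target GC content in \[0, 1\].
#' @param seed integer seed; the same seed and parameters reproduce the
#'   sequence exactly.
#' @param id sequence identifier.
#' @return a `dsrna_construct` object (see [dsrna_construct()]).
#' @examples
#' ds <- gen_dsrna(876, 0.5, seed = 7)
#' ds$length
#' @export
gen_dsrna <- function(length = 876L, gc_fraction = 0.5, seed = 1L,
                      id = "dsRNA") {
  length <- as.integer(length)
  if (length < 24L) stop("dsRNA length must be >= 24 nt", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("gc_fraction must be in [0, 1]", call. = FALSE)
  }
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE,
                                      prob = p), collapse = ""))
  dsrna_construct(id = id, sequence = seq)
}

#' Generate a transcript set with planted near-match off-target sites
#'
#' Builds `n_transcripts` random transcripts and embeds, for each entry of
#' `planted`, one k-mer copied from the dsRNA with exactly the requested
#' number of substitutions, at a recorded position. The returned truth table
#' is the ground truth for scanner recovery tests.
#'
#' @param n_transcripts number of transcripts (planted sites occupy the first
#'   `length(planted)` of them; must be >= that).
#' @param length_range integer length-2 vector, min/max transcript length.
#' @param dsrna a [dsrna_construct()].
#' @param planted list of `c(k, hamming)` pairs: plant a `k`-mer at Hamming
#'   distance `hamming` from its dsRNA origin. `k` in 21..24, `0 <= hamming
#'   <= k`.
#' @param seed integer seed.
#' @return list with `transcripts` (named character vector of sequences) and
#'   `truth` (data.frame: transcript_id, position \[0-based\], k, hamming,
#'   kmer_start \[0-based on the sense strand\]).
#' @export
gen_transcriptome <- function(n_transcripts, length_range = c(200L, 500L),
                              dsrna, planted = list(), seed = 1L) {
  stopifnot(inherits(dsrna, "dsrna_construct"))
  n_transcripts <- as.integer(n_transcripts)
  for (p in planted) {
    k <- p[[1]]; h <- p[[2]]
    if (k < 21 || k > 24) stop("planted k must be in 21..24", call. = FALSE)
    if (h < 0 || h > k) stop("planted hamming must be in 0..k", call. = FALSE)
  }
  if (n_transcripts < length(planted)) {
    stop("need at least one transcript per planted site", call. = FALSE)
  }
  if (min(length_range) <
      max(c(21, vapply(planted, function(p) as.numeric(p[[1]]), 1)))) {
    stop("transcript lengths must accommodate the planted k-mers", call. = FALSE)
  }
  with_seed(seed, {
    lens <- if (n_transcripts > 0) {
      sample(seq(length_range[1], length_range[2]), n_transcripts,
             replace = TRUE)
    } else integer(0)
    seqs <- vapply(lens, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- if (n_transcripts > 0) {
      sprintf("tx%03d", seq_len(n_transcripts))
    } else character(0)
    truth <- data.frame(transcript_id = character(0), position = integer(0),
                        k = integer(0), hamming = integer(0),
                        kmer_start = integer(0), stringsAsFactors = FALSE)
    for (i in seq_along(planted)) {
      k <- as.integer(planted[[i]][[1]]); h <- as.integer(planted[[i]][[2]])
      src <- sample.int(dsrna$length - k + 1L, 1L) - 1L       # 0-based
      kmer <- substr(dsrna$sequence, src + 1L, src + k)
      if (h > 0) {
        at <- sample.int(k, h)
        chars <- strsplit(kmer, "", fixed = TRUE)[[1]]
        for (j in at) chars[j] <- sample(setdiff(DNA_BASES, chars[j]), 1L)
        kmer <- paste(chars, collapse = "")
      }
      tid <- names(seqs)[i]
      pos <- sample.int(lens[i] - k + 1L, 1L) - 1L            # 0-based
      substr(seqs[i], pos + 1L, pos + k) <- kmer
      truth <- rbind(truth, data.frame(transcript_id = tid, position = pos,
                                       k = k, hamming = h, kmer_start = src,
                                       stringsAsFactors = FALSE))
    }
    list(transcripts = seqs, truth = truth)
  })
}

#' Generate small-RNA reads from a dsRNA construct
#'
#' Draws `(1 - background_fraction) * n_reads` reads as exact substrings of
#' either strand of the dsRNA, with 5' start positions drawn from a hotspot
#' distribution and lengths from `length_weights`; the remainder are random
#' background sequences. With all mass on 21 nt this reproduces the
#' 21-nt-dominated size profile characteristic of Dicer products.
#'
#' @param dsrna a [dsrna_construct()].
#' @param n_reads total number of reads.
#' @param length_weights named numeric vector, names are read lengths within
#'   18..30, values nonnegative weights (not all zero).
#' @param hotspots data.frame or matrix with columns `position` (0-based 5'
#'   start on the sampled strand) and `weight`; `NULL` means uniform over all
#'   valid starts.
#' @param background_fraction fraction of random background reads in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame with columns `id`, `sequence`, `length`, `origin`
#'   (`"dsrna"` or `"background"`).
#' @export
gen_srna_reads <- function(dsrna, n_reads, length_weights = c("21" = 1),
                           hotspots = NULL, background_fraction = 0,
                           seed = 1L) {
  stopifnot(inherits(dsrna, "dsrna_construct"))
  lens <- as.integer(names(length_weights))
  w <- as.numeric(length_weights)
  if (any(w < 0) || all(w == 0)) {
    stop("length weights must be nonnegative and not all zero", call. = FALSE)
  }
  if (any(lens < 18L | lens > 30L)) {
    stop("read lengths must lie in 18..30", call. = FALSE)
  }
  if (!is.null(hotspots)) {
    hotspots <- as.data.frame(hotspots)
    if (any(hotspots$position < 0 | hotspots$position > dsrna$length - min(lens))) {
      stop("hotspot position out of range for the shortest read length",
           call. = FALSE)
    }
  }
  if (background_fraction < 0 || background_fraction > 1) {
    stop("background_fraction must be in [0, 1]", call. = FALSE)
  }
  strands <- c(sense = dsrna$sequence, antisense = revcomp(dsrna$sequence))
  with_seed(seed, {
    n_bg <- round(background_fraction * n_reads)
    n_ds <- n_reads - n_bg
    read_len <- lens[sample.int(length(lens), n_reads, replace = TRUE,
                                prob = w)]
    seqs <- character(n_reads)
    origin <- c(rep("dsrna", n_ds), rep("background", n_bg))
    for (i in seq_len(n_ds)) {
      L <- read_len[i]
      strand <- sample(c("sense", "antisense"), 1L)
      pos <- if (is.null(hotspots)) {
        sample.int(dsrna$length - L + 1L, 1L) - 1L
      } else {
        ok <- hotspots$position <= dsrna$length - L
        hp <- hotspots[ok, , drop = FALSE]
        if (nrow(hp) == 0) stop("no hotspot fits read length ", L, call. = FALSE)
        hp$position[sample.int(nrow(hp), 1L, prob = hp$weight)]
      }
      seqs[i] <- substr(strands[[strand]], pos + 1L, pos + L)
    }
    for (i in seq_len(n_bg)) {
      seqs[n_ds + i] <- paste(sample(DNA_BASES, read_len[n_ds + i],
                                     replace = TRUE), collapse = "")
    }
    data.frame(id = sprintf("read%06d", seq_len(n_reads)), sequence = seqs,
               length = nchar(seqs), origin = origin, stringsAsFactors = FALSE)
  })
}

## Shared machinery for the expression / metabolome generators. `planted` is a
## list of list(line=, n_de=, log2fc=) entries: n_de features are shifted by
## log2fc in every replicate of that line. `line` may name several lines, in
## which case the same features shift in all of them (a shared genetic
## background effect).
gen_intensity_study <- function(design, n_features, planted, base_log2_mean,
                                base_log2_sd, rep_sd, seed) {
  stopifnot(inherits(design, "study_design"))
  n_features <- as.integer(n_features)
  for (p in planted) {
    if (!all(p$line %in% design$lines)) {
      stop("planted effect names unknown line: ",
           paste(setdiff(p$line, design$lines), collapse = ", "),
           call. = FALSE)
    }
  }
  with_seed(seed, {
    ids <- sprintf("feat%05d", seq_len(n_features))
    samples <- sample_ids(design)
    base <- rnorm(n_features, base_log2_mean, base_log2_sd)
    log2x <- matrix(rnorm(n_features * length(samples), mean = base,
                          sd = rep_sd),
                    nrow = n_features, ncol = length(samples),
                    dimnames = list(ids, samples))
    truth <- data.frame(feature_id = character(0), line = character(0),
                        log2_effect = numeric(0), stringsAsFactors = FALSE)
    used <- integer(0)
    line_of <- sample_line(samples, design)
    for (p in planted) {
      free <- setdiff(seq_len(n_features), used)
      if (length(free) < p$n_de) stop("not enough features to plant effects",
                                      call. = FALSE)
      pick <- sample(free, p$n_de)
      used <- c(used, pick)
      cols <- line_of %in% p$line
      log2x[pick, cols] <- log2x[pick, cols] + p$log2fc
      truth <- rbind(truth, data.frame(feature_id = ids[pick],
                                       line = paste(p$line, collapse = "+"),
                                       log2_effect = p$log2fc,
                                       stringsAsFactors = FALSE))
    }
    list(matrix = omics_matrix(2^log2x, design), truth = truth)
  })
}

#' Generate an expression study with planted differential features
#'
#' FPKM-like intensities are log-normal: a per-feature baseline drawn from
#' `N(base_log2_mean, base_log2_sd)` on the log2 scale, plus replicate noise
#' of standard deviation `rep_sd` (log2 units). Planted features are shifted
#' by `log2fc` in every replicate of the named line, so any comparison
#' involving that line carries the effect.
#'
#' @param design a [study_design()].
#' @param n_features number of features.
#' @param planted list of `list(line=, n_de=, log2fc=)` entries.
#' @param base_log2_mean,base_log2_sd baseline log2-intensity distribution.
#' @param rep_sd biological replicate noise, sd on the log2 scale.
#' @param seed integer seed.
#' @return list with `matrix` (an [omics_matrix()]) and `truth` (data.frame:
#'   feature_id, line, log2_effect).
#' @export
gen_expression_study <- function(design, n_features, planted = list(),
                                 base_log2_mean = 5, base_log2_sd = 1.5,
                                 rep_sd = 0.25, seed = 1L) {
  gen_intensity_study(design, n_features, planted, base_log2_mean,
                      base_log2_sd, rep_sd, seed)
}

#' Generate a metabolite study with planted effects and MCAR missing cells
#'
#' Same intensity model as [gen_expression_study()] plus cells set missing
#' completely at random at rate `missing_rate`, emulating undetected ion
#' peaks.
#'
#' @inheritParams gen_expression_study
#' @param missing_rate probability in \[0, 1\] that any cell is missing.
#' @return as [gen_expression_study()]; the matrix may contain `NA`.
#' @export
gen_metabolome_study <- function(design, n_features, planted = list(),
                                 missing_rate = 0, base_log2_mean = 14,
                                 base_log2_sd = 2, rep_sd = 0.25, seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be in [0, 1]", call. = FALSE)
  }
  out <- gen_intensity_study(design, n_features, planted, base_log2_mean,
                             base_log2_sd, rep_sd, seed)
  if (missing_rate > 0) {
    m <- out$matrix
    drop <- with_seed(seed + 1L,
                      matrix(runif(length(m)) < missing_rate, nrow = nrow(m)))
    m[drop] <- NA_real_
    out$matrix <- omics_matrix(unclass(m)[, , drop = FALSE],
                               matrix_design(out$matrix))
  }
  out
}

#' Generate a gene-to-pathway annotation with one over-represented term
#'
#' Terms are random subsets of the feature universe except `planted_term`,
#' which is forced to contain `overdraw` members of `list_features` (the
#' feature list later tested for over-representation).
#'
#' @param feature_ids universe of feature identifiers.
#' @param n_terms number of terms.
#' @param term_size_range integer range of term sizes (capped at the universe
#'   size).
#' @param planted_term optional `list(term_id=, overdraw=)`; `overdraw`
#'   members of `list_features` are planted into that term.
#' @param list_features feature list the planted term is enriched in
#'   (required when `planted_term` is given).
#' @param seed integer seed.
#' @return list with `annotation` (named list term -> member feature ids) and
#'   `truth` (the planted term id, or `NA`).
#' @export
gen_annotation <- function(feature_ids, n_terms, term_size_range = c(5L, 40L),
                           planted_term = NULL, list_features = NULL,
                           seed = 1L) {
  if (max(term_size_range) > length(feature_ids)) {
    stop("term sizes cannot exceed the number of features", call. = FALSE)
  }
  with_seed(seed, {
    ann <- list()
    if (n_terms > 0) {
      for (i in seq_len(n_terms)) {
        sz <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
        ann[[sprintf("term%03d", i)]] <- sample(feature_ids, sz)
      }
    }
    planted_id <- NA_character_
    if (!is.null(planted_term)) {
      stopifnot(!is.null(list_features))
      planted_id <- planted_term$term_id
      overdraw <- min(planted_term$overdraw, length(list_features))
      inlist <- sample(list_features, overdraw)
      rest <- sample(setdiff(feature_ids, list_features),
                     max(0L, sample(seq(term_size_range[1],
                                        term_size_range[2]), 1L) - overdraw))
      ann[[planted_id]] <- c(inlist, rest)
    }
    list(annotation = ann, truth = planted_id)
  })
}
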