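#' @useDynLib siromics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats p.adjust phyper prcomp t.test sd var hclust dist cor
#'   as.dist cutree rnorm runif rbinom complete.cases setNames
#' @importFrom utils read.delim write.table head modifyList combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## Every generator routes its randomness through this so identical seeds give
## byte-identical output without disturbing the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of sequences over A/C/G/T (case-insensitive;
#'   U is treated as T).
#' @return character vector of reverse complements, upper case.
#' @examples
#' revcomp("ACGT")   # "ACGT"
#' revcomp("AAGTC")  # "GACTT"
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTU", "TGCAA", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

## Normalize a sequence to the DNA alphabet; stop (or warn) on invalid chars.
normalize_dna <- function(x, what = "sequence") {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside A/C/G/T (first offender: %s)",
                 what, x[bad][1]), call. = FALSE)
  }
  x
}

is_valid_dna <- function(x) !grepl("[^ACGT]", chartr("U", "T", toupper(x)))

gc_fraction_of <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  sum(gc) / sum(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
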