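## Readers and writers -------------------------------------------------------
##
## One dialect everywhere: TSV (tab-separated, UTF-8, '.' decimal), FASTA/
## FASTQ via Biostrings, GMT-like annotation (term, description, members),
## Newick dendrograms, YAML configs. Enrichment scores are written with 4
## fixed decimals next to a full-precision column.

#' Read a FASTA file
#'
#' @param path file path.
#' @param normalize_u convert U to T (with a notice) so RNA input enters the
#'   DNA-alphabet pipeline.
#' @return named character vector of sequences (ids truncated at the first
#'   whitespace).
#' @export
read_fasta <- function(path, normalize_u = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0)) {
    stop("record without sequence in ", path, call. = FALSE)
  }
  if (normalize_u && any(grepl("U", seqs, fixed = TRUE))) {
    message("normalizing U -> T in ", path)
    seqs <- chartr("U", "T", seqs)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path file path.
#' @return data.frame with `id`, `sequence` (U->T normalized, upper case),
#'   `length`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fastq")
  seqs <- chartr("U", "T", toupper(as.character(set)))
  data.frame(id = sub("\\s.*$", "", names(set)), sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write reads to FASTQ with constant quality
#'
#' @param reads data.frame with `id` and `sequence`.
#' @param path output path.
#' @param quality_char quality character applied to every base (default
#'   `"I"`, Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  lines <- character(4L * nrow(reads))
  if (nrow(reads) > 0) {
    idx <- seq_len(nrow(reads))
    lines[4 * idx - 3] <- paste0("@", reads$id)
    lines[4 * idx - 2] <- reads$sequence
    lines[4 * idx - 1] <- "+"
    lines[4 * idx] <- strrep(quality_char, nchar(reads$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a features-by-samples TSV matrix
#'
#' First column holds feature ids; remaining column names must resolve as
#' `<line>_<rep>` sample ids of the design. Empty cells become missing
#' values (not zeros).
#'
#' @param path TSV path.
#' @param design a [study_design()].
#' @return an [omics_matrix()].
#' @export
read_matrix <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (ncol(tab) < 2) stop("matrix file needs a feature column and samples",
                          call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  ## validates sample names against the design
  omics_matrix(vals, design)
}

#' Write an omics matrix to TSV
#'
#' @param matrix an [omics_matrix()] (or plain matrix with dimnames).
#' @param path output path.
#' @param feature_col name of the first column (default `"feature_id"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, feature_col = "feature_id") {
  vals <- unclass(matrix)
  df <- data.frame(rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a GMT-like annotation file
#'
#' One term per line: `term_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return list with `annotation` (named list term -> members) and
#'   `term_names` (named character vector of descriptions).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  ann <- list(); nms <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("malformed GMT line %d in %s", i, path), call. = FALSE)
    }
    ann[[parts[1]]] <- parts[-(1:2)]
    nms[parts[1]] <- parts[2]
  }
  list(annotation = ann, term_names = nms)
}

#' Write a GMT-like annotation file
#'
#' @param annotation named list term -> members.
#' @param path output path.
#' @param term_names optional named descriptions (default: the term id).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotation, path, term_names = NULL) {
  lines <- vapply(names(annotation), function(tid) {
    desc <- if (!is.null(term_names)) term_names[[tid]] %||% tid else tid
    paste(c(tid, desc, annotation[[tid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an enrichment table to TSV
#'
#' Columns follow the conventional report order (term, margins, pval, padj,
#' enrichment score). The score is formatted with 4 fixed decimals; the
#' full-precision value is kept in `enrichment_score_full`.
#'
#' @param table an `enrichment_table` from [hypergeom_ora()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(table, path) {
  df <- as.data.frame(table)
  df$enrichment_score_full <- df$enrichment_score
  df$enrichment_score <- sprintf("%.4f", df$enrichment_score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scan hits to TSV
#'
#' Transcript coordinates are converted to 1-based inclusive for the report
#' (internally 0-based half-open); a header comment records the convention.
#'
#' @param hits a `transcript_hits` data.frame from [hamming_search()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  df <- as.data.frame(hits)
  df$t_start_1based <- df$t_start + 1L
  df$t_end_1based <- df$t_end          # half-open end == 1-based incl. end
  df$t_start <- NULL; df$t_end <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive on the transcript", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML with a `design` block (`lines`, `roles`, `replicates_per_line`,
#' `seed`) and optional stage parameter blocks. Unknown top-level keys are
#' rejected.
#'
#' @param path YAML path.
#' @return list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("design", "dsrna", "transcriptome", "reads", "expression",
             "metabolome", "annotation", "scan", "deg", "dam",
             "multivariate", "enrichment", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$design)) stop("configuration needs a design block",
                                call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}
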