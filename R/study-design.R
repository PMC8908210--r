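#' Study design: lines, roles and replication
#'
#' Describes a multi-line equivalence study: a set of genetically engineered
#' (GE) lines, the single parental line they were transformed from, and
#' conventional breeding lines used as the natural-variation reference. The
#' default is the six-line maize design with three GE lines, one parent and
#' two related conventional lines, each with three biological replicates.
#'
#' @param lines character vector of unique line identifiers.
#' @param roles named character vector mapping every line to one of
#'   `"ge"`, `"parent"`, `"conventional"`.
#' @param replicates_per_line integer >= 2, biological replicates per line.
#' @param seed integer seed recorded with the design (used by generators that
#'   take the design as their parameterisation).
#' @return an object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$lines
#' sample_ids(d)[1:6]
#' @export
study_design <- function(lines = c("DTS_108", "DTS_123", "DTS_127",
                                   "TJ806", "AR02", "AR03"),
                         roles = c(DTS_108 = "ge", DTS_123 = "ge",
                                   DTS_127 = "ge", TJ806 = "parent",
                                   AR02 = "conventional", AR03 = "conventional"),
                         replicates_per_line = 3L,
                         seed = 1L) {
  if (anyDuplicated(lines)) stop("line identifiers must be unique", call. = FALSE)
  if (!all(lines %in% names(roles))) {
    stop("every line needs a role in `roles`", call. = FALSE)
  }
  roles <- roles[lines]
  if (!all(roles %in% c("ge", "parent", "conventional"))) {
    stop("roles must be 'ge', 'parent' or 'conventional'", call. = FALSE)
  }
  if (any(roles == "ge") && sum(roles == "parent") != 1L) {
    stop("exactly one parent line is required when GE lines are present",
         call. = FALSE)
  }
  replicates_per_line <- as.integer(replicates_per_line)
  if (replicates_per_line < 2L) {
    stop("replicates_per_line must be >= 2", call. = FALSE)
  }
  structure(list(lines = lines, roles = roles,
                 replicates_per_line = replicates_per_line,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$lines), "lines x",
      x$replicates_per_line, "replicates\n")
  for (r in c("ge", "parent", "conventional")) {
    ln <- x$lines[x$roles == r]
    if (length(ln)) cat(sprintf("  %-12s %s\n", r, paste(ln, collapse = ", ")))
  }
  invisible(x)
}

#' Sample identifiers of a design
#'
#' Samples are named `<line>_<replicate>`, replicates numbered from 1.
#'
#' @param design a [study_design()].
#' @return character vector of length `n_lines * replicates_per_line`.
#' @export
sample_ids <- function(design) {
  stopifnot(inherits(design, "study_design"))
  as.vector(t(outer(design$lines, seq_len(design$replicates_per_line),
                    function(l, r) paste(l, r, sep = "_"))))
}

#' Map sample identifiers back to their line
#'
#' @param ids character vector of sample ids of the form `<line>_<rep>`.
#' @param design a [study_design()].
#' @return character vector of line names, same length as `ids`.
#' @export
sample_line <- function(ids, design) {
  stopifnot(inherits(design, "study_design"))
  line <- sub("_[0-9]+$", "", ids)
  bad <- !line %in% design$lines
  if (any(bad)) {
    stop(sprintf("sample id(s) do not resolve to a design line: %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  line
}

#' Features-by-samples omics matrix
#'
#' Thin container shared by the expression and metabolite stages: a numeric
#' matrix (features in rows, samples in columns, `NA` allowed for missing
#' metabolite intensities) whose column names resolve to lines of a study
#' design.
#'
#' @param values numeric matrix with feature-id rownames and
#'   `<line>_<rep>` colnames.
#' @param design a [study_design()].
#' @return an object of class `omics_matrix` (a matrix with a `design`
#'   attribute and per-column `line` attribute).
#' @export
omics_matrix <- function(values, design) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("feature ids must be present and unique", call. = FALSE)
  }
  if (is.null(colnames(values))) stop("sample ids required", call. = FALSE)
  line <- sample_line(colnames(values), design)
  structure(values, design = design, line = line,
            class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("omics_matrix:", nrow(x), "features x", ncol(x), "samples (",
      sum(is.na(x)), "missing cells )\n")
  invisible(x)
}

matrix_lines <- function(x) attr(x, "line")
matrix_design <- function(x) attr(x, "design")

## subset an omics_matrix to one line's replicate columns
line_columns <- function(x, line) {
  which(matrix_lines(x) == line)
}
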