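## Pairwise comparison design, Venn set logic and over-representation --------

#' Build the pairwise comparison design
#'
#' Enumerates all unordered line pairs of a study design and assigns each to
#' one of four comparison groups by the roles of its two lines:
#'
#' * group 1 — GE line vs parent,
#' * group 2 — conventional vs parent, and conventional vs conventional
#'   (the natural-variation reference),
#' * group 3 — GE vs GE,
#' * group 4 — GE vs conventional.
#'
#' With three GE lines, one parent and two conventional lines this yields
#' the 15 comparisons partitioned 3/3/3/6.
#'
#' @param design a [study_design()].
#' @return data.frame of class `comparison_design`: columns `line_a`,
#'   `line_b`, `label` (`"line_a/line_b"`), `group` (integer 1-4). GE lines
#'   are placed in `line_a` against parent/conventional lines; conventional
#'   lines in `line_a` against the parent.
#' @examples
#' cd <- build_design(study_design())
#' table(cd$group)  # 3 3 3 6
#' @export
build_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  if (length(design$lines) < 2) stop("need >= 2 lines", call. = FALSE)
  roles <- design$roles
  pairs <- t(combn(design$lines, 2))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    ra <- roles[[a]]; rb <- roles[[b]]
    if (is.na(ra) || is.na(rb)) stop("missing role", call. = FALSE)
    key <- paste(sort(c(ra, rb)), collapse = "-")
    group <- switch(key,
                    "ge-parent" = 1L,
                    "conventional-parent" = 2L,
                    "conventional-conventional" = 2L,
                    "ge-ge" = 3L,
                    "conventional-ge" = 4L,
                    "parent-parent" = stop("two parent lines", call. = FALSE))
    ## convention: the derived/test line first, the reference line second
    first_roles <- c(ge = 1L, conventional = 2L, parent = 3L)
    if (first_roles[[ra]] > first_roles[[rb]] ||
        (ra == rb && a > b)) {
      tmp <- a; a <- b; b <- tmp
    }
    data.frame(line_a = a, line_b = b, label = paste(a, b, sep = "/"),
               group = group, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("comparison_design", "data.frame")
  out
}

#' Shared and unique members of 2-4 named sets
#'
#' Full disjoint Venn decomposition, matching the arity of the usual 2-4
#' set diagrams.
#'
#' @param sets named list of 2-4 character vectors.
#' @return object of class `set_summary`: list with `regions` (named list;
#'   names are `+`-joined set-membership signatures), `region_counts`,
#'   `shared_all` (intersection of all sets), `unique` (named list, each
#'   set minus the union of the others), `union_size`.
#' @examples
#' s <- shared_unique(list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(3, 4, 5)))
#' s$shared_all  # "3"
#' @export
shared_unique <- function(sets) {
  if (length(sets) < 2 || length(sets) > 4) {
    stop("between 2 and 4 sets are supported", call. = FALSE)
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be uniquely named", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  all_items <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) all_items %in% s,
                       logical(length(all_items)))
  if (length(all_items) == 1) membership <- matrix(membership, nrow = 1)
  sig <- apply(membership, 1, function(m) {
    paste(names(sets)[m], collapse = "+")
  })
  regions <- split(all_items, sig)
  shared_all <- all_items[rowSums(membership) == length(sets)]
  uniq <- lapply(seq_along(sets), function(i) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    setdiff(sets[[i]], others)
  })
  names(uniq) <- names(sets)
  out <- list(regions = regions,
              region_counts = vapply(regions, length, integer(1)),
              shared_all = shared_all, unique = uniq,
              union_size = length(all_items))
  class(out) <- "set_summary"
  out
}

#' @export
print.set_summary <- function(x, ...) {
  cat("Venn decomposition over", length(x$unique), "sets; union",
      x$union_size, "\n")
  for (n in names(x$region_counts)) {
    cat(sprintf("  %-24s %d\n", n, x$region_counts[[n]]))
  }
  invisible(x)
}

#' Fold-enrichment score
#'
#' Ratio of the list hit rate to the population hit rate:
#' `(ListHits/ListTotal) / (PopHits/PopTotal)`. A score of 1 means the term
#' is hit at exactly the background rate.
#'
#' @param list_hits,list_total,pop_hits,pop_total over-representation
#'   margins; `list_total`, `pop_hits` and `pop_total` must be positive.
#' @return numeric score (vectorised).
#' @examples
#' enrichment_score(2, 44, 49, 6694)  # 6.2096 (4 dp)
#' @export
enrichment_score <- function(list_hits, list_total, pop_hits, pop_total) {
  if (any(list_total <= 0) || any(pop_hits <= 0) || any(pop_total <= 0)) {
    stop("denominator counts must be positive", call. = FALSE)
  }
  (list_hits / list_total) / (pop_hits / pop_total)
}

#' Expected hits of a term in a list
#'
#' Hypergeometric mean: `list_total * pop_hits / pop_total`.
#'
#' @inheritParams enrichment_score
#' @return expected hit count.
#' @examples
#' expected_hits(44, 49, 6694)  # 0.3221 (4 dp)
#' @export
expected_hits <- function(list_total, pop_hits, pop_total) {
  if (any(pop_total <= 0)) stop("pop_total must be positive", call. = FALSE)
  list_total * pop_hits / pop_total
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the feature list hits the term
#' more often than expected from the universe: upper-tail hypergeometric
#' `P(X >= ListHits)` with population `PopTotal`, successes `PopHits` and
#' draws `ListTotal`, BH-adjusted across terms within the list.
#'
#' The universe defaults to the features present in the annotation (terms
#' are restricted to it); the analysed list is intersected with the
#' universe.
#'
#' @param list_features character vector, the feature list (e.g. DEGs of one
#'   comparison).
#' @param annotation named list, term id -> member feature ids.
#' @param universe background feature ids; default: union of all annotated
#'   features.
#' @param term_names optional named character vector of display names.
#' @return data.frame of class `enrichment_table`, sorted by p-value:
#'   `term_id`, `term`, `ListHits`, `ListTotal`, `PopHits`, `PopTotal`,
#'   `pval`, `padj`, `enrichment_score` (`NA` when the term has no
#'   population hits).
#' @export
hypergeom_ora <- function(list_features, annotation, universe = NULL,
                          term_names = NULL) {
  if (is.null(universe)) {
    universe <- unique(unlist(annotation, use.names = FALSE))
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  lst <- intersect(unique(as.character(list_features)), universe)
  pop_total <- length(universe)
  list_total <- length(lst)
  rows <- lapply(names(annotation), function(tid) {
    members <- intersect(unique(annotation[[tid]]), universe)
    pop_hits <- length(members)
    list_hits <- length(intersect(lst, members))
    pval <- if (list_total == 0 || pop_hits == 0) 1 else
      phyper(list_hits - 1, pop_hits, pop_total - pop_hits, list_total,
             lower.tail = FALSE)
    es <- if (pop_hits > 0 && list_total > 0) {
      enrichment_score(list_hits, list_total, pop_hits, pop_total)
    } else NA_real_
    data.frame(term_id = tid,
               term = if (!is.null(term_names)) term_names[[tid]] %||% tid else tid,
               ListHits = list_hits, ListTotal = list_total,
               PopHits = pop_hits, PopTotal = pop_total,
               pval = pval, enrichment_score = es,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), term = character(0),
                      ListHits = integer(0), ListTotal = integer(0),
                      PopHits = integer(0), PopTotal = integer(0),
                      pval = numeric(0), enrichment_score = numeric(0))
  }
  out$padj <- bh_adjust(out$pval)
  out <- out[order(out$pval, out$term_id),
             c("term_id", "term", "ListHits", "ListTotal", "PopHits",
               "PopTotal", "pval", "padj", "enrichment_score")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
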