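## End-to-end orchestration ---------------------------------------------------

#' Default pipeline configuration (synthetic study)
#'
#' Parameterises a fully synthetic run shaped like the motivating maize
#' study: an 876-nt dsRNA, a transcript set with planted off-target sites at
#' Hamming distances 0-3, 21-nt-dominated small-RNA reads, and 6-line x
#' 3-replicate expression/metabolite matrices with planted differential
#' features and one over-represented pathway term.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  cfg <- list(
    design = list(seed = seed),
    dsrna = list(length = 876L, gc_fraction = 0.5),
    transcriptome = list(n_transcripts = 60L, length_range = c(200L, 400L),
                         planted = list(c(21L, 0L), c(21L, 1L), c(21L, 2L),
                                        c(21L, 3L))),
    reads = list(n_reads = 4000L,
                 length_weights = c("21" = 0.7, "22" = 0.15, "23" = 0.1,
                                    "24" = 0.05),
                 background_fraction = 0.05),
    expression = list(n_features = 400L,
                      planted = list(list(line = "DTS_108", n_de = 8L,
                                          log2fc = 3),
                                     list(line = "AR02", n_de = 30L,
                                          log2fc = 3),
                                     list(line = "AR03", n_de = 20L,
                                          log2fc = -3))),
    metabolome = list(n_features = 300L, missing_rate = 0.1,
                      planted = list(list(line = "DTS_123", n_de = 6L,
                                          log2fc = 3),
                                     list(line = "AR02", n_de = 15L,
                                          log2fc = 3))),
    annotation = list(n_terms = 20L, overdraw = 6L),
    scan = list(max_mm = 2L, mode = "all_mock"),
    deg = list(padj_threshold = 0.05, fc_up = 2, fc_down = 0.5),
    dam = list(fc_threshold = 2, p_threshold = 0.05),
    enrichment = list(),
    output_dir = NULL)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> mock library -> off-target scan -> siRNA profile ->
#' DEG -> DAM -> multivariate -> Venn -> enrichment as configured. When
#' `output_dir` is set every artifact is written (FASTA, FASTQ, TSV, GMT,
#' Newick) together with a JSON manifest of inputs, parameters and seed;
#' reruns with the same seed are byte-identical.
#'
#' @param config a `pipeline_config`, e.g. [default_config()] or
#'   [read_config()].
#' @param output_dir optional directory for artifacts (overrides the config
#'   entry).
#' @return list of class `pipeline_result` with all stage outputs and
#'   planted truths.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  ## two-level merge: user entries replace defaults wholesale at the
  ## stage-parameter level (a user-supplied `planted` list is not spliced
  ## into the default one)
  cfg <- unclass(default_config())
  user <- unclass(config)
  for (stage in names(user)) {
    if (is.list(user[[stage]]) && is.list(cfg[[stage]])) {
      for (key in names(user[[stage]])) {
        cfg[[stage]][[key]] <- user[[stage]][[key]]
      }
    } else {
      cfg[[stage]] <- user[[stage]]
    }
  }
  seed <- as.integer(cfg$design$seed %||% 1L)
  output_dir <- output_dir %||% cfg$output_dir

  design <- study_design(seed = seed)
  if (!is.null(cfg$design$lines)) {
    design <- study_design(lines = cfg$design$lines,
                           roles = unlist(cfg$design$roles),
                           replicates_per_line =
                             cfg$design$replicates_per_line %||% 3L,
                           seed = seed)
  }

  ## --- simulate -------------------------------------------------------
  dsrna <- gen_dsrna(cfg$dsrna$length, cfg$dsrna$gc_fraction, seed = seed)
  txome <- gen_transcriptome(cfg$transcriptome$n_transcripts,
                             cfg$transcriptome$length_range, dsrna,
                             planted = cfg$transcriptome$planted,
                             seed = seed + 1L)
  reads <- gen_srna_reads(dsrna, cfg$reads$n_reads,
                          length_weights = unlist(cfg$reads$length_weights),
                          background_fraction = cfg$reads$background_fraction,
                          seed = seed + 2L)
  expr <- gen_expression_study(design, cfg$expression$n_features,
                               planted = cfg$expression$planted,
                               seed = seed + 3L)
  metab <- gen_metabolome_study(design, cfg$metabolome$n_features,
                                planted = cfg$metabolome$planted,
                                missing_rate = cfg$metabolome$missing_rate,
                                seed = seed + 4L)

  ## --- mock library and off-target scan -------------------------------
  kmers <- enumerate_kmers(dsrna, 21L, 24L, both_strands = TRUE)
  hits <- hamming_search(kmers, txome$transcripts, max_mm = cfg$scan$max_mm)
  profile <- sirna_profile(reads, dsrna)
  expressed <- unique(as.data.frame(profile$alignments)$sequence)
  report <- combine_offtargets(hits, expressed_sirnas = expressed,
                               mode = cfg$scan$mode)

  ## --- differential calling over the full comparison design -----------
  comparisons <- build_design(design)
  degs <- lapply(seq_len(nrow(comparisons)), function(i) {
    call_degs(expr$matrix, c(comparisons$line_a[i], comparisons$line_b[i]),
              padj_threshold = cfg$deg$padj_threshold,
              fc_up = cfg$deg$fc_up, fc_down = cfg$deg$fc_down)
  })
  names(degs) <- comparisons$label
  metab_f <- missing_value_filter(metab$matrix)
  dams <- lapply(seq_len(nrow(comparisons)), function(i) {
    call_dams(metab_f, c(comparisons$line_a[i], comparisons$line_b[i]),
              fc_threshold = cfg$dam$fc_threshold,
              p_threshold = cfg$dam$p_threshold)
  })
  names(dams) <- comparisons$label

  ## --- multivariate ----------------------------------------------------
  expr_log <- log2(unclass(expr$matrix) + 1)
  pca_expr <- pca_model(expr_log, n_components = 2L)
  hc_expr <- hcluster(expr_log, distance = "correlation")
  metab_complete <- unclass(metab_f)
  metab_complete <- metab_complete[complete.cases(metab_complete), ,
                                   drop = FALSE]
  scaled <- pareto_scale(log2(metab_complete + 1))
  ge_or_parent <- matrix_lines(metab_f) %in%
    design$lines[design$roles != "conventional"]
  opls <- oplsda(scaled$values,
                 ifelse(ge_or_parent, "ge_parent", "conventional"))

  ## --- Venn + enrichment ----------------------------------------------
  group1 <- comparisons$label[comparisons$group == 1]
  deg_sets <- lapply(degs[group1],
                     function(d) d$feature_id[d$call])
  venn_g1 <- shared_unique(deg_sets)
  union_g1 <- unique(unlist(deg_sets, use.names = FALSE))
  ann <- gen_annotation(rownames(expr$matrix), cfg$annotation$n_terms,
                        planted_term = list(term_id = "planted_term",
                                            overdraw = cfg$annotation$overdraw),
                        list_features = if (length(union_g1)) union_g1 else
                          rownames(expr$matrix)[1:10],
                        seed = seed + 5L)
  enr <- hypergeom_ora(union_g1, ann$annotation,
                       universe = rownames(expr$matrix))

  result <- list(design = design, dsrna = dsrna, transcriptome = txome,
                 reads = reads, expression = expr, metabolome = metab,
                 kmers = kmers, hits = hits, profile = profile,
                 offtarget_report = report, comparisons = comparisons,
                 degs = degs, dams = dams, pca = pca_expr,
                 hclust = hc_expr, oplsda = opls, venn_group1 = venn_g1,
                 annotation = ann, enrichment = enr, seed = seed,
                 config = cfg)
  class(result) <- "pipeline_result"

  if (!is.null(output_dir)) {
    write_pipeline_outputs(result, output_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (seed", x$seed, ")\n")
  cat("  mock library:", nrow(x$kmers), "positioned k-mers\n")
  cat("  off-target transcripts:", nrow(x$offtarget_report$per_transcript),
      "\n")
  cat("  comparisons:", nrow(x$comparisons), "in",
      length(unique(x$comparisons$group)), "groups\n")
  cat("  DEG calls:", sum(vapply(x$degs, function(d) sum(d$call), 1)),
      "across comparisons\n")
  cat("  DAM calls:", sum(vapply(x$dams, function(d) sum(d$call), 1)),
      "across comparisons\n")
  invisible(x)
}

## Write every artifact plus a manifest; deterministic given the seed.
write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  write_fasta(setNames(result$dsrna$sequence, result$dsrna$id),
              p("dsrna.fasta"))
  write_fasta(result$transcriptome$transcripts, p("transcripts.fasta"))
  write_fastq(result$reads, p("reads.fastq"))
  write_matrix(result$expression$matrix, p("expression.tsv"))
  write_matrix(result$metabolome$matrix, p("metabolome.tsv"))
  write_hits(result$hits, p("offtarget_hits.tsv"))
  write_gmt(result$annotation$annotation, p("annotation.gmt"))
  write_enrichment(result$enrichment, p("enrichment.tsv"))
  for (lab in names(result$degs)) {
    safe <- gsub("/", "_vs_", lab, fixed = TRUE)
    write.table(result$degs[[lab]], p(paste0("deg_", safe, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(dendrogram_newick(result$hclust), p("expression_dendrogram.nwk"))
  sizes <- result$profile$size_distribution
  write.table(data.frame(length = names(sizes), count = as.integer(sizes)),
              p("sirna_size_distribution.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(seed = result$seed,
                   package_version =
                     as.character(utils::packageVersion("siromics")),
                   parameters = result$config[setdiff(names(result$config),
                                                      "output_dir")],
                   coordinate_convention =
                     "0-based half-open internal, 1-based inclusive in reports",
                   artifacts = sort(list.files(output_dir)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(output_dir)
}
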