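## Univariate statistics shared by the expression and metabolite stages ------

#' FPKM normalisation
#'
#' Fragments per kilobase of feature per million mapped fragments:
#' `count * 1e9 / (library_size * feature_length)`.
#'
#' @param count fragment count(s) for the feature.
#' @param feature_length feature length in bp, > 0.
#' @param library_size total mapped fragments in the library, > 0.
#' @return FPKM value(s).
#' @examples
#' fpkm(10, 1000, 1e6)  # 10
#' @export
fpkm <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0)) stop("feature_length must be > 0", call. = FALSE)
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  count * 1e9 / (library_size * feature_length)
}

#' Relative expression by the 2^-ddCt method
#'
#' Target-gene qPCR expression normalised to a reference gene and a
#' calibrator sample: `2^-((Ct_t,s - Ct_r,s) - (Ct_t,c - Ct_r,c))`.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and reference
#'   gene in the calibrator.
#' @return relative expression (1 when sample equals calibrator).
#' @examples
#' ddct_relative_expression(20, 18, 24, 20)  # 4
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Two-group test on replicate values
#'
#' Two-sided t-test between replicate groups. `"student_log2"` (default for
#' intensity screens) tests `log2(x + pseudocount)` with the classical
#' pooled-variance statistic — with equal small replicate numbers per line
#' the pooled t is exactly calibrated, where Welch's Satterthwaite
#' approximation is conservative at n = 3. `"welch_log2"` uses the
#' unequal-variance statistic on the same transform; `"student"` is the
#' pooled t on the raw values (the qPCR verification convention).
#' Degenerate inputs (fewer than two finite values in a group, or zero
#' variance in both groups) yield `p = 1` with a `degenerate` flag rather
#' than an error, so feature-wise screens never abort.
#'
#' @param values_a,values_b numeric replicate vectors (NA allowed, dropped).
#' @param mode `"student_log2"`, `"welch_log2"` or `"student"`.
#' @param pseudocount added before the log2 transform in the `_log2` modes.
#' @return list with `p_value` and `degenerate` flag.
#' @export
group_test <- function(values_a, values_b,
                       mode = c("student_log2", "welch_log2", "student"),
                       pseudocount = 1) {
  mode <- match.arg(mode)
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    return(list(p_value = 1, degenerate = TRUE))
  }
  if (mode %in% c("student_log2", "welch_log2")) {
    a <- log2(a + pseudocount)
    b <- log2(b + pseudocount)
  }
  if (var(a) == 0 && var(b) == 0) {
    ## identical flat groups: no evidence either way
    return(list(p_value = 1, degenerate = TRUE))
  }
  p <- t.test(a, b, var.equal = mode != "welch_log2")$p.value
  list(p_value = p, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order (monotone step-up, capped at
#'   1).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

## Fold change of group means with stage-appropriate zero handling.
fold_change <- function(mean_a, mean_b, pseudo) {
  (mean_a + pseudo) / (mean_b + pseudo)
}

## Shared differential caller. `call_rule` receives (fc, p, padj) vectors.
differential_table <- function(matrix, line_a, line_b, mode, pseudocount) {
  design <- matrix_design(matrix)
  for (ln in c(line_a, line_b)) {
    if (!ln %in% design$lines) stop("unknown line: ", ln, call. = FALSE)
  }
  ca <- line_columns(matrix, line_a)
  cb <- line_columns(matrix, line_b)
  if (length(ca) < 2 || length(cb) < 2) {
    stop("each line needs >= 2 replicates", call. = FALSE)
  }
  vals <- unclass(matrix)
  mean_a <- rowMeans(vals[, ca, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(vals[, cb, drop = FALSE], na.rm = TRUE)
  p <- vapply(seq_len(nrow(vals)), function(i) {
    group_test(vals[i, ca], vals[i, cb], mode = mode,
               pseudocount = pseudocount)$p_value
  }, numeric(1))
  fc <- fold_change(mean_a, mean_b, 0)
  ## undefined means (all-missing group) give NaN fold changes; keep as NA
  fc[!is.finite(fc)] <- NA_real_
  data.frame(feature_id = rownames(vals),
             comparison = paste(line_a, line_b, sep = "/"),
             fold_change = fc, log2fc = log2(fc), p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially expressed genes
#'
#' For one pairwise line comparison: fold change of group mean FPKM, pooled
#' t on `log2(FPKM + 1)`, BH adjustment over the comparison's full feature
#' set, and the call `padj < padj_threshold AND (FC >= fc_up OR FC <=
#' fc_down)` — the fold-change bounds are inclusive at this stage.
#'
#' @param matrix an [omics_matrix()] of expression values.
#' @param comparison length-2 character vector `c(line_a, line_b)`; fold
#'   change is `line_a / line_b`.
#' @param padj_threshold adjusted-p cutoff (default 0.05).
#' @param fc_up,fc_down inclusive fold-change bounds (defaults 2 and 0.5).
#' @param mode test passed to [group_test()] (default `"student_log2"`).
#' @param pseudocount for the log transform (default 1, FPKM scale).
#' @return data.frame: feature_id, comparison, fold_change, log2fc, p_value,
#'   p_adjusted, call.
#' @export
call_degs <- function(matrix, comparison, padj_threshold = 0.05, fc_up = 2,
                      fc_down = 0.5, mode = "student_log2", pseudocount = 1) {
  tab <- differential_table(matrix, comparison[1], comparison[2], mode,
                            pseudocount)
  tab$p_adjusted <- bh_adjust(tab$p_value)
  fc_ok <- !is.na(tab$fold_change) &
    (tab$fold_change >= fc_up | tab$fold_change <= fc_down)
  tab$call <- tab$p_adjusted < padj_threshold & fc_ok
  tab
}

#' Missing-value filter for metabolite matrices
#'
#' Deletes a feature iff in at least one replicate group its missing
#' fraction exceeds `max_missing` (strict `>`; the conventional rule deletes
#' ion peaks with more than 50% missing values within a group).
#'
#' @param matrix an [omics_matrix()] with possible `NA` cells.
#' @param max_missing maximum tolerated within-group missing fraction
#'   (default 0.5).
#' @return the filtered [omics_matrix()].
#' @export
missing_value_filter <- function(matrix, max_missing = 0.5) {
  design <- matrix_design(matrix)
  lines <- matrix_lines(matrix)
  vals <- unclass(matrix)
  drop <- rep(FALSE, nrow(vals))
  for (ln in design$lines) {
    cols <- which(lines == ln)
    frac <- rowMeans(is.na(vals[, cols, drop = FALSE]))
    drop <- drop | frac > max_missing
  }
  omics_matrix(vals[!drop, , drop = FALSE], design)
}

#' Accurate-mass match in parts per million
#'
#' @param observed_mass,theoretical_mass positive masses (Da).
#' @param tolerance ppm tolerance; match iff `ppm < tolerance` (strict).
#' @return list with `ppm` and logical `match`.
#' @examples
#' ppm_match(500.0050, 500.0000)  # 10 ppm, match
#' @export
ppm_match <- function(observed_mass, theoretical_mass, tolerance = 25) {
  if (any(observed_mass <= 0) || any(theoretical_mass <= 0)) {
    stop("masses must be > 0", call. = FALSE)
  }
  ppm <- abs(observed_mass - theoretical_mass) / theoretical_mass * 1e6
  ## strict <, with the boundary decided to double precision: a mass pair
  ## sitting exactly at the tolerance is not a match
  list(ppm = ppm, match = (tolerance - ppm) > tolerance * 1e-9)
}

#' Call differentially accumulated metabolites
#'
#' For one pairwise comparison on a missing-value-filtered intensity matrix:
#' the call is `(FC > fc_threshold OR FC < 1/fc_threshold) AND raw p <
#' p_threshold` — strict fold-change bounds at this stage, and the raw
#' p-value rather than the adjusted one. Optionally attaches OPLS-DA VIP
#' values (annotation only; VIP does not enter the call).
#'
#' @param matrix an [omics_matrix()] of metabolite intensities (apply
#'   [missing_value_filter()] first).
#' @param comparison length-2 character vector `c(line_a, line_b)`.
#' @param fc_threshold strict fold-change bound (default 2).
#' @param p_threshold raw-p cutoff (default 0.05).
#' @param two_sided also call depletion (`FC < 1/fc_threshold`); default
#'   TRUE.
#' @param vip optional named numeric vector of VIP values, e.g. from
#'   [oplsda()]; matched by feature id.
#' @param mode,pseudocount test configuration; the default pseudocount
#'   (`NULL`) uses half the smallest positive intensity in the matrix.
#' @return data.frame: feature_id, comparison, fold_change, log2fc, p_value,
#'   p_adjusted (BH, reported for reference), vip (if given), call.
#' @export
call_dams <- function(matrix, comparison, fc_threshold = 2, p_threshold = 0.05,
                      two_sided = TRUE, vip = NULL, mode = "student_log2",
                      pseudocount = NULL) {
  if (is.null(pseudocount)) {
    v <- unclass(matrix)
    pos <- v[is.finite(v) & v > 0]
    pseudocount <- if (length(pos)) min(pos) / 2 else 1
  }
  tab <- differential_table(matrix, comparison[1], comparison[2], mode,
                            pseudocount)
  tab$p_adjusted <- bh_adjust(tab$p_value)
  fc_ok <- !is.na(tab$fold_change) & (tab$fold_change > fc_threshold |
    (two_sided & tab$fold_change < 1 / fc_threshold))
  tab$call <- fc_ok & tab$p_value < p_threshold
  if (!is.null(vip)) tab$vip <- unname(vip[tab$feature_id])
  tab
}
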