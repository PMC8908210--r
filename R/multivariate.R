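## Pattern-recognition stages -------------------------------------------------

#' Pareto scaling
#'
#' Per feature (row): centre on the mean and divide by the square root of
#' the sample standard deviation — the compromise between unit-variance and
#' mean-centred scaling conventional for mass-spectrometry intensities.
#' Zero-variance features scale to zeros and are flagged. Means and scale
#' factors are retained so the input can be recomposed exactly.
#'
#' @param matrix numeric matrix, features in rows, samples in columns (an
#'   [omics_matrix()] works; `NA` cells are not allowed — impute or filter
#'   first).
#' @return object of class `pareto_scaled`: list with `values` (scaled
#'   matrix), `center`, `scale` (per-feature `sqrt(sd)`, 1 for flat
#'   features), `flat` (logical, zero-variance features).
#' @examples
#' ps <- pareto_scale(matrix(c(1, 2, 3), 1, 3, dimnames = list("f", NULL)))
#' ps$values  # -1 0 1
#' @export
pareto_scale <- function(matrix) {
  x <- unclass(matrix)
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(x)) stop("missing cells: impute or filter before scaling",
                     call. = FALSE)
  ctr <- rowMeans(x)
  sds <- apply(x, 1, sd)
  flat <- sds == 0
  scl <- sqrt(sds)
  scl[flat] <- 1
  if (any(flat)) {
    warning(sum(flat), " zero-variance feature(s) scaled to zeros")
  }
  out <- list(values = (x - ctr) / scl, center = ctr, scale = scl,
              flat = flat)
  class(out) <- "pareto_scaled"
  out
}

#' Invert a Pareto scaling
#'
#' @param scaled a `pareto_scaled` object.
#' @return the original matrix (`values * scale + center`).
#' @export
pareto_unscale <- function(scaled) {
  stopifnot(inherits(scaled, "pareto_scaled"))
  scaled$values * scaled$scale + scaled$center
}

#' Principal component analysis of a samples-in-columns matrix
#'
#' SVD of the column-centred, transposed matrix (samples become rows, as in
#' score plots of omics QC). Loading signs are fixed by making each loading
#' vector's largest-magnitude entry positive, so results are deterministic.
#'
#' @param matrix numeric matrix, features x samples.
#' @param n_components number of components to retain (default all).
#' @return object of class `latent_model`: list with `scores` (samples x
#'   components), `loadings` (features x components), `explained_variance`
#'   (fractions), `total_variance`.
#' @export
pca_model <- function(matrix, n_components = NULL) {
  x <- t(unclass(matrix))                     # samples x features
  if (nrow(x) < 2) stop("need >= 2 samples", call. = FALSE)
  rank <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    warning("n_components exceeds the matrix rank; truncated to ", rank)
    n_components <- rank
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  load <- fit$rotation[, keep, drop = FALSE]
  scores <- fit$x[, keep, drop = FALSE]
  ## deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total <- sum(fit$sdev^2)
  out <- list(scores = scores, loadings = load,
              explained_variance = fit$sdev[keep]^2 / total,
              total_variance = total)
  class(out) <- "latent_model"
  out
}

#' @export
print.latent_model <- function(x, ...) {
  cat("Latent model:", ncol(x$scores), "component(s),", nrow(x$scores),
      "samples\n")
  ev <- x$explained_variance
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * ev), collapse = ", "), "\n")
  if (!is.null(x$vip)) {
    cat(sprintf("  VIP over %d features (mean VIP^2 = %.6f)\n",
                length(x$vip), mean(x$vip^2)))
  }
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the columns of an intensity matrix, with
#' Euclidean or correlation (1 - Pearson) distance and average or complete
#' linkage. Columns are ordered lexicographically by id before clustering so
#' the result is invariant to input column order.
#'
#' @param matrix numeric matrix, features x samples.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"average"` or `"complete"`.
#' @return an [stats::hclust] object (labels are the sample ids).
#' @export
hcluster <- function(matrix, distance = c("euclidean", "correlation"),
                     linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- unclass(matrix)
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  x <- x[, order(colnames(x)), drop = FALSE]
  d <- if (distance == "euclidean") {
    dist(t(x))
  } else {
    as.dist(1 - cor(x))
  }
  if (anyNA(d)) stop("distances contain NA; filter or impute first",
                     call. = FALSE)
  hclust(d, method = linkage)
}

#' Dendrogram to Newick
#'
#' @param hc an [stats::hclust] object.
#' @return single Newick string with branch lengths.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' OPLS-DA with VIP scores
#'
#' Orthogonal partial least squares discriminant analysis for two classes:
#' `n_orthogonal` rounds of orthogonal signal correction remove
#' class-uncorrelated variation from X, then a single predictive PLS
#' component is fitted against the centred class vector. The variable
#' importance for the projection is computed on the predictive component,
#' `VIP_j = sqrt(p * w_j^2 * SSY / SSY) = sqrt(p) * |w_j| / ||w||`, so
#' `mean(VIP^2) = 1` by construction.
#'
#' Apply [pareto_scale()] (or another scaling) upstream; the fit only
#' centres columns.
#'
#' @param matrix numeric matrix, features x samples.
#' @param class_labels factor-like vector over exactly 2 classes, one entry
#'   per sample (column).
#' @param n_orthogonal number of orthogonal components removed (default 1).
#' @return object of class `c("oplsda", "latent_model")`: `scores`
#'   (predictive then orthogonal component scores per sample), `loadings`,
#'   `weights` (predictive weights), `vip` (named by feature),
#'   `explained_variance` (fraction of X variance per retained component),
#'   `classes`, `class_labels`.
#' @export
oplsda <- function(matrix, class_labels, n_orthogonal = 1L) {
  x <- t(unclass(matrix))                     # samples x features
  cls <- as.factor(class_labels)
  if (nlevels(cls) != 2) stop("exactly 2 classes required", call. = FALSE)
  if (any(table(cls) < 2)) stop("each class needs >= 2 samples", call. = FALSE)
  if (length(cls) != nrow(x)) stop("one class label per sample required",
                                   call. = FALSE)
  y <- as.numeric(cls == levels(cls)[2])
  y <- y - mean(y)
  x_center <- colMeans(x)
  xc <- sweep(x, 2, x_center)
  total_var <- sum(xc^2)
  normalize <- function(v) v / sqrt(sum(v^2))

  t_orth <- list(); p_orth <- list(); w_orth <- list()
  for (a in seq_len(n_orthogonal)) {
    w <- normalize(drop(crossprod(xc, y)))
    tt <- drop(xc %*% w)
    p <- drop(crossprod(xc, tt)) / sum(tt^2)
    wo <- p - drop(crossprod(w, p)) * w
    if (sqrt(sum(wo^2)) < 1e-12) break       # no orthogonal variation left
    wo <- normalize(wo)
    to <- drop(xc %*% wo)
    po <- drop(crossprod(xc, to)) / sum(to^2)
    xc <- xc - tcrossprod(to, po)
    t_orth[[a]] <- to; p_orth[[a]] <- po; w_orth[[a]] <- wo
  }
  w <- normalize(drop(crossprod(xc, y)))
  tp <- drop(xc %*% w)
  pp <- drop(crossprod(xc, tp)) / sum(tp^2)

  p_feat <- ncol(x)
  vip <- sqrt(p_feat) * abs(w) / sqrt(sum(w^2))
  names(vip) <- colnames(x)

  scores <- cbind(predictive = tp)
  loadings <- cbind(predictive = pp)
  if (length(t_orth)) {
    for (a in seq_along(t_orth)) {
      scores <- cbind(scores, t_orth[[a]])
      loadings <- cbind(loadings, p_orth[[a]])
      colnames(scores)[ncol(scores)] <- paste0("orthogonal", a)
      colnames(loadings)[ncol(loadings)] <- paste0("orthogonal", a)
    }
  }
  rownames(scores) <- rownames(x)
  ## explained X variance per component: ||t p'||^2 / ||X||^2
  ev <- vapply(seq_len(ncol(scores)), function(j) {
    sum(tcrossprod(scores[, j], loadings[, j])^2) / total_var
  }, numeric(1))
  out <- list(scores = scores, loadings = loadings, weights = w, vip = vip,
              explained_variance = ev, classes = levels(cls),
              class_labels = cls, x_center = x_center)
  class(out) <- c("oplsda", "latent_model")
  out
}

#' Extract VIP scores
#'
#' @param model an [oplsda()] fit.
#' @return named numeric vector of VIP values (mean of squares is 1).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  model$vip
}

#' @export
coef.oplsda <- function(object, ...) {
  ## regression-style weights of the predictive component
  setNames(object$weights, names(object$vip))
}

#' @export
predict.oplsda <- function(object, newdata, ...) {
  ## predictive-component score of new samples (columns of newdata),
  ## centred by the training means
  x <- t(unclass(newdata))
  drop(sweep(x, 2, object$x_center) %*% object$weights)
}
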