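test_that("Pareto scaling matches the definition and recomposes exactly", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("f", c("s1", "s2", "s3")))
  ps <- pareto_scale(m)
  expect_equal(unname(ps$values[1, ]), c(-1, 0, 1))  # mean 2, sd 1
  set.seed(3)
  big <- matrix(rlnorm(300), 30, 10,
                dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:10)))
  psb <- pareto_scale(big)
  expect_lt(max(abs(pareto_unscale(psb) - big)), 1e-9)
  # constant feature scales to zeros with a flag
  flat <- rbind(big, flatf = rep(5, 10))
  expect_warning(psf <- pareto_scale(flat), "zero-variance")
  expect_true(all(psf$values["flatf", ] == 0))
  expect_true(psf$flat[["flatf"]])
})

test_that("PCA explains variance correctly in degenerate geometries", {
  # collinear samples: PC1 carries 100%
  line <- outer(c(1, 2, 5), c(1, 2, 3, 4))
  dimnames(line) <- list(paste0("f", 1:3), paste0("s", 1:4))
  p1 <- pca_model(line)
  expect_equal(p1$explained_variance[1], 1)
  # two orthogonal equal-variance directions: 50/50
  sym <- rbind(f1 = c(1, -1, 1, -1), f2 = c(1, 1, -1, -1))
  colnames(sym) <- paste0("s", 1:4)
  p2 <- pca_model(sym)
  expect_equal(unname(p2$explained_variance), c(0.5, 0.5))
  # retained variances sum to the total; deterministic sign convention
  set.seed(9)
  x <- matrix(rnorm(120), 12, 10,
              dimnames = list(paste0("f", 1:12), paste0("s", 1:10)))
  pf <- pca_model(x)
  expect_equal(sum(pf$explained_variance), 1, tolerance = 1e-9)
  for (j in seq_len(ncol(pf$loadings))) {
    expect_gt(pf$loadings[which.max(abs(pf$loadings[, j])), j], 0)
  }
  expect_warning(pca_model(x, n_components = 50), "rank")
})

test_that("PCA separates backgrounds in a synthetic six-line study", {
  d <- study_design()
  # shared background effect in both conventional lines, as in a study where
  # the conventional material diverges from the transformation pedigree
  e <- gen_expression_study(d, 300,
                            planted = list(list(line = c("AR02", "AR03"),
                                                n_de = 40, log2fc = 2)),
                            seed = 12)
  p <- pca_model(log2(unclass(e$matrix) + 1), 2)
  conv <- sub("_[0-9]+$", "", rownames(p$scores)) %in% c("AR02", "AR03")
  # conventional lines separate from GE+parent on PC1 (positive silhouette)
  gap <- abs(mean(p$scores[conv, 1]) - mean(p$scores[!conv, 1]))
  spread <- max(sd(p$scores[conv, 1]), sd(p$scores[!conv, 1]))
  expect_gt(gap, 2 * spread)
})

test_that("hierarchical clustering is order-invariant and groups by signal", {
  m <- cbind(a1 = c(0, 0), a2 = c(0.1, 0), far = c(10, 10))
  rownames(m) <- c("f1", "f2")
  hc <- hcluster(m, distance = "euclidean", linkage = "average")
  expect_equal(hc$height[1], 0.1)
  first_pair <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first_pair, c("a1", "a2"))
  # identical profiles merge at height 0
  m0 <- cbind(x = c(1, 2), y = c(1, 2), z = c(5, 9))
  rownames(m0) <- c("f1", "f2")
  expect_equal(hcluster(m0)$height[1], 0)
  # column order does not change the tree
  perm <- m[, c(3, 1, 2)]
  expect_equal(hcluster(m)$merge, hcluster(perm)$merge)
  expect_equal(hcluster(m)$height, hcluster(perm)$height)
  expect_error(hcluster(m[, 1, drop = FALSE]), "samples")
})

test_that("six-line clustering puts GE lines with the parent", {
  d <- study_design()
  e <- gen_expression_study(d, 200,
                            planted = list(list(line = c("AR02", "AR03"),
                                                n_de = 30, log2fc = 2.5),
                                           list(line = "AR03", n_de = 10,
                                                log2fc = 1.5)),
                            seed = 22)
  # average replicates per line, cluster lines
  vals <- log2(unclass(e$matrix) + 1)
  lines <- sub("_[0-9]+$", "", colnames(vals))
  per_line <- sapply(unique(lines), function(l) {
    rowMeans(vals[, lines == l, drop = FALSE])
  })
  hc <- hcluster(per_line, distance = "correlation")
  k2 <- cutree(hc, 2)
  expect_equal(length(unique(k2[c("DTS_108", "DTS_123", "DTS_127",
                                  "TJ806")])), 1)
  expect_false(k2[["AR02"]] == k2[["TJ806"]])
  # Newick export round-trips through ape
  nwk <- dendrogram_newick(hc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, unique(lines))
})

test_that("OPLS-DA VIP satisfies its normalisation and ranks signal over noise", {
  set.seed(5)
  cls <- rep(c("a", "b"), each = 6)
  signal <- ifelse(cls == "a", -3, 3) + rnorm(12, sd = 0.1)
  noise <- matrix(rnorm(12 * 19), 19, 12)
  m <- rbind(sig = signal, noise)
  rownames(m) <- c("sig", paste0("n", 1:19))
  colnames(m) <- paste0("s", 1:12)
  fit <- oplsda(m, cls)
  v <- vip(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-9)
  expect_gt(v[["sig"]], 1)
  expect_true(all(v[["sig"]] > v[names(v) != "sig"]))
  # one-feature model: VIP forced to 1
  one <- m["sig", , drop = FALSE]
  expect_equal(unname(vip(oplsda(one, cls))), 1)
  expect_error(oplsda(m, rep("a", 12)), "2 classes")
  # scores of the predictive component separate the classes
  expect_gt(abs(mean(fit$scores[cls == "a", 1]) -
                  mean(fit$scores[cls == "b", 1])), 0)
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(8)
  cls <- rep(c("a", "b"), each = 5)
  m <- matrix(rnorm(10 * 8), 8, 10,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:10)))
  m["f1", ] <- m["f1", ] + ifelse(cls == "a", -2, 2)
  # with zero orthogonal components this is a one-component PLS-DA
  fit <- oplsda(m, cls, n_orthogonal = 0)
  ref <- mixOmics::plsda(t(m), factor(cls), ncomp = 1, scale = FALSE)
  ref_vip <- mixOmics::vip(ref)[, 1]
  expect_gt(cor(vip(fit)[names(ref_vip)], ref_vip), 0.99)
  expect_equal(which.max(vip(fit)), which.max(ref_vip[names(vip(fit))]))
})

test_that("shuffled class labels give a null VIP distribution around 1", {
  set.seed(13)
  m <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:10)))
  stats <- replicate(20, {
    cls <- sample(rep(c("a", "b"), each = 5))
    v <- vip(oplsda(m, cls))
    c(meansq = mean(v^2), mean = mean(v), max = max(v))
  })
  # mean VIP^2 is pinned at 1; mean VIP of an isotropic weight vector in
  # p = 30 dimensions sits near sqrt(2/pi) ~ 0.80
  expect_true(all(abs(stats["meansq", ] - 1) < 1e-9))
  expect_equal(mean(stats["mean", ]), sqrt(2 / pi), tolerance = 0.1)
  expect_lt(mean(stats["max", ]), 3.5)     # no consistently dominant feature
})
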