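# The six-line design and the published KEGG report margins exercised here
paper_lines <- c("DTS_108", "DTS_123", "DTS_127", "TJ806", "AR02", "AR03")

test_that("the six-line design yields the 15 labelled comparisons in 4 groups", {
  cd <- build_design(study_design())
  expect_equal(nrow(cd), 15)
  expect_equal(as.integer(table(cd$group)), c(3L, 3L, 3L, 6L))
  expect_setequal(cd$label[cd$group == 1],
                  c("DTS_108/TJ806", "DTS_123/TJ806", "DTS_127/TJ806"))
  expect_setequal(cd$label[cd$group == 2],
                  c("AR02/TJ806", "AR03/TJ806", "AR02/AR03"))
  expect_setequal(cd$label[cd$group == 3],
                  c("DTS_108/DTS_123", "DTS_108/DTS_127", "DTS_123/DTS_127"))
  expect_setequal(cd$label[cd$group == 4],
                  c("DTS_108/AR02", "DTS_123/AR02", "DTS_127/AR02",
                    "DTS_108/AR03", "DTS_123/AR03", "DTS_127/AR03"))
})

test_that("pair enumeration follows C(n, 2) and validates roles", {
  two <- study_design(lines = c("L1", "L2"),
                      roles = c(L1 = "conventional", L2 = "conventional"),
                      replicates_per_line = 2)
  expect_equal(nrow(build_design(two)), 1)
  for (n in 3:6) {
    lines <- paste0("L", 1:n)
    roles <- setNames(rep("conventional", n), lines)
    d <- study_design(lines = lines, roles = roles, replicates_per_line = 2)
    expect_equal(nrow(build_design(d)), choose(n, 2))
  }
  expect_error(study_design(lines = c("A", "B"),
                            roles = c(A = "ge", B = "ge")),
               "parent")
})

test_that("Venn decomposition partitions the union with correct regions", {
  s <- shared_unique(list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(3, 4, 5)))
  expect_equal(s$shared_all, "3")
  expect_equal(s$unique$A, "1")
  expect_equal(s$unique$B, character(0))
  expect_equal(s$unique$C, "5")
  expect_equal(sum(s$region_counts), s$union_size)

  same <- shared_unique(list(x = letters[1:3], y = letters[1:3]))
  expect_setequal(same$shared_all, letters[1:3])
  expect_equal(lengths(same$unique), c(x = 0L, y = 0L))

  disj <- shared_unique(list(x = "a", y = "b", z = "c", w = "d"))
  expect_equal(length(disj$shared_all), 0)
  expect_equal(lengths(disj$unique), c(x = 1L, y = 1L, z = 1L, w = 1L))

  expect_error(shared_unique(list(a = 1)), "2 and 4")
  expect_error(shared_unique(list(1:2, 2:3, 3:4, 4:5, 5:6)), "2 and 4")

  # regions are disjoint and reconstruct each input set
  set.seed(2)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- paste0("S", 1:4)
  dec <- shared_unique(sets)
  expect_equal(anyDuplicated(unlist(dec$regions)), 0)
  for (nm in names(sets)) {
    rebuilt <- unlist(dec$regions[grepl(nm, names(dec$regions))],
                      use.names = FALSE)
    expect_setequal(rebuilt, sets[[nm]])
  }
})

test_that("hypergeometric p-values match direct enumeration", {
  # 4 draws, 5 successes in a population of 10, all 4 hit
  ann <- list(term = paste0("g", 1:5))
  universe <- paste0("g", 1:10)
  res <- hypergeom_ora(paste0("g", 1:4), ann, universe)
  expect_equal(res$pval, 5 / 210, tolerance = 1e-12)
  expect_equal(res$pval, hyper_upper(4, 5, 10, 4), tolerance = 1e-12)

  # no hits: P(X >= 0) = 1
  res0 <- hypergeom_ora(paste0("g", 6:9), list(term = "g1"), universe)
  expect_equal(res0$ListHits, 0)
  expect_equal(res0$pval, 1)

  # oracle sweep over random margins
  set.seed(4)
  for (i in 1:20) {
    pop <- sample(20:60, 1)
    hits <- sample(3:10, 1)
    draws <- sample(5:15, 1)
    universe <- sprintf("u%02d", 1:pop)
    ann <- list(t = sample(universe, hits))
    lst <- sample(universe, draws)
    got <- hypergeom_ora(lst, ann, universe)
    k <- length(intersect(lst, ann$t))
    expect_equal(got$pval, hyper_upper(k, hits, pop, draws),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_ora("g1", list(t = "g1"), character(0)), "universe")
})

test_that("hypergeometric tail is monotone in the hit count", {
  ps <- vapply(0:10, hyper_upper, numeric(1), pop_hits = 15, pop_total = 100,
               draws = 10)
  got <- vapply(0:10, function(k) {
    phyper(k - 1, 15, 85, 10, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(got, ps, tolerance = 1e-12)
  expect_true(all(diff(got) <= 0))
  expect_true(all(got >= 0 & got <= 1))
})

test_that("enrichment score reproduces every published report row to 4 decimals", {
  rows <- rbind(
    c(2, 44, 49, 6694, 6.2096),    # ribosome biogenesis, GE vs parent
    c(26, 771, 112, 6694, 2.0155), # starch and sucrose metabolism
    c(2, 44, 15, 6694, 20.2848),   # ABC transporters
    c(4, 771, 7, 6694, 4.9613),    # monoterpenoid biosynthesis
    c(2, 63, 27, 6694, 7.8707),    # flavonoid biosynthesis
    c(5, 63, 145, 6694, 3.6639),   # phenylpropanoid biosynthesis
    c(21, 809, 74, 6694, 2.3481),  # glutathione metabolism
    c(2, 63, 16, 6694, 13.2817),   # diterpenoid biosynthesis
    c(6, 63, 202, 6694, 3.1561),   # plant hormone signal transduction
    c(8, 100, 145, 6694, 3.6932),  # phenylpropanoid, GE vs conventional
    c(3, 100, 24, 6694, 8.3675),   # photosynthesis antenna proteins
    c(3, 100, 34, 6694, 5.9065),   # cyanoamino acid metabolism
    c(5, 63, 112, 6694, 4.7435),   # starch and sucrose, GE vs conventional
    c(2, 63, 49, 6694, 4.3369),    # ribosome biogenesis, GE vs conventional
    c(7, 100, 112, 6694, 4.1838))  # starch and sucrose (half-up boundary)
  es <- enrichment_score(rows[, 1], rows[, 2], rows[, 3], rows[, 4])
  expect_true(all(abs(es - rows[, 5]) <= 5.05e-5))
  expect_equal(enrichment_score(5, 10, 50, 100), 1)
  expect_error(enrichment_score(1, 0, 5, 10), "positive")
})

test_that("enrichment score exceeds 1 exactly when the list rate beats background", {
  set.seed(6)
  for (i in 1:50) {
    lt <- sample(5:50, 1); pt <- sample(100:500, 1)
    lh <- sample(0:lt, 1); ph <- sample(1:pt, 1)
    es <- enrichment_score(lh, lt, ph, pt)
    expect_equal(es > 1, lh / lt > ph / pt)
  }
})

test_that("expected hit counts follow the hypergeometric mean", {
  expect_equal(round(expected_hits(44, 49, 6694), 4), 0.3221)
  expect_equal(expected_hits(10, 0, 500), 0)
  expect_equal(expected_hits(1, 500, 500), 1)
  # equals the mean of the corresponding hypergeometric distribution
  expect_equal(expected_hits(10, 15, 100),
               sum((0:10) * dhyper(0:10, 15, 85, 10)))
})

test_that("ORA ranks a planted over-drawn term first with BH across terms", {
  feats <- sprintf("f%03d", 1:400)
  lst <- sprintf("f%03d", 1:40)
  ann <- gen_annotation(feats, 25,
                        planted_term = list(term_id = "hot", overdraw = 15),
                        list_features = lst, seed = 3)
  res <- hypergeom_ora(lst, ann$annotation, universe = feats)
  expect_equal(res$term_id[1], "hot")
  expect_true(!is.unsorted(res$pval))
  expect_equal(res$padj, bh_adjust(res$pval), tolerance = 1e-12)
  expect_true(all(res$ListHits <= pmin(res$ListTotal, res$PopHits)))
  expect_true(all(res$PopHits <= res$PopTotal))
})
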