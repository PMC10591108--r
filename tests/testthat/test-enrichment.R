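# CERES dependency binning, Fisher exact enrichment, hypergeometric
# pathway enrichment and GMT round trips.

test_that("genes are binned by median score with lower-inclusive bins", {
  ceres <- rbind(gA = c(-0.5, -0.5, -0.6),
                 gB = c(-0.4, -0.4, -0.4),
                 gC = c(0.3, 0.4, 0.2),
                 gD = c(-1.9, -2.1, -1.8))
  bins <- bin_genes_by_ceres(ceres)
  expect_true("gA" %in% bins[["[-0.8,-0.4)"]])
  expect_true("gB" %in% bins[["[-0.4,0)"]])   # boundary goes up
  expect_true("gC" %in% bins$other)
  expect_true("gD" %in% bins[["[-2,-1.6)"]])

  ceres2 <- rbind(ceres, gE = c(NA, NA, NA))
  expect_warning(bins2 <- bin_genes_by_ceres(ceres2), "all-NA")
  expect_false("gE" %in% unlist(bins2))
})

test_that("bin assignment equals a median-then-bucket oracle", {
  set.seed(1)
  ceres <- matrix(runif(300, -2.5, 0.5), 60, 5,
                  dimnames = list(sprintf("g%02d", 1:60), NULL))
  bins <- bin_genes_by_ceres(ceres)
  med <- apply(ceres, 1, median)
  breaks <- seq(-2, 0, 0.4)
  for (g in rownames(ceres)) {
    want <- if (med[g] < -2 || med[g] >= 0) "other" else {
      i <- findInterval(med[g], breaks)
      sprintf("[%g,%g)", breaks[i], breaks[i + 1])
    }
    expect_true(g %in% bins[[want]])
  }
})

test_that("Fisher enrichment handles the exchangeable table and fold arithmetic", {
  universe <- sprintf("g%03d", 1:4)
  row <- fisher_enrichment(c("g001", "g002"), c("g001", "g003"), universe)
  expect_equal(row$p_value, 1)
  expect_equal(row$odds_ratio, 1)

  # overlap 10, target 100, annotated 20, universe 1000 -> fold 5
  universe <- sprintf("u%04d", 1:1000)
  target <- universe[1:100]
  annotated <- c(universe[1:10], universe[901:910])
  row2 <- fisher_enrichment(target, annotated, universe)
  expect_equal(row2$fold_enrichment, 5.0)
  expect_equal(row2$overlap, 10)

  expect_error(fisher_enrichment(character(), annotated, universe),
               "empty target")
  expect_error(fisher_enrichment(target, annotated, character()),
               "empty universe")
})

test_that("two-sided Fisher p matches enumeration and fisher.test", {
  for (N in 2:12) {
    parts <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    parts <- parts[rowSums(parts) <= N, ]
    for (i in seq_len(nrow(parts))) {
      a <- parts$a[i]; b <- parts$b[i]; c <- parts$c[i]
      d <- N - a - b - c
      if (a + b == 0) next  # empty target not meaningful
      p_impl <- epidriver:::fisher_two_sided_p(a, b, c, d)
      expect_equal(p_impl, bf_fisher_p(a, b, c, d), tolerance = 1e-12)
      p_ref <- stats::fisher.test(matrix(c(a, b, c, d), 2,
                                         byrow = TRUE))$p.value
      expect_equal(p_impl, min(1, p_ref), tolerance = 1e-7)
    }
  }
})

test_that("two-sided p dominates the observed-direction one-sided p", {
  set.seed(2)
  for (r in 1:30) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c <- sample(0:8, 1); d <- sample(0:8, 1)
    if (a + b == 0 || a + b + c + d == 0) next
    p2 <- epidriver:::fisher_two_sided_p(a, b, c, d)
    upper <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
    lower <- stats::phyper(a, a + c, b + d, a + b)
    expect_gte(p2 + 1e-12, min(upper, lower))
    expect_lte(p2, 1)
    expect_gt(p2, 0)
  }
})

test_that("zero-cell odds ratios are flagged, with optional correction", {
  universe <- sprintf("g%02d", 1:40)
  row <- fisher_enrichment(universe[1:5], universe[1:5], universe)
  expect_true(is.infinite(row$odds_ratio))
  expect_true(row$zero_cell)
  row_c <- fisher_enrichment(universe[1:5], universe[1:5], universe,
                             continuity = TRUE)
  expect_true(is.finite(row_c$odds_ratio))
})

test_that("hypergeometric enrichment matches direct summation", {
  universe <- sprintf("g%02d", 1:20)
  coll <- gene_set_collection(list(setA = universe[1:6],
                                   setB = universe[5:12],
                                   whole = universe),
                              universe = universe)
  target <- universe[c(1:4, 15)]
  res <- hypergeom_enrichment(target, coll)
  # direct summation oracle for setA: overlap 4, K 6, N 20, n 5
  direct <- sum(dhyper(4:5, 6, 14, 5))
  expect_equal(res$p_value[res$set_name == "setA"], direct,
               tolerance = 1e-12)
  expect_equal(res$p_value[res$set_name == "whole"], 1)
  expect_equal(res$gene_ratio[res$set_name == "setA"], 4 / 5)

  dup <- gene_set_collection(list(s1 = universe[1:6], s2 = universe[1:6]),
                             universe = universe)
  res2 <- hypergeom_enrichment(target, dup)
  expect_equal(res2$p_value[1], res2$p_value[2])
  expect_equal(res2$fdr[1], res2$fdr[2])

  expect_error(hypergeom_enrichment("absent", coll), "disjoint")
})

test_that("universe against itself has fold enrichment 1", {
  universe <- sprintf("g%02d", 1:30)
  row <- fisher_enrichment(universe, universe, universe)
  expect_equal(row$fold_enrichment, 1)
})

test_that("GMT files round-trip", {
  coll <- gene_set_collection(list(one = c("a", "b"), two = c("c", "d", "e")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path)
  expect_equal(back$sets, coll$sets)
  expect_setequal(back$universe, coll$universe)
  writeLines("badline\tonly-two-fields", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("the planted gene set wins the collection on synthetic assets", {
  wins <- vapply(1:20, function(r) {
    co <- generate_cohort(generator_config(
      n_cell_lines = 10, n_genes = 300, n_drugs = 4, n_patients = 20,
      seed = 9000 + r))
    assets <- generate_downstream_assets(co)
    res <- hypergeom_enrichment(assets$planted$target_genes,
                                assets$gene_sets)
    res$set_name[which.min(res$p_value)] == assets$planted$enriched_set
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})
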