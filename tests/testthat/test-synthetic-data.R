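# Cohort generator: determinism, the structural causal model, peak-file
# emission and downstream assets.

test_that("identical config and seed give identical cohorts and files", {
  cfg <- generator_config(n_cell_lines = 8, n_tfs = 3, n_hms = 2,
                          n_loci_per_pair = 5, n_private_loci = 3,
                          n_genes = 30, n_drugs = 6, n_patients = 20,
                          seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_peak_files(a, d1)
  m2 <- generate_peak_files(b, d2)
  expect_identical(m1$n_peaks, m2$n_peaks)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readLines(m1$path[i]), readLines(m2$path[i]))
  }
  a1 <- generate_downstream_assets(a)
  a2 <- generate_downstream_assets(b)
  expect_identical(a1, a2)
})

test_that("without confounding the OLS slope recovers the planted effect", {
  cfg <- small_config(n = 5000, beta1 = 1.5, gamma = 0, delta = 0,
                      seed = 11)
  co <- generate_cohort(cfg)
  slope <- stats::coef(stats::lm(co$hm_activity[, 1] ~
                                   co$tf_activity[, 1]))[2]
  expect_lt(abs(slope - 1.5), 0.05)
})

test_that("planted confounding makes TF activity endogenous", {
  cfg <- small_config(n = 2000, seed = 12)
  co <- generate_cohort(cfg)
  # structural error of the mark equation, reassembled from recorded truth
  struct_err <- cfg$confounder_strengths[["delta"]] * co$truth$confounder[, 1] +
    co$truth$noise_hm[, 1]
  expect_gt(stats::cov(co$tf_activity[, 1], struct_err), 0.2)
})

test_that("Monte-Carlo OLS slope matches beta1 plus the analytic bias", {
  cfg0 <- small_config(n = 400)
  bias <- expected_ols_bias(cfg0)
  slopes <- vapply(1:200, function(r) {
    ols_planted_slope(generate_cohort(small_config(n = 400, seed = 5000 + r)))
  }, 0)
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (1.5 + bias)), 3 * se + 1e-8)
})

test_that("the instrument is independent of confounder and noise", {
  cfg <- small_config(n = 20000, seed = 13)
  co <- generate_cohort(cfg)
  mut <- co$mutation[, 1]
  expect_lt(abs(stats::cor(mut, co$truth$confounder[, 1])), 0.025)
  expect_lt(abs(stats::cor(mut, co$truth$noise_hm[, 1])), 0.025)
  expect_lt(abs(stats::cor(mut, co$truth$noise_tf[, 1])), 0.025)
})

test_that("peak files round-trip to the cohort activity matrices", {
  cfg <- generator_config(n_cell_lines = 6, n_tfs = 3, n_hms = 2,
                          n_loci_per_pair = 6, n_private_loci = 4,
                          seed = 21)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  man <- generate_peak_files(co, dir)
  sets <- lapply(seq_len(nrow(man)), function(i) {
    read_peak_file(man$path[i], man$dialect[i])
  })
  m <- build_activity_matrix(sets, normalize = FALSE)
  cls <- attr(m, "factor_class")
  tf_cols <- names(cls)[cls == "TF"]
  hm_cols <- names(cls)[cls == "HM"]
  expect_lt(max(abs(m[, tf_cols] -
                      co$tf_activity[rownames(m), tf_cols])), 1e-9)
  expect_lt(max(abs(m[, hm_cols] -
                      co$hm_activity[rownames(m), hm_cols])), 1e-9)
})

test_that("emitted peak files honor their dialect column counts", {
  cfg <- generator_config(n_cell_lines = 3, n_tfs = 2, n_hms = 2,
                          n_loci_per_pair = 4, n_private_loci = 2,
                          seed = 22)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  man <- generate_peak_files(co, dir)
  for (i in seq_len(nrow(man))) {
    nf <- lengths(strsplit(readLines(man$path[i]), "\t"))
    want <- if (man$dialect[i] == "narrowPeak") 10L else 9L
    expect_true(all(nf == want))
  }
})

test_that("planted pairs share co-bound loci, unplanted pairs do not", {
  cfg <- generator_config(n_cell_lines = 3, n_tfs = 2, n_hms = 2,
                          planted_pairs = data.frame(tf = 1L, hm = 1L,
                                                     beta1 = 1.5),
                          n_loci_per_pair = 6, n_private_loci = 3,
                          seed = 23)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  man <- generate_peak_files(co, dir)
  get <- function(cell, fac) {
    row <- man[man$cell_line == cell & man$factor_id == fac, ]
    read_peak_file(row$path, row$dialect)
  }
  planted <- intersect_peaks(get("CL001", "TF01"), get("CL001", "H3K4me1"))
  unplanted <- intersect_peaks(get("CL001", "TF02"), get("CL001", "H3K4me1"))
  expect_gt(sum(planted$end - planted$start),
            sum(unplanted$end - unplanted$start))
  expect_equal(nrow(planted), 6)
})

test_that("downstream assets carry their planted signals", {
  cfg <- generator_config(n_cell_lines = 20, censoring_rate = 0,
                          n_genes = 120, n_drugs = 12, n_patients = 50,
                          seed = 31)
  co <- generate_cohort(cfg)
  assets <- generate_downstream_assets(co)
  # censoring_rate = 0 -> every record is an event
  expect_true(all(assets$survival$event == 1))
  # planted hub survives the score-700 filter at min_degree 5
  g <- load_interactions(assets$interactions, score_threshold = 700)
  expect_true(assets$planted$hub %in% hub_nodes(g, min_degree = 5))
  # dependency block is centered below zero
  med <- apply(assets$ceres[assets$planted$dependency_genes, ], 1,
               stats::median)
  expect_true(all(med < 0))
})

test_that("coupled drug class slopes carry the planted sign", {
  cfg <- generator_config(n_cell_lines = 500, n_tfs = 2, n_hms = 1,
                          planted_pairs = data.frame(tf = 1L, hm = 1L,
                                                     beta1 = 1.5),
                          n_genes = 100, n_drugs = 40, n_patients = 20,
                          seed = 32)
  co <- generate_cohort(cfg)
  assets <- generate_downstream_assets(co)
  me <- rowMeans(assets$gene_expression[, assets$planted$target_genes])
  rows <- drug_response_assoc(assets$ic50, me, co$cancer_type)
  coupled <- assets$drug_classes$drug[
    assets$drug_classes$class == assets$planted$coupled_class]
  frac_pos <- mean(rows$beta1[rows$drug %in% coupled] > 0)
  expect_gte(frac_pos, 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(mutation_prob = 0), "mutation_prob")
  expect_error(generator_config(n_tfs = 0), "count")
  expect_error(generator_config(noise_sd_tf = 0), "noise")
  expect_error(generator_config(censoring_rate = 1), "censoring_rate")
  expect_error(generator_config(
    planted_pairs = data.frame(tf = 99L, hm = 1L, beta1 = 1)),
    "out of range")
})
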