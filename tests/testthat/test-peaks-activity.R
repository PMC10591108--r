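# Peak parsing, activity scoring, interval intersection, target assignment.

write_lines_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("narrowPeak parsing preserves rows, sorts, takes signal column 7", {
  path <- write_lines_tmp(c(
    "chr2\t50\t150\tp1\t0\t.\t4.5\t-1\t-1\t-1",
    "chr1\t300\t400\tp2\t0\t.\t2.0\t-1\t-1\t-1",
    "chr1\t100\t200\tp3\t0\t.\t3.0\t-1\t-1\t-1"), ".narrowPeak")
  ps <- read_peak_file(path, "narrowPeak")
  expect_equal(nrow(ps$intervals), 3)
  expect_equal(ps$intervals$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(ps$intervals$start, c(100, 300, 50))
  expect_equal(ps$intervals$signal, c(3.0, 2.0, 4.5))
  expect_equal(ps$factor_class, "TF")
})

test_that("dialect column counts are enforced with a line number", {
  ten <- "chr1\t1\t10\tp\t0\t.\t1.0\t-1\t-1\t-1"
  nine <- "chr1\t1\t10\tp\t0\t.\t1.0\t-1\t-1"
  path <- write_lines_tmp(c(nine, ten), ".broadPeak")
  expect_error(read_peak_file(path, "broadPeak"), "line 2.*9 columns")
  path2 <- write_lines_tmp(nine, ".narrowPeak")
  expect_error(read_peak_file(path2, "narrowPeak"), "10 columns")
  path3 <- write_lines_tmp("chr1\t10\t10\tp\t0\t.\t1\t-1\t-1", ".broadPeak")
  expect_error(read_peak_file(path3, "broadPeak"), "start >= end")
})

test_that("write-then-read round trip preserves coordinates and signal", {
  set.seed(1)
  df <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                   start = sample.int(1000, 20), signal = runif(20, 0, 50))
  df$end <- df$start + sample.int(100, 20)
  ps <- make_peak_set(df, dialect = "broadPeak", factor_class = "HM")
  path <- withr::local_tempfile(fileext = ".broadPeak")
  write_peak_file(ps, path)
  back <- read_peak_file(path, "broadPeak")
  expect_equal(back$intervals[, c("chrom", "start", "end", "signal")],
               ps$intervals[, c("chrom", "start", "end", "signal")])
})

test_that("activity score is the mean of log2(1 + signal)", {
  one <- make_peak_set(data.frame(chrom = "chr1", start = 0, end = 10,
                                  signal = 3))
  expect_equal(activity_score(one), 2.0)
  same <- make_peak_set(data.frame(chrom = "chr1", start = c(0, 20, 40),
                                   end = c(10, 30, 50), signal = 7))
  expect_equal(activity_score(same), 3.0)
  set.seed(2)
  sig <- runif(50, 0, 100)
  rand <- make_peak_set(data.frame(chrom = "chr1", start = seq(0, 980, 20),
                                   end = seq(10, 990, 20), signal = sig))
  expect_equal(activity_score(rand), mean(log2(1 + sig)))
  empty <- make_peak_set(data.frame(chrom = character(), start = integer(),
                                    end = integer(), signal = numeric()))
  expect_true(is.na(activity_score(empty)))
})

test_that("activity matrix z-scores per factor and handles degenerate columns", {
  mk <- function(cell, sig) {
    make_peak_set(data.frame(chrom = "chr1", start = 0, end = 10,
                             signal = sig), sample_id = cell,
                  factor_id = "TFA")
  }
  m <- build_activity_matrix(list(mk("c1", 3), mk("c2", 7)))
  expect_equal(sort(unname(m[, "TFA"])), c(-1, 1) / sqrt(2))

  expect_warning(
    m2 <- build_activity_matrix(list(mk("c1", 5), mk("c2", 5))),
    "zero variance")
  expect_equal(unname(m2[, "TFA"]), c(0, 0))

  expect_warning(build_activity_matrix(list(mk("c1", 5))),
                 "un-normalized")

  # property: non-constant columns have mean 0, sd 1
  set.seed(3)
  sets <- unlist(lapply(1:5, function(j) {
    lapply(1:8, function(i) {
      make_peak_set(data.frame(chrom = "chr1", start = 0, end = 10,
                               signal = runif(1, 0, 20)),
                    sample_id = paste0("c", i),
                    factor_id = paste0("F", j))
    })
  }), recursive = FALSE)
  m3 <- build_activity_matrix(sets)
  expect_lt(max(abs(colMeans(m3))), 1e-9)
  expect_lt(max(abs(apply(m3, 2, sd) - 1)), 1e-9)
})

test_that("replicate files for the same cell and factor are averaged", {
  mk <- function(cell, sig) {
    make_peak_set(data.frame(chrom = "chr1", start = 0, end = 10,
                             signal = sig), sample_id = cell,
                  factor_id = "TFA")
  }
  m <- build_activity_matrix(list(mk("c1", 1), mk("c1", 3), mk("c2", 7)),
                             normalize = FALSE)
  expect_equal(unname(m["c1", "TFA"]),
               mean(c(log2(2), log2(4))))
})

test_that("interval intersection matches trivial geometry", {
  a <- make_peak_set(data.frame(chrom = "chr1", start = 0, end = 100,
                                signal = 2))
  b <- make_peak_set(data.frame(chrom = "chr1", start = 200, end = 300,
                                signal = 5), factor_class = "HM")
  expect_equal(nrow(intersect_peaks(a, b)), 0)

  c1 <- make_peak_set(data.frame(chrom = "chr1", start = 10, end = 50,
                                 signal = 2))
  c2 <- make_peak_set(data.frame(chrom = "chr1", start = 10, end = 50,
                                 signal = 9), factor_class = "HM")
  loci <- intersect_peaks(c1, c2)
  expect_equal(loci[, c("start", "end")], data.frame(start = 10, end = 50))
  expect_equal(loci$tf_signal, 2)
  expect_equal(loci$hm_signal, 9)

  d <- make_peak_set(data.frame(chrom = "chr1", start = 0, end = 100,
                                signal = 1), sample_id = "other")
  expect_error(intersect_peaks(a, d), "different cell lines")
})

test_that("intersection agrees with the per-base brute-force oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    mk <- function(n) {
      start <- sample.int(20000, n)
      data.frame(chrom = "chr1", start = start,
                 end = start + sample.int(60, n, replace = TRUE),
                 signal = runif(n))
    }
    a <- make_peak_set(mk(300))
    b <- make_peak_set(mk(300), factor_class = "HM")
    loci <- intersect_peaks(a, b)
    got <- if (nrow(loci)) bf_bases(loci$start, loci$end) else integer()
    want <- intersect(bf_bases(a$intervals$start, a$intervals$end),
                      bf_bases(b$intervals$start, b$intervals$end))
    expect_setequal(got, want)
    # commutativity in covered bases
    rev <- intersect_peaks(b, a)
    got_rev <- if (nrow(rev)) bf_bases(rev$start, rev$end) else integer()
    expect_setequal(got_rev, want)
    # total intersected length bounded by either side's footprint
    expect_lte(length(unique(got)),
               min(length(bf_bases(a$intervals$start, a$intervals$end)),
                   length(bf_bases(b$intervals$start, b$intervals$end))))
  }
})

test_that("target gene assignment follows the TSS window rule", {
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr1"),
                    tss = c(500, 5000), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  loci <- data.frame(chrom = "chr1", start = 480, end = 520,
                     tf_signal = 1, hm_signal = 1, cell_line = "c1",
                     stringsAsFactors = FALSE)
  expect_equal(assign_target_genes(loci, ann, hm = "H3K4me3",
                                   promoter_window = 100), "g1")
  expect_equal(assign_target_genes(loci[0, ], ann), character())
  expect_warning(
    out <- assign_target_genes(loci, ann[0, ], hm = "H3K4me3"),
    "empty gene annotation")
  expect_equal(out, character())

  # promoter vs enhancer window choice by mark
  far <- data.frame(chrom = "chr1", start = 3000, end = 3010,
                    tf_signal = 1, hm_signal = 1, cell_line = "c1",
                    stringsAsFactors = FALSE)
  expect_equal(assign_target_genes(far, ann, hm = "H3K4me3",
                                   promoter_window = 100,
                                   enhancer_window = 3000), character())
  expect_equal(assign_target_genes(far, ann, hm = "H3K27ac",
                                   promoter_window = 100,
                                   enhancer_window = 3000), c("g1", "g2"))
})

test_that("target assignment equals the all-pairs window oracle", {
  set.seed(4)
  for (rep in 1:5) {
    n_loci <- 40
    start <- sample.int(50000, n_loci)
    loci <- data.frame(chrom = sample(c("chr1", "chr2"), n_loci, TRUE),
                       start = start, end = start + sample.int(500, n_loci),
                       tf_signal = 1, hm_signal = 1, cell_line = "c1",
                       stringsAsFactors = FALSE)
    ann <- data.frame(gene_id = sprintf("g%02d", 1:30),
                      chrom = sample(c("chr1", "chr2"), 30, TRUE),
                      tss = sample.int(50000, 30),
                      strand = sample(c("+", "-"), 30, TRUE),
                      stringsAsFactors = FALSE)
    w <- 800
    got <- assign_target_genes(loci, ann, hm = "H3K27ac",
                               enhancer_window = w)
    hit <- vapply(seq_len(30), function(g) {
      any(loci$chrom == ann$chrom[g] &
            loci$start < ann$tss[g] + w &
            loci$end > ann$tss[g] - w)
    }, TRUE)
    expect_equal(got, sort(ann$gene_id[hit]))
  }
})
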