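# Peak-file I/O, binding-activity quantification, TF x histone-mark interval
# intersection and target-gene assignment. Coordinates are BED-style
# throughout: 0-based, half-open.

PEAK_DIALECT_COLS <- c(narrowPeak = 10L, broadPeak = 9L)
PROMOTER_MARKS <- c("H3K4me3", "H3K9ac")

#' Read a narrowPeak or broadPeak file
#'
#' Strict dialect parser: narrowPeak rows must have 10 columns, broadPeak 9.
#' Signal enrichment is taken from column 7 (signalValue). Intervals are
#' validated (start < end, signal >= 0) and returned sorted by
#' (chrom, start).
#'
#' @param path peak file.
#' @param dialect `"narrowPeak"` (TF) or `"broadPeak"` (histone mark).
#' @param sample_id,factor_id identifiers; default parsed from a
#'   `<sample>__<factor>.<ext>` file name.
#' @param factor_class `"TF"` or `"HM"`; defaults by dialect.
#' @return a `peak_set`: list with `sample_id`, `factor_id`, `factor_class`,
#'   `dialect` and an `intervals` data frame
#'   (chrom, start, end, name, score, strand, signal).
#' @export
read_peak_file <- function(path, dialect = c("narrowPeak", "broadPeak"),
                           sample_id = NULL, factor_id = NULL,
                           factor_class = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- PEAK_DIALECT_COLS[[dialect]]
  nf <- lengths(fields)
  bad <- which(nf != want)
  if (length(bad)) {
    stop_usage("format error in %s line %d: %s requires %d columns, found %d",
               path, bad[1], dialect, want, nf[bad[1]])
  }
  m <- do.call(rbind, fields)
  intervals <- data.frame(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    name = m[, 4],
    score = as.numeric(m[, 5]),
    strand = m[, 6],
    signal = as.numeric(m[, 7]),
    stringsAsFactors = FALSE)
  bad <- which(!(intervals$start < intervals$end))
  if (length(bad)) {
    stop_usage("validation error in %s line %d: start >= end", path, bad[1])
  }
  bad <- which(is.na(intervals$signal) | intervals$signal < 0)
  if (length(bad)) {
    stop_usage("validation error in %s line %d: signal must be >= 0",
               path, bad[1])
  }
  intervals <- intervals[order(intervals$chrom, intervals$start,
                               intervals$end), , drop = FALSE]
  rownames(intervals) <- NULL
  stem <- sub("\\.[^.]+$", "", basename(path))
  parts <- strsplit(stem, "__", fixed = TRUE)[[1]]
  structure(list(
    sample_id = sample_id %||% parts[1],
    factor_id = factor_id %||% if (length(parts) > 1) parts[2] else stem,
    factor_class = factor_class %||%
      if (dialect == "narrowPeak") "TF" else "HM",
    dialect = dialect,
    intervals = intervals), class = "peak_set")
}

#' Write a peak_set back to its dialect
#'
#' @param peaks a `peak_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_file <- function(peaks, path) {
  iv <- peaks$intervals
  tab <- data.frame(iv$chrom, iv$start, iv$end, iv$name,
                    as.integer(round(iv$score)), iv$strand, iv$signal,
                    -1, -1)
  if (peaks$dialect == "narrowPeak") tab$peak <- -1L
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Raw binding activity of one sample
#'
#' Mean of `log2(1 + signal)` over a sample's peaks: the per-file activity
#' score before cross-cell-line normalization.
#'
#' @param peaks a `peak_set`.
#' @return a single number, or `NA_real_` for an empty peak set.
#' @export
activity_score <- function(peaks) {
  iv <- peaks$intervals
  if (nrow(iv) == 0) return(NA_real_)
  mean(log2(1 + iv$signal))
}

#' Build a cell-line x factor activity matrix from peak sets
#'
#' Scores every peak set with [activity_score()], averages replicate files of
#' the same (cell line, factor), and by default z-scores each factor column
#' across cell lines so activities are comparable pan-cancer. Missing
#' (cell line, factor) combinations are `NA`. Constant columns become all
#' zero with a warning; a factor observed in a single cell line is left
#' un-normalized with a warning.
#'
#' @param peak_sets list of `peak_set` objects.
#' @param normalize z-score per factor column (default `TRUE`).
#' @return numeric matrix (cell lines x factors) with a `factor_class`
#'   attribute (named character vector per column).
#' @export
build_activity_matrix <- function(peak_sets, normalize = TRUE) {
  assert_that(length(peak_sets) >= 1, "no peak sets supplied")
  scores <- data.frame(
    cell = vapply(peak_sets, function(p) p$sample_id, ""),
    factor = vapply(peak_sets, function(p) p$factor_id, ""),
    class = vapply(peak_sets, function(p) p$factor_class, ""),
    score = vapply(peak_sets, activity_score, 0),
    stringsAsFactors = FALSE)
  cells <- sort(unique(scores$cell))
  factors <- sort(unique(scores$factor))
  m <- matrix(NA_real_, length(cells), length(factors),
              dimnames = list(cells, factors))
  agg <- stats::aggregate(score ~ cell + factor, scores, mean, na.rm = TRUE)
  m[cbind(match(agg$cell, cells), match(agg$factor, factors))] <- agg$score
  if (normalize) {
    for (j in seq_along(factors)) {
      v <- m[, j]
      obs <- which(!is.na(v))
      if (length(obs) < 2) {
        warning("factor ", factors[j],
                " observed in < 2 cell lines; column left un-normalized",
                call. = FALSE)
        next
      }
      s <- stats::sd(v[obs])
      if (s == 0) {
        warning("factor ", factors[j], " has zero variance; column set to 0",
                call. = FALSE)
        m[obs, j] <- 0
      } else {
        m[obs, j] <- (v[obs] - mean(v[obs])) / s
      }
    }
  }
  cls <- scores$class[match(factors, scores$factor)]
  names(cls) <- factors
  attr(m, "factor_class") <- cls
  m
}

peaks_to_granges <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end))
}

#' Intersect TF and histone-mark peaks into co-bound loci
#'
#' Every maximal non-empty intersection of a TF interval with a histone-mark
#' interval from the same cell line, carrying both parents' signal values.
#'
#' @param tf,hm `peak_set` objects from the same cell line.
#' @return data frame (chrom, start, end, tf_signal, hm_signal, cell_line),
#'   0-based half-open, sorted by (chrom, start, end).
#' @export
intersect_peaks <- function(tf, hm) {
  assert_that(identical(tf$sample_id, hm$sample_id),
              "usage error: peak sets come from different cell lines (%s vs %s)",
              tf$sample_id, hm$sample_id)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      tf_signal = numeric(), hm_signal = numeric(),
                      cell_line = character(), stringsAsFactors = FALSE)
  if (nrow(tf$intervals) == 0 || nrow(hm$intervals) == 0) return(empty)
  gr_tf <- peaks_to_granges(tf$intervals)
  gr_hm <- peaks_to_granges(hm$intervals)
  hits <- GenomicRanges::findOverlaps(gr_tf, gr_hm)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  inter <- GenomicRanges::pintersect(gr_tf[qi], gr_hm[si])
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(inter)),
    start = GenomicRanges::start(inter) - 1L,
    end = GenomicRanges::end(inter),
    tf_signal = tf$intervals$signal[qi],
    hm_signal = hm$intervals$signal[si],
    cell_line = tf$sample_id,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign target genes to co-bound loci
#'
#' A gene is a target when any locus overlaps the window `[TSS - w, TSS + w)`
#' around its transcription start site. `w` is `promoter_window` when the
#' pair's histone mark is a promoter mark (H3K4me3, H3K9ac) and
#' `enhancer_window` otherwise; strand only places the TSS. The window rule
#' is deliberately configurable: peak-to-gene assignment has no single field
#' convention.
#'
#' @param loci co-bound locus table from [intersect_peaks()] (rows may be
#'   pooled over cell lines).
#' @param annotation data frame with columns gene_id, chrom, tss, strand
#'   (tss 0-based).
#' @param hm histone-mark name of the pair, used to pick the window.
#' @param promoter_window,enhancer_window half-window sizes in bp.
#' @return sorted character vector of target gene ids.
#' @export
assign_target_genes <- function(loci, annotation, hm = "H3K27ac",
                                promoter_window = 2000,
                                enhancer_window = 50000) {
  assert_that(promoter_window >= 0 && enhancer_window >= 0,
              "windows must be >= 0")
  if (nrow(annotation) == 0) {
    warning("empty gene annotation; no targets assigned", call. = FALSE)
    return(character())
  }
  assert_that(!anyDuplicated(annotation$gene_id),
              "annotation gene ids must be unique")
  if (is.null(loci) || nrow(loci) == 0) return(character())
  w <- if (hm %in% PROMOTER_MARKS) promoter_window else enhancer_window
  gr_loci <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  win_start <- pmax(0L, annotation$tss - w)
  gr_genes <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = win_start + 1L,
                              end = annotation$tss + w))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_loci)
  sort(unique(annotation$gene_id[S4Vectors::queryHits(hits)]))
}

#' Pool co-bound loci for one TF/mark pair over all cell lines
#'
#' Convenience wrapper: intersects the pair's peak sets cell line by cell
#' line and row-binds the loci.
#'
#' @param tf_sets,hm_sets lists of `peak_set` objects keyed by cell line id.
#' @return pooled locus data frame (possibly zero rows).
#' @export
pool_cobound_loci <- function(tf_sets, hm_sets) {
  cells <- intersect(names(tf_sets), names(hm_sets))
  out <- lapply(cells, function(cl) intersect_peaks(tf_sets[[cl]],
                                                    hm_sets[[cl]]))
  out <- out[vapply(out, nrow, 0L) > 0]
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), tf_signal = numeric(),
                      hm_signal = numeric(), cell_line = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
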