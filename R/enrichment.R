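# Gene-set characterization of driver-pair target genes: CERES
# dependency-bin fold enrichment with a two-sided Fisher exact test, and
# upper-tail hypergeometric enrichment against GMT collections.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene ids); empty sets are
#'   rejected.
#' @param universe background gene ids; defaults to the union of all sets.
#' @param restrict drop set members outside the universe.
#' @return a `gene_set_collection` list with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL, restrict = FALSE) {
  assert_that(length(sets) > 0 && !is.null(names(sets)),
              "sets must be a non-empty named list")
  sets <- lapply(sets, unique)
  assert_that(all(lengths(sets) > 0), "gene sets must be non-empty")
  universe <- unique(universe %||% unlist(sets, use.names = FALSE))
  if (restrict) sets <- lapply(sets, intersect, y = universe)
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read a GMT file
#'
#' Tab-separated gene-set format: set name, description, then member genes.
#'
#' @param path GMT file.
#' @param universe optional background; defaults to the union of all sets.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop_usage("format error in %s line %d: GMT rows need name, description and >= 1 gene",
               path, bad[1])
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1)
  gene_set_collection(sets, universe = universe)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @param description description column value.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "synthetic") {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, description, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Bin genes by median CERES dependency score
#'
#' Each gene is assigned by its median score across cell lines to half-open
#' (lower-inclusive) bins of the given width over `[lower, upper)`; the
#' defaults give `[-2,-1.6), [-1.6,-1.2), [-1.2,-0.8), [-0.8,-0.4),
#' [-0.4, 0)`. Genes with medians outside the range fall into an `"other"`
#' bucket; all-NA genes are excluded with a warning.
#'
#' @param ceres gene x cell-line numeric matrix.
#' @param width bin width (default 0.4).
#' @param lower,upper bin range (default `[-2, 0)`).
#' @return named list of gene-id vectors, one per bin plus `"other"`, with
#'   the per-gene medians in the `medians` attribute.
#' @export
bin_genes_by_ceres <- function(ceres, width = 0.4, lower = -2, upper = 0) {
  assert_that(upper > lower && width > 0, "invalid bin range")
  med <- apply(ceres, 1, stats::median, na.rm = TRUE)
  dropped <- names(med)[is.na(med)]
  if (length(dropped)) {
    warning(length(dropped), " gene(s) with all-NA scores excluded",
            call. = FALSE)
    med <- med[!is.na(med)]
  }
  breaks <- round(seq(lower, upper, by = width), 10)
  labels <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  idx <- findInterval(med, breaks, rightmost.closed = FALSE)
  bins <- c(stats::setNames(
    lapply(seq_along(labels),
           function(i) names(med)[idx == i & med < upper]),
    labels),
    list(other = names(med)[med < lower | med >= upper]))
  attr(bins, "medians") <- med
  bins
}

# Two-sided Fisher exact p by the minimum-likelihood rule: sum of
# hypergeometric table probabilities no larger than the observed one.
fisher_two_sided_p <- function(a, b, c, d) {
  K <- a + c          # annotated
  n_draw <- a + b     # target size
  N <- a + b + c + d
  support <- max(0, n_draw - (N - K)):min(n_draw, K)
  probs <- stats::dhyper(support, K, N - K, n_draw)
  obs <- stats::dhyper(a, K, N - K, n_draw)
  min(1, sum(probs[probs <= obs * (1 + 1e-07)]))
}

#' Fisher exact enrichment of a target gene set
#'
#' Builds the 2x2 table (in/out of target x in/out of annotated set over the
#' universe) and reports the two-sided Fisher exact p (minimum-likelihood
#' rule), the sample odds ratio `ad/bc` (0 or Inf for zero cells, flagged;
#' optional Haldane continuity correction), and the fold enrichment
#' `(overlap/target) / (annotated/universe)`.
#'
#' @param target,annotated,universe character vectors of gene ids; target
#'   and annotated are intersected with the universe.
#' @param continuity add 0.5 to every cell for the odds ratio only.
#' @return one-row data frame: overlap, target_size, set_size, universe_size,
#'   fold_enrichment, odds_ratio, zero_cell, p_value.
#' @export
fisher_enrichment <- function(target, annotated, universe,
                              continuity = FALSE) {
  universe <- unique(universe)
  assert_that(length(universe) > 0, "undefined result: empty universe")
  target <- intersect(unique(target), universe)
  annotated <- intersect(unique(annotated), universe)
  assert_that(length(target) > 0, "undefined result: empty target set")
  a <- length(intersect(target, annotated))
  b <- length(target) - a
  c <- length(annotated) - a
  d <- length(universe) - a - b - c
  p <- fisher_two_sided_p(a, b, c, d)
  zero_cell <- any(c(a, b, c, d) == 0)
  or <- if (continuity) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  fold <- (a / length(target)) /
    (length(annotated) / length(universe))
  data.frame(overlap = a, target_size = length(target),
             set_size = length(annotated),
             universe_size = length(universe),
             fold_enrichment = fold, odds_ratio = or,
             zero_cell = zero_cell, p_value = p,
             stringsAsFactors = FALSE)
}

#' Hypergeometric pathway enrichment over a collection
#'
#' Upper-tail hypergeometric p per set (probability of an overlap at least
#' as large as observed), with Benjamini-Hochberg adjustment across the
#' collection.
#'
#' @param target character vector of gene ids; must intersect the universe.
#' @param collection a [gene_set_collection()].
#' @return data frame (set_name, overlap, target_size, set_size, gene_ratio,
#'   p_value, fdr), one row per set in collection order.
#' @export
hypergeom_enrichment <- function(target, collection) {
  assert_that(inherits(collection, "gene_set_collection"),
              "collection must be a gene_set_collection")
  N <- length(collection$universe)
  target <- intersect(unique(target), collection$universe)
  assert_that(length(target) > 0,
              "target genes disjoint from the collection universe")
  n_draw <- length(target)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], collection$universe)
    k <- length(intersect(target, set))
    K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, target_size = n_draw,
               set_size = K, gene_ratio = k / n_draw, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p_value)
  res
}
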