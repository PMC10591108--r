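# Protein-interaction networks over target genes: score-thresholded graph
# construction from STRING-style exports, hub extraction, and
# weight-filtered cluster (connected component) selection.

#' Load a STRING-style interaction table as a weighted graph
#'
#' Keeps interactions with `combined_score >= score_threshold` (inclusive,
#' the high-confidence convention), collapses duplicate unordered pairs to
#' their maximum score, drops self-loops, and sets edge weight to
#' `combined_score / 1000` so weights lie in `[0, 1]`.
#'
#' @param table path to a TSV with columns protein1, protein2,
#'   combined_score, or a data frame with those columns.
#' @param score_threshold minimum combined score (default 700).
#' @return an undirected [igraph::igraph] with a `weight` edge attribute.
#' @export
load_interactions <- function(table, score_threshold = 700) {
  df <- if (is.character(table)) read_tsv(table) else as.data.frame(table)
  need <- c("protein1", "protein2", "combined_score")
  assert_that(all(need %in% names(df)),
              "interaction table needs columns: %s", paste(need, collapse = ", "))
  score <- as.numeric(df$combined_score)
  bad <- which(is.na(score) | score < 0 | score > 1000)
  if (length(bad)) {
    stop_usage("validation error: combined_score outside [0, 1000] at line %d",
               bad[1] + 1L)  # +1 for the header line
  }
  keep <- score >= score_threshold & df$protein1 != df$protein2
  df <- df[keep, , drop = FALSE]
  score <- score[keep]
  if (nrow(df) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  key <- paste(a, b, sep = "\r")
  best <- tapply(score, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[[`, "", 1),
                      to = vapply(parts, `[[`, "", 2),
                      weight = as.vector(best) / 1000,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Induced subgraph on a gene set
#'
#' Restricts the graph to `genes` present among its nodes; genes with no
#' remaining interactions stay as degree-0 nodes.
#'
#' @param graph an igraph object.
#' @param genes character vector of node ids.
#' @return induced igraph subgraph.
#' @export
subgraph_genes <- function(graph, genes) {
  keep <- intersect(genes, igraph::V(graph)$name)
  igraph::induced_subgraph(graph, keep)
}

#' Hub nodes of an interaction graph
#'
#' Nodes with degree at least `min_degree`, ordered by decreasing degree
#' then id.
#'
#' @param graph an igraph object.
#' @param min_degree hub threshold (default 5).
#' @return character vector of node ids (possibly empty).
#' @export
hub_nodes <- function(graph, min_degree = 5) {
  if (igraph::vcount(graph) == 0) return(character())
  deg <- igraph::degree(graph)
  hubs <- deg[deg >= min_degree]
  names(hubs)[order(-hubs, names(hubs))]
}

#' Weight-filtered clusters
#'
#' Connected components retained when (i) they contain at least one node
#' whose degree in the FULL graph is `>= min_degree` and (ii) their mean
#' internal edge weight is `>= min_avg_weight` (weights on the 0-1 combined
#' score scale). Edge-less components fail (ii).
#'
#' @param graph an igraph object with a `weight` edge attribute.
#' @param min_degree full-graph degree requirement (default 5).
#' @param min_avg_weight mean internal edge weight floor (default 0.05).
#' @return list of character vectors (node ids per retained cluster).
#' @export
filter_clusters <- function(graph, min_degree = 5, min_avg_weight = 0.05) {
  if (igraph::vcount(graph) == 0) return(list())
  deg <- igraph::degree(graph)
  comp <- igraph::components(graph)
  out <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == ci]
    if (!any(deg[nodes] >= min_degree)) next
    sub <- igraph::induced_subgraph(graph, nodes)
    if (igraph::ecount(sub) == 0) next
    if (mean(igraph::E(sub)$weight) < min_avg_weight) next
    out[[length(out) + 1L]] <- sort(nodes)
  }
  out
}
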