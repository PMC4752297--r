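#' Rank the top-k edges by betweenness
#'
#' Returns the `k` highest-scoring edges of a centrality table — the
#' "primary pathway" of the map when applied to the full binary-relation
#' graph with the default `k = 50`. Ties are broken deterministically by
#' lexicographic order of the edge's (source label, target label) pair
#' (endpoint labels sorted first on undirected graphs).
#'
#' @param table a `centrality_table` with edge scores, from
#'   [edge_betweenness()] or [node_betweenness()].
#' @param k number of edges to keep; defaults to 50. When `k` exceeds the
#'   edge count, all edges are returned sorted.
#' @return An `edge_ranking`: data frame with columns `rank`, `from`,
#'   `to`, `score`, carrying attributes `k` and `tie_rule`.
#' @export
top_k_edges <- function(table, k = 50L) {
  stopifnot(inherits(table, "centrality_table"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("k must be a single positive integer")
  }
  edges <- table$edges
  if (!nrow(edges)) stop("centrality table has no edge scores")

  if (table$directed) {
    key1 <- edges$from; key2 <- edges$to
  } else {
    key1 <- pmin(edges$from, edges$to)
    key2 <- pmax(edges$from, edges$to)
  }
  ord <- order(-edges$raw, key1, key2)
  keep <- utils::head(ord, min(as.integer(k), nrow(edges)))
  out <- data.frame(rank = seq_along(keep),
                    from = edges$from[keep], to = edges$to[keep],
                    score = edges$raw[keep], stringsAsFactors = FALSE)
  structure(out, k = as.integer(k),
            tie_rule = "lexicographic on sorted (source, target) labels",
            class = c("edge_ranking", "data.frame"))
}

#' Extract the k-hop neighbourhood around seed nodes
#'
#' Retains every node within `hops` of at least one seed (hop distance is
#' measured on the undirected skeleton regardless of the graph's
#' directedness, so "two hops" is symmetric between the seeds), together
#' with all induced edges. The defaults reproduce the common disease-map
#' analysis: two hops around "Ceramide" and "Inflammation".
#'
#' Seeds given `by = "label"` are matched against node display labels
#' case-insensitively after whitespace normalisation; an unresolvable seed
#' raises an error listing near-miss labels, an ambiguous one lists all
#' matches. `by = "id"` matches the SBML species ids merged into each
#' node.
#'
#' @param graph an igraph from [build_binary_graph()].
#' @param seeds node labels (or species ids) to grow from.
#' @param hops non-negative hop budget; `hops = 0` keeps just the seeds.
#' @param by match seeds by display `"label"` (default) or species `"id"`.
#' @return A `subnetwork`: list with the induced `graph`, the resolved
#'   `seeds`, `hops` and a `provenance` string.
#' @export
khop_neighborhood <- function(graph, seeds = c("Ceramide", "Inflammation"),
                              hops = 2L, by = c("label", "id")) {
  stopifnot(inherits(graph, "igraph"))
  by <- match.arg(by)
  if (!is.numeric(hops) || length(hops) != 1L || is.na(hops) || hops < 0) {
    stop("hops must be a single non-negative integer")
  }
  seeds <- as.character(seeds)
  if (!length(seeds)) stop("at least one seed is required")

  idx <- vapply(seeds, function(s) resolve_seed(graph, s, by), integer(1))

  hood <- igraph::ego(graph, order = as.integer(hops), nodes = idx,
                      mode = "all")
  keep <- sort(unique(unlist(lapply(hood, as.integer))))
  sub <- igraph::induced_subgraph(graph, keep)

  structure(
    list(graph = sub, seeds = vertex_labels(graph)[idx],
         hops = as.integer(hops),
         provenance = sprintf("%d-hop neighbourhood of {%s} in '%s'",
                              as.integer(hops),
                              paste(vertex_labels(graph)[idx],
                                    collapse = ", "),
                              igraph::graph_attr(graph, "source_name") %||%
                                "<graph>")),
    class = "subnetwork"
  )
}

# Resolve one seed to a vertex index, with near-miss reporting.
resolve_seed <- function(graph, seed, by) {
  norm <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))
  if (by == "label") {
    labs <- vertex_labels(graph)
    hits <- which(norm(labs) == norm(seed))
  } else {
    ids <- strsplit(igraph::vertex_attr(graph, "species_ids") %||%
                      igraph::vertex_attr(graph, "name"), ",", fixed = TRUE)
    hits <- which(vapply(ids, function(v) seed %in% v, logical(1)))
  }
  if (length(hits) == 1L) return(hits)
  if (length(hits) > 1L) {
    stop("seed '", seed, "' is ambiguous; matches: ",
         paste(vertex_labels(graph)[hits], collapse = ", "))
  }
  labs <- vertex_labels(graph)
  near <- unique(labs[agrepl(seed, labs, ignore.case = TRUE,
                             max.distance = 0.25)])
  stop("seed '", seed, "' does not resolve to any node",
       if (length(near)) paste0("; near misses: ",
                                paste(utils::head(near, 8L),
                                      collapse = ", ")) else "")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("<subnetwork> ", x$provenance, "\n", sep = "")
  cat("  nodes: ", igraph::vcount(x$graph),
      ", edges: ", igraph::ecount(x$graph), "\n", sep = "")
  invisible(x)
}

#' Re-rank edges inside a subnetwork
#'
#' Recomputes edge betweenness from scratch on the induced subnetwork —
#' scores are *not* inherited from the parent graph, because shortest
#' paths change when the rest of the map is cut away — and returns the
#' top-k edges of that local ranking.
#'
#' @param sub a `subnetwork` from [khop_neighborhood()].
#' @param k number of edges to keep (default 50).
#' @return An `edge_ranking` (see [top_k_edges()]).
#' @export
rerank_subnetwork <- function(sub, k = 50L) {
  stopifnot(inherits(sub, "subnetwork"))
  if (igraph::vcount(sub$graph) == 0L) stop("subnetwork is empty")
  if (igraph::ecount(sub$graph) == 0L) {
    stop("subnetwork has no edges to rank")
  }
  top_k_edges(edge_betweenness(sub$graph), k = k)
}

#' Write an edge ranking as TSV
#'
#' @param ranking an `edge_ranking`.
#' @param path output file path.
#' @param graph optional igraph supplying display labels for the node
#'   keys; when given, `from`/`to` are written as display labels.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path, graph = NULL) {
  stopifnot(inherits(ranking, "edge_ranking"))
  df <- as.data.frame(ranking)
  if (!is.null(graph)) {
    key2lab <- stats::setNames(vertex_labels(graph),
                               igraph::vertex_attr(graph, "name"))
    df$from <- unname(key2lab[df$from])
    df$to <- unname(key2lab[df$to])
  }
  write_utf8_tsv(df, path)
}
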