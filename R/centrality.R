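#' Node betweenness centrality
#'
#' Betweenness centrality measures how many shortest paths between all node
#' pairs pass through a node. For a node `v`,
#' `score(v) = sum over pairs s != v != t of sigma_st(v) / sigma_st`, where
#' `sigma_st` counts shortest s-t paths and `sigma_st(v)` those through
#' `v`; endpoints are never counted as intermediates, and pairs in
#' different components contribute 0. On an undirected graph the sum runs
#' over unordered pairs. Normalised scores divide by `(n-1)(n-2)/2`
#' (undirected) or `(n-1)(n-2)` (directed), with `n` the total node count
#' of the graph, so they lie in `[0, 1]` even on disconnected graphs.
#'
#' Computed with Brandes' single-source accumulation algorithm (unweighted
#' breadth-first variant, exact, `O(nm)`), implemented in C++.
#'
#' @param graph an igraph, e.g. from [build_binary_graph()]. Must be
#'   simple (no self-loops or parallel edges).
#' @param normalized divide node scores by the pair count? Default `TRUE`.
#' @return A `centrality_table`: list with data frames `nodes`
#'   (`node`, `display`, `raw`, and `normalized` when requested) and
#'   `edges` (`from`, `to`, `raw`), plus the `normalized`, `directed` and
#'   `n_nodes` conventions used.
#' @seealso [edge_betweenness()], [brute_force_betweenness()]
#' @export
node_betweenness <- function(graph, normalized = TRUE) {
  betweenness_table(graph, normalized = normalized)
}

#' Edge betweenness centrality
#'
#' For an edge `e`, `score(e) = sum over pairs s != t of
#' sigma_st(e) / sigma_st` — the number of pair-wise shortest paths
#' carried by the edge, fractionally when shortest paths tie. Scores are
#' reported raw (unnormalised); ranking edges, as [top_k_edges()] does, is
#' unaffected by normalisation.
#'
#' @inheritParams node_betweenness
#' @return A `centrality_table` (see [node_betweenness()]).
#' @export
edge_betweenness <- function(graph) {
  betweenness_table(graph, normalized = FALSE)
}

# Shared Brandes driver: one pass computes node and edge scores.
betweenness_table <- function(graph, normalized = TRUE) {
  stopifnot(inherits(graph, "igraph"))
  n <- igraph::vcount(graph)
  if (n == 0L) stop("graph has no nodes")
  if (igraph::any_loop(graph) || igraph::any_multiple(graph)) {
    stop("graph must be simple: remove self-loops and parallel edges first")
  }
  directed <- igraph::is_directed(graph)

  el <- igraph::as_edgelist(graph, names = FALSE)
  res <- .brandes_betweenness(n, matrix(as.integer(el - 1L), ncol = 2L),
                              directed)
  node_raw <- res$node
  edge_raw <- res$edge
  if (!directed) {
    # Brandes accumulates over ordered pairs; fold to unordered
    node_raw <- node_raw / 2
    edge_raw <- edge_raw / 2
  }

  node_names <- igraph::vertex_attr(graph, "name") %||%
    as.character(seq_len(n))
  nodes <- data.frame(node = node_names, display = vertex_labels(graph),
                      raw = node_raw, stringsAsFactors = FALSE)
  if (normalized) {
    if (n < 3L) {
      warning("normalised betweenness is undefined for fewer than 3 nodes; ",
              "returning zeros", call. = FALSE)
      nodes$normalized <- rep(0, n)
    } else {
      divisor <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
      nodes$normalized <- node_raw / divisor
    }
  }

  el_named <- igraph::as_edgelist(graph, names = TRUE)
  edges <- data.frame(
    from = if (nrow(el_named)) el_named[, 1L] else character(),
    to = if (nrow(el_named)) el_named[, 2L] else character(),
    raw = edge_raw, stringsAsFactors = FALSE)

  structure(
    list(nodes = nodes, edges = edges, normalized = normalized,
         directed = directed, n_nodes = n),
    class = "centrality_table"
  )
}

#' @export
print.centrality_table <- function(x, ...) {
  cat("<centrality_table> ", x$n_nodes, " nodes, ", nrow(x$edges),
      " edges (", if (x$directed) "directed" else "undirected",
      if (x$normalized) ", normalized" else "", ")\n", sep = "")
  ord <- order(-x$nodes$raw)
  top <- utils::head(x$nodes[ord, , drop = FALSE], 5L)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Brute-force betweenness by explicit shortest-path enumeration
#'
#' Test oracle: computes node and edge betweenness by enumerating every
#' shortest path between every node pair via breadth-first search and
#' backtracking through the predecessor DAG, then crediting each
#' intermediate node and each edge with `1 / (number of shortest paths)`
#' per path. Independent of the Brandes implementation; quadratic blow-up
#' limits it to small graphs.
#'
#' @param graph an igraph with at most 15 nodes.
#' @param normalized normalise node scores as in [node_betweenness()]?
#' @return A `centrality_table` (see [node_betweenness()]).
#' @export
brute_force_betweenness <- function(graph, normalized = FALSE) {
  stopifnot(inherits(graph, "igraph"))
  n <- igraph::vcount(graph)
  if (n == 0L) stop("graph has no nodes")
  if (n > 15L) {
    stop("brute_force_betweenness refuses graphs with more than 15 nodes ",
         "(got ", n, "); it is a test oracle, not a production path")
  }
  directed <- igraph::is_directed(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- nrow(el)

  adj <- vector("list", n)  # per vertex: list of c(neighbour, edge id)
  for (e in seq_len(m)) {
    u <- el[e, 1L]; v <- el[e, 2L]
    adj[[u]] <- c(adj[[u]], list(c(v, e)))
    if (!directed) adj[[v]] <- c(adj[[v]], list(c(u, e)))
  }

  node_bc <- numeric(n)
  edge_bc <- numeric(m)

  bfs_preds <- function(s) {
    dist <- rep(-1L, n)
    preds <- vector("list", n)  # predecessor (vertex, edge) pairs
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[v]]) {
        w <- nb[1L]; eid <- nb[2L]
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          preds[[w]] <- c(preds[[w]], list(c(v, eid)))
        }
      }
    }
    list(dist = dist, preds = preds)
  }

  # all shortest s->t paths as lists of (vertex sequence, edge sequence)
  enumerate_paths <- function(preds, s, t) {
    if (t == s) return(list(list(vertices = s, edges = integer())))
    if (is.null(preds[[t]])) return(list())
    out <- list()
    for (pe in preds[[t]]) {
      for (sub in enumerate_paths(preds, s, pe[1L])) {
        out <- c(out, list(list(vertices = c(sub$vertices, t),
                                edges = c(sub$edges, pe[2L]))))
      }
    }
    out
  }

  for (s in seq_len(n)) {
    bp <- bfs_preds(s)
    targets <- if (directed) setdiff(seq_len(n), s) else
      seq_len(n)[seq_len(n) > s]
    for (t in targets) {
      if (bp$dist[t] <= 0L) next
      paths <- enumerate_paths(bp$preds, s, t)
      if (!length(paths)) next
      w <- 1 / length(paths)
      for (p in paths) {
        interior <- setdiff(p$vertices, c(s, t))
        node_bc[interior] <- node_bc[interior] + w
        edge_bc[p$edges] <- edge_bc[p$edges] + w
      }
    }
  }

  node_names <- igraph::vertex_attr(graph, "name") %||%
    as.character(seq_len(n))
  nodes <- data.frame(node = node_names, display = vertex_labels(graph),
                      raw = node_bc, stringsAsFactors = FALSE)
  if (normalized) {
    if (n < 3L) {
      nodes$normalized <- rep(0, n)
    } else {
      divisor <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
      nodes$normalized <- node_bc / divisor
    }
  }
  el_named <- igraph::as_edgelist(graph, names = TRUE)
  edges <- data.frame(
    from = if (m) el_named[, 1L] else character(),
    to = if (m) el_named[, 2L] else character(),
    raw = edge_bc, stringsAsFactors = FALSE)

  structure(
    list(nodes = nodes, edges = edges, normalized = normalized,
         directed = directed, n_nodes = n),
    class = "centrality_table"
  )
}

#' Write ranked centrality scores as TSV
#'
#' @param table a `centrality_table`.
#' @param path output file path.
#' @param what `"nodes"` or `"edges"`.
#' @return `path`, invisibly.
#' @export
write_centrality_tsv <- function(table, path, what = c("nodes", "edges")) {
  stopifnot(inherits(table, "centrality_table"))
  what <- match.arg(what)
  if (what == "nodes") {
    df <- table$nodes[order(-table$nodes$raw, table$nodes$display), ,
                      drop = FALSE]
    df <- cbind(rank = seq_len(nrow(df)), df)
  } else {
    df <- table$edges
    lo <- pmin(df$from, df$to)
    hi <- pmax(df$from, df$to)
    df <- df[order(-df$raw, lo, hi), , drop = FALSE]
    df <- cbind(rank = seq_len(nrow(df)), df)
  }
  write_utf8_tsv(df, path)
}
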