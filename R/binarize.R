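#' Decompose one process-description reaction into binary relations
#'
#' A process-description reaction joins reactants, products and modifiers
#' around a single reaction node. Flattening it to pairwise relations
#' produces one `REACTANT_PRODUCT` relation per (reactant, product) pair
#' and one `MODIFIER_PRODUCT` relation per (modifier, product) pair. For a
#' reversible reaction, one additional `REACTANT_PRODUCT` relation is
#' emitted per (product, reactant) pair; modifier relations are not
#' mirrored. Output order is deterministic: reactant-product pairs first
#' (reactants outer loop, products inner, both in input order), then
#' modifier-product pairs, then the reversed pairs.
#'
#' @param reaction a list (or one-row slice of a [pathway_map()] reaction
#'   table) with elements `id`, `reactants`, `products`, `modifiers`,
#'   `reversible`.
#' @return Data frame with columns `source`, `target`, `rule`
#'   (`REACTANT_PRODUCT` or `MODIFIER_PRODUCT`) and `origin_reaction`.
#'   Relations with `source == target` (e.g. transport of a species between
#'   compartments recorded under one id) are emitted here and dropped later
#'   by the self-loop policy of [build_binary_graph()].
#' @export
decompose_reaction <- function(reaction) {
  if (is.data.frame(reaction)) {
    stopifnot(nrow(reaction) == 1L)
    reaction <- list(
      id = reaction$id, reversible = reaction$reversible,
      reactants = reaction$reactants[[1L]],
      products = reaction$products[[1L]],
      modifiers = reaction$modifiers[[1L]]
    )
  }
  reactants <- as.character(reaction$reactants %||% character())
  products <- as.character(reaction$products %||% character())
  modifiers <- as.character(reaction$modifiers %||% character())
  rid <- as.character(reaction$id %||% NA_character_)
  reversible <- isTRUE(reaction$reversible)

  if (!length(products)) {
    warning("reaction '", rid, "' has no products; no relations emitted",
            call. = FALSE)
    return(empty_relation_table())
  }

  pair_grid <- function(src, tgt, rule) {
    if (!length(src) || !length(tgt)) return(empty_relation_table())
    data.frame(
      source = rep(src, each = length(tgt)),
      target = rep(tgt, times = length(src)),
      rule = rule, origin_reaction = rid,
      stringsAsFactors = FALSE
    )
  }

  out <- rbind(
    pair_grid(reactants, products, "REACTANT_PRODUCT"),
    pair_grid(modifiers, products, "MODIFIER_PRODUCT")
  )
  if (reversible) {
    out <- rbind(out, pair_grid(products, reactants, "REACTANT_PRODUCT"))
  }
  out
}

empty_relation_table <- function() {
  data.frame(source = character(), target = character(),
             rule = character(), origin_reaction = character(),
             stringsAsFactors = FALSE)
}

#' Decompose every reaction of a map
#'
#' @param map a [pathway_map()].
#' @return Data frame of binary relations (see [decompose_reaction()]),
#'   reactions in table order.
#' @export
decompose_map <- function(map) {
  stopifnot(inherits(map, "pathway_map"))
  rx <- map$reactions
  if (!nrow(rx)) return(empty_relation_table())
  parts <- lapply(seq_len(nrow(rx)), function(i) {
    suppressWarnings(decompose_reaction(list(
      id = rx$id[i], reversible = rx$reversible[i],
      reactants = rx$reactants[[i]], products = rx$products[[i]],
      modifiers = rx$modifiers[[i]]
    )))
  })
  do.call(rbind, parts)
}

#' Build the type-filtered binary-relation graph of a pathway map
#'
#' Assembles the simple graph on which centralities are computed:
#' reactions are decomposed into binary relations
#' ([decompose_reaction()]), relations touching a species outside
#' `allowed_classes` are dropped, self-loops are removed, and parallel
#' relations between the same node pair collapse into a single edge that
#' retains all supporting rules and origin reactions.
#'
#' Node identity defaults to merge-by-name: species sharing the same
#' display name (after whitespace normalisation) *and* molecule class are
#' unified into one node, so an entity transported between compartments is
#' a single node. With `merge_by_name = FALSE` nodes are keyed by species
#' id. Either way the choice is recorded as a graph attribute.
#'
#' @param map a [pathway_map()].
#' @param allowed_classes molecule classes admitted to the graph; defaults
#'   to [DEFAULT_ALLOWED_CLASSES] (ions and degraded products excluded).
#' @param directed build a directed graph (`source -> target`)? Default
#'   `FALSE`: the analysis convention treats relations as undirected.
#' @param merge_by_name unify same-named species of the same class across
#'   compartments? Default `TRUE`.
#' @param keep_isolated also keep allowed-class species with no surviving
#'   relation as isolated nodes? Default `FALSE`.
#' @return An [igraph::igraph] with vertex attributes `name` (node key),
#'   `display` (label), `molecule_class`, `species_ids`
#'   (comma-separated merged ids) and edge attributes `rule`, `origins`,
#'   `n_relations`; graph attributes record the conventions used.
#' @export
build_binary_graph <- function(map,
                               allowed_classes = DEFAULT_ALLOWED_CLASSES,
                               directed = FALSE,
                               merge_by_name = TRUE,
                               keep_isolated = FALSE) {
  stopifnot(inherits(map, "pathway_map"))
  allowed_classes <- unique(as.character(allowed_classes))
  if (!length(allowed_classes)) {
    stop("allowed_classes must name at least one molecule class")
  }
  bad <- setdiff(allowed_classes, MOLECULE_CLASSES)
  if (length(bad)) {
    stop("unknown molecule class(es) in allowed_classes: ",
         paste(bad, collapse = ", "))
  }

  sp <- map$species
  sp <- sp[sp$molecule_class %in% allowed_classes, , drop = FALSE]

  # node key: merged (normalised name, class) or raw species id
  norm_name <- function(x) gsub("[[:space:]]+", " ", trimws(x))
  if (merge_by_name) {
    sp$node_key <- paste(norm_name(sp$name), sp$molecule_class, sep = "||")
  } else {
    sp$node_key <- sp$id
  }

  nodes <- do.call(rbind, lapply(split(sp, sp$node_key), function(g) {
    data.frame(name = g$node_key[1L], display = norm_name(g$name[1L]),
               molecule_class = g$molecule_class[1L],
               species_ids = paste(sort(g$id), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) {
    nodes <- data.frame(name = character(), display = character(),
                        molecule_class = character(),
                        species_ids = character(), stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$name), , drop = FALSE]

  rel <- decompose_map(map)
  key_of <- stats::setNames(sp$node_key, sp$id)
  # drop relations touching a species outside the allowed classes
  rel <- rel[rel$source %in% sp$id & rel$target %in% sp$id, , drop = FALSE]
  if (nrow(rel)) {
    rel$from <- unname(key_of[rel$source])
    rel$to <- unname(key_of[rel$target])
    rel <- rel[rel$from != rel$to, , drop = FALSE] # self-loop policy
  }

  if (nrow(rel)) {
    if (directed) {
      pair_key <- paste(rel$from, rel$to, sep = "\r")
    } else {
      pair_key <- paste(pmin(rel$from, rel$to), pmax(rel$from, rel$to),
                        sep = "\r")
    }
    edges <- do.call(rbind, lapply(split(rel, pair_key), function(g) {
      data.frame(
        from = if (directed) g$from[1L] else min(g$from[1L], g$to[1L]),
        to = if (directed) g$to[1L] else max(g$from[1L], g$to[1L]),
        rule = paste(sort(unique(g$rule)), collapse = ","),
        origins = paste(sort(unique(g$origin_reaction)), collapse = ","),
        n_relations = nrow(g),
        stringsAsFactors = FALSE
      )
    }))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(), to = character(),
                        rule = character(), origins = character(),
                        n_relations = integer(), stringsAsFactors = FALSE)
  }

  if (!keep_isolated) {
    touched <- unique(c(edges$from, edges$to))
    nodes <- nodes[nodes$name %in% touched, , drop = FALSE]
  }

  g <- igraph::graph_from_data_frame(edges, directed = directed,
                                     vertices = nodes)
  g <- igraph::set_graph_attr(g, "allowed_classes",
                              paste(sort(allowed_classes), collapse = ","))
  g <- igraph::set_graph_attr(g, "merge_by_name", merge_by_name)
  g <- igraph::set_graph_attr(g, "source_name", map$source_name)
  g
}

#' Write a graph in SIF (simple interaction format)
#'
#' One line per edge: `source <TAB> interaction <TAB> target`, using the
#' node display labels and the relation rule as the interaction keyword.
#' Isolated nodes are written as single-column lines, as Cytoscape expects.
#'
#' @param graph an igraph as built by [build_binary_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path) {
  labs <- vertex_labels(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  rules <- igraph::edge_attr(graph, "rule")
  if (is.null(rules)) rules <- rep("relation", nrow(el))
  lines <- character()
  if (nrow(el)) {
    lines <- paste(labs[el[, 1L]], rules, labs[el[, 2L]], sep = "\t")
  }
  isolated <- setdiff(seq_along(labs),
                      unique(as.vector(el)))
  lines <- c(lines, labs[isolated])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Write a graph as GraphML with node and edge attributes
#'
#' Thin wrapper over [igraph::write_graph()]; the exported file carries the
#' node labels, molecule classes and edge provenance and opens in
#' Cytoscape.
#'
#' @param graph an igraph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

# Display labels with a fallback chain: display attr, then name.
vertex_labels <- function(graph) {
  labs <- igraph::vertex_attr(graph, "display")
  if (is.null(labs)) labs <- igraph::vertex_attr(graph, "name")
  if (is.null(labs)) labs <- as.character(seq_len(igraph::vcount(graph)))
  labs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
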