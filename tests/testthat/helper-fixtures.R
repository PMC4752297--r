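# Fixtures are built in code; nothing is read from disk.

# Three-species map: protein A --(state transition, modifier M)--> phenotype P
tiny_map <- function() {
  sp <- data.frame(
    id = c("s1", "s2", "s3"),
    name = c("A", "P", "M"),
    molecule_class = c("PROTEIN", "PHENOTYPE", "PROTEIN"),
    compartment = "default", stringsAsFactors = FALSE)
  rx <- data.frame(id = "r1", reaction_type = "STATE_TRANSITION",
                   reversible = FALSE, stringsAsFactors = FALSE)
  rx$reactants <- list("s1")
  rx$products <- list("s2")
  rx$modifiers <- list("s3")
  pathway_map(sp, rx, source_name = "tiny")
}

# Build a pathway_map from a compact reaction spec:
# species: named character vector id -> class; reactions: list of
# list(r =, p =, m =, type =, rev =) with species ids.
make_map <- function(species_classes, reactions = list(),
                     names = NULL) {
  ids <- names(species_classes)
  sp <- data.frame(
    id = ids,
    name = if (is.null(names)) ids else names,
    molecule_class = unname(species_classes),
    compartment = "default", stringsAsFactors = FALSE)
  if (!length(reactions)) {
    return(pathway_map(sp, source_name = "fixture"))
  }
  rx <- data.frame(
    id = sprintf("r%d", seq_along(reactions)),
    reaction_type = vapply(reactions, function(x) x$type %||%
                             "STATE_TRANSITION", character(1)),
    reversible = vapply(reactions, function(x) isTRUE(x$rev), logical(1)),
    stringsAsFactors = FALSE)
  rx$reactants <- lapply(reactions, function(x) x$r %||% character())
  rx$products <- lapply(reactions, function(x) x$p %||% character())
  rx$modifiers <- lapply(reactions, function(x) x$m %||% character())
  pathway_map(sp, rx, source_name = "fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Named undirected graph from an edge list given as c(from, to, from, to, …)
named_graph <- function(edges, directed = FALSE, isolated = character()) {
  el <- matrix(edges, ncol = 2, byrow = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = directed,
    vertices = unique(c(as.vector(t(el)), isolated)))
}

path_graph <- function(labels, directed = FALSE) {
  n <- length(labels)
  named_graph(as.vector(rbind(labels[-n], labels[-1])), directed = directed)
}

# Erdos-Renyi graph with letter labels; resampled until it has >= 1 edge.
random_test_graph <- function(n, p = 0.35, directed = FALSE) {
  repeat {
    g <- igraph::sample_gnp(n, p, directed = directed)
    if (igraph::ecount(g) >= 1) break
  }
  igraph::set_vertex_attr(g, "name",
                          value = sprintf("v%02d", seq_len(n)))
}

# Random reaction role lists over a pool of species ids.
random_reaction <- function(pool) {
  list(id = "rx",
       reactants = sample(pool, sample(0:3, 1)),
       products = sample(pool, sample(0:3, 1)),
       modifiers = sample(pool, sample(0:2, 1)),
       reversible = runif(1) < 0.3)
}

expect_tables_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$nodes$raw[order(a$nodes$node)],
               b$nodes$raw[order(b$nodes$node)], tolerance = tol)
  ka <- paste(pmin(a$edges$from, a$edges$to), pmax(a$edges$from, a$edges$to))
  kb <- paste(pmin(b$edges$from, b$edges$to), pmax(b$edges$from, b$edges$to))
  expect_equal(a$edges$raw[order(ka)], b$edges$raw[order(kb)],
               tolerance = tol)
}

# Drop-in location for the real curated map, when a user supplies it.
real_map_path <- function() {
  system.file("extdata", "alzpathway_sbml_map.xml", package = "pdnet")
}
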