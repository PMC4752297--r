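test_that("reaction decomposition emits the reactant-product and modifier-product pairs", {
  rel <- decompose_reaction(list(id = "r1", reactants = c("A", "B"),
                                 products = "C", modifiers = "M",
                                 reversible = FALSE))
  expect_equal(rel$source, c("A", "B", "M"))
  expect_equal(rel$target, c("C", "C", "C"))
  expect_equal(rel$rule, c("REACTANT_PRODUCT", "REACTANT_PRODUCT",
                           "MODIFIER_PRODUCT"))
  expect_equal(unique(rel$origin_reaction), "r1")

  # single pair
  rel1 <- decompose_reaction(list(id = "r2", reactants = "A",
                                  products = "B", modifiers = character(),
                                  reversible = FALSE))
  expect_equal(nrow(rel1), 1)
  expect_equal(rel1$source, "A")
  expect_equal(rel1$target, "B")

  # 2 reactants x 2 products + 2 modifiers x 2 products = 8
  rel8 <- decompose_reaction(list(id = "r3", reactants = c("A", "B"),
                                  products = c("C", "D"),
                                  modifiers = c("M", "N"),
                                  reversible = FALSE))
  expect_equal(nrow(rel8), 8)
  # deterministic order: reactants outer, products inner, modifiers after
  expect_equal(rel8$source, c("A", "A", "B", "B", "M", "M", "N", "N"))
  expect_equal(rel8$target, rep(c("C", "D"), 4))

  # reversible adds the (product, reactant) pairs, not modifier mirrors
  rev <- decompose_reaction(list(id = "r4", reactants = "A", products = "B",
                                 modifiers = "M", reversible = TRUE))
  expect_equal(nrow(rev), 3)
  expect_equal(rev$source[3], "B")
  expect_equal(rev$target[3], "A")
  expect_equal(rev$rule[3], "REACTANT_PRODUCT")

  expect_warning(
    empty <- decompose_reaction(list(id = "r5", reactants = "A",
                                     products = character(),
                                     modifiers = "M", reversible = FALSE)),
    "no products")
  expect_equal(nrow(empty), 0)
})

test_that("decomposition size is |R||P| + |M||P|, doubled for reversible", {
  set.seed(42)
  pool <- sprintf("s%02d", 1:12)
  for (i in 1:60) {
    rx <- random_reaction(pool)
    n_expected <- length(rx$reactants) * length(rx$products) +
      length(rx$modifiers) * length(rx$products) +
      if (rx$reversible) length(rx$products) * length(rx$reactants) else 0
    rel <- suppressWarnings(decompose_reaction(rx))
    expect_equal(nrow(rel), n_expected)
  }
})

test_that("binary graph deduplicates parallel relations and keeps provenance", {
  m <- make_map(c(a = "PROTEIN", c = "PROTEIN"),
                list(list(r = "a", p = "c"),
                     list(r = "a", p = "c", type = "TRANSPORT")))
  g <- build_binary_graph(m)
  expect_equal(igraph::ecount(g), 1)
  ed <- igraph::as_data_frame(g)
  expect_equal(ed$n_relations, 2)
  expect_equal(ed$origins, "r1,r2")
})

test_that("disallowed classes and self-loops never reach the graph", {
  # an ion reactant: the relation is dropped and the ion is absent
  m <- make_map(c(ca = "ION", x = "PROTEIN", y = "PROTEIN"),
                list(list(r = c("ca", "y"), p = "x")))
  g <- build_binary_graph(m)
  expect_false(any(igraph::V(g)$molecule_class == "ION"))
  expect_equal(igraph::ecount(g), 1)  # only y -> x survives

  # transport recorded under a single species id becomes a self-loop: dropped
  mt <- make_map(c(x = "PROTEIN", y = "PROTEIN"),
                 list(list(r = "x", p = "x", type = "TRANSPORT"),
                      list(r = "x", p = "y")))
  gt <- build_binary_graph(mt)
  expect_equal(igraph::ecount(gt), 1)
  expect_false(igraph::any_loop(gt))

  # property over synthetic maps: default graph is simple, no ION/DEGRADED
  for (s in 1:4) {
    cfg <- synthetic_map_config(
      c(PROTEIN = 15L, ION = 5L, DEGRADED = 4L, PHENOTYPE = 3L),
      c(STATE_TRANSITION = 12L, OMITTED_TRANSITION = 4L), seed = s)
    g <- build_binary_graph(generate_map(cfg)$map)
    expect_false(any(igraph::V(g)$molecule_class %in% c("ION", "DEGRADED")))
    expect_false(igraph::any_loop(g))
    expect_false(igraph::any_multiple(g))
  }
})

test_that("merge-by-name unifies same-named species of the same class only", {
  sp <- data.frame(
    id = c("c1x", "c2x", "gene"),
    name = c("NFKB", "NFKB", "NFKB"),
    molecule_class = c("PROTEIN", "PROTEIN", "GENE"),
    compartment = c("cytosol", "nucleus", "nucleus"),
    stringsAsFactors = FALSE)
  rx <- data.frame(id = c("t1", "t2"),
                   reaction_type = c("TRANSPORT", "TRANSCRIPTION"),
                   reversible = FALSE, stringsAsFactors = FALSE)
  rx$reactants <- list("c1x", "gene")
  rx$products <- list("c2x", "c1x")
  rx$modifiers <- list(character(), character())
  m <- pathway_map(sp, rx)

  g <- build_binary_graph(m, merge_by_name = TRUE)
  # the two protein aliases merge (making t1 a self-loop); the gene stays
  expect_equal(igraph::vcount(g), 2)
  expect_equal(sort(igraph::V(g)$molecule_class), c("GENE", "PROTEIN"))
  expect_equal(igraph::ecount(g), 1)

  g2 <- build_binary_graph(m, merge_by_name = FALSE)
  expect_equal(igraph::vcount(g2), 3)
  expect_equal(igraph::ecount(g2), 2)
})

test_that("enlarging allowed_classes never removes nodes or edges", {
  set.seed(7)
  cfg <- synthetic_map_config(
    c(PROTEIN = 12L, SIMPLE_MOLECULE = 6L, ION = 6L, PHENOTYPE = 4L),
    c(STATE_TRANSITION = 14L, TRANSPORT = 6L), seed = 11)
  m <- generate_map(cfg)$map
  g_small <- build_binary_graph(m, allowed_classes = c("PROTEIN",
                                                       "SIMPLE_MOLECULE"))
  g_big <- build_binary_graph(m, allowed_classes = DEFAULT_ALLOWED_CLASSES)
  g_all <- build_binary_graph(m, allowed_classes = MOLECULE_CLASSES)

  edge_keys <- function(g) {
    el <- igraph::as_edgelist(g)
    if (!nrow(el)) return(character())
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  expect_true(all(igraph::V(g_small)$name %in% igraph::V(g_big)$name))
  expect_true(all(edge_keys(g_small) %in% edge_keys(g_big)))
  expect_true(all(igraph::V(g_big)$name %in% igraph::V(g_all)$name))
  expect_true(all(edge_keys(g_big) %in% edge_keys(g_all)))

  expect_error(build_binary_graph(m, allowed_classes = character()),
               "at least one")
})

test_that("SIF export writes one labelled line per edge", {
  g <- build_binary_graph(tiny_map())
  f <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, f)
  lines <- readLines(f)
  expect_length(lines, 2)
  expect_true(any(grepl("^A\tREACTANT_PRODUCT\tP$", lines)))
  expect_true(any(grepl("^M\tMODIFIER_PRODUCT\tP$", lines)))
})
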