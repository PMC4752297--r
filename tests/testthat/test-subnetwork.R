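test_that("top-k edge ranking sorts by score with a lexicographic tie-break", {
  tab <- structure(
    list(nodes = data.frame(node = c("a", "b", "c", "d"),
                            display = c("a", "b", "c", "d"),
                            raw = 0, stringsAsFactors = FALSE),
         edges = data.frame(from = c("c", "a", "b"), to = c("d", "b", "c"),
                            raw = c(3, 1, 3), stringsAsFactors = FALSE),
         normalized = FALSE, directed = FALSE, n_nodes = 4L),
    class = "centrality_table")
  rk <- top_k_edges(tab, k = 2)
  # ties at 3: b-c before c-d lexicographically; a-b (score 1) excluded
  expect_equal(rk$from, c("b", "c"))
  expect_equal(rk$to, c("c", "d"))
  expect_equal(rk$rank, 1:2)

  # k larger than the edge count returns everything, sorted
  rk_all <- top_k_edges(tab, k = 99)
  expect_equal(nrow(rk_all), 3)
  expect_true(all(diff(rk_all$score) <= 0))

  expect_error(top_k_edges(tab, k = 0), "positive")
  expect_error(top_k_edges(tab, k = -3), "positive")

  # path a-b-c-d: the middle edge uniquely carries the most pairs (raw 4)
  p4 <- path_graph(c("a", "b", "c", "d"))
  rk1 <- top_k_edges(edge_betweenness(p4), k = 1)
  expect_equal(sort(c(rk1$from, rk1$to)), c("b", "c"))
  expect_equal(rk1$score, 4)
})

test_that("k-hop neighbourhoods retain exactly the nodes within reach", {
  p5 <- path_graph(c("a", "b", "c", "d", "e"))
  sn <- khop_neighborhood(p5, seeds = "a", hops = 2)
  expect_setequal(igraph::V(sn$graph)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(sn$graph), 2)

  # union over seeds
  sn2 <- khop_neighborhood(p5, seeds = c("a", "e"), hops = 2)
  expect_setequal(igraph::V(sn2$graph)$name, c("a", "b", "c", "d", "e"))

  # zero hops: the seed alone, no edges
  sn0 <- khop_neighborhood(p5, seeds = "c", hops = 0)
  expect_equal(igraph::V(sn0$graph)$name, "c")
  expect_equal(igraph::ecount(sn0$graph), 0)

  expect_error(khop_neighborhood(p5, seeds = "q", hops = 1),
               "does not resolve")
  expect_error(khop_neighborhood(p5, seeds = "a", hops = -1),
               "non-negative")
})

test_that("seed labels match case-insensitively and report near misses", {
  g <- build_binary_graph(make_map(
    c(s1 = "SIMPLE_MOLECULE", s2 = "PHENOTYPE", s3 = "PROTEIN"),
    list(list(r = "s1", p = "s2", m = "s3")),
    names = c("Ceramide", "Inflammation", "SMPD1")))
  sn <- khop_neighborhood(g, seeds = c("ceramide", "INFLAMMATION "),
                          hops = 1)
  expect_setequal(sn$seeds, c("Ceramide", "Inflammation"))

  err <- tryCatch(khop_neighborhood(g, seeds = "Ceramid", hops = 1),
                  error = conditionMessage)
  expect_match(err, "near misses")
  expect_match(err, "Ceramide")

  # ambiguity: two distinct nodes with the same label
  g2 <- build_binary_graph(make_map(
    c(a = "PROTEIN", b = "GENE", c = "PROTEIN"),
    list(list(r = "a", p = "c", m = "b")),
    names = c("TREM2", "TREM2", "DAP12")), merge_by_name = TRUE)
  expect_error(khop_neighborhood(g2, seeds = "TREM2", hops = 1),
               "ambiguous")
})

test_that("k-hop subnetworks satisfy containment, monotonicity and inducedness", {
  set.seed(515)
  for (i in 1:15) {
    g <- random_test_graph(sample(6:12, 1), p = 0.3)
    seeds <- sample(igraph::V(g)$name, 2)
    prev <- character()
    for (h in 0:3) {
      sn <- khop_neighborhood(g, seeds = seeds, hops = h)
      keep <- igraph::V(sn$graph)$name
      # seeds always contained; node set grows monotonically with hops
      expect_true(all(seeds %in% keep))
      expect_true(all(prev %in% keep))
      # distance bound: every retained node within h of some seed
      d <- igraph::distances(g, v = seeds, to = keep)
      expect_true(all(apply(d, 2, min) <= h))
      # nothing reachable within h is missed
      d_all <- igraph::distances(g, v = seeds)
      expect_setequal(keep,
                      colnames(d_all)[apply(d_all, 2, min) <= h])
      # induced-subgraph property: edge kept iff both ends kept in parent
      el_sub <- igraph::as_edgelist(sn$graph)
      el_par <- igraph::as_edgelist(g)
      key <- function(el) if (!nrow(el)) character() else
        paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      expect_setequal(
        key(el_sub),
        key(el_par)[el_par[, 1] %in% keep & el_par[, 2] %in% keep])
      prev <- keep
    }
  }
})

test_that("re-ranking recomputes betweenness on the induced subnetwork", {
  # a path subnetwork: both edges tie at raw 2, reported in label order
  p3 <- path_graph(c("a", "b", "c"))
  sn <- khop_neighborhood(p3, seeds = "b", hops = 1)
  rk <- rerank_subnetwork(sn, k = 2)
  expect_equal(rk$score, c(2, 2))
  expect_equal(rk$from, c("a", "b"))

  # subnetwork equal to the whole graph reproduces the global ranking
  g <- random_test_graph(9, p = 0.35)
  sn_all <- khop_neighborhood(g, seeds = igraph::V(g)$name[1],
                              hops = igraph::vcount(g))
  if (igraph::vcount(sn_all$graph) == igraph::vcount(g)) {
    rk_sub <- rerank_subnetwork(sn_all, k = 10)
    rk_full <- top_k_edges(edge_betweenness(g), k = 10)
    expect_equal(rk_sub$score, rk_full$score)
  }

  # locality: scores depend only on the induced graph (oracle recheck)
  set.seed(616)
  for (i in 1:10) {
    g <- random_test_graph(8, p = 0.4)
    seed <- sample(igraph::V(g)$name, 1)
    sn <- khop_neighborhood(g, seeds = seed, hops = 2)
    if (igraph::ecount(sn$graph) == 0 ||
        igraph::vcount(sn$graph) > 15) next
    rk <- rerank_subnetwork(sn, k = igraph::ecount(sn$graph))
    oracle <- brute_force_betweenness(sn$graph)
    ork <- top_k_edges(oracle, k = igraph::ecount(sn$graph))
    # per-edge scores agree with the oracle; rank order may differ only
    # where floating-point sums of tied edges differ below tolerance
    key <- function(r) paste(pmin(r$from, r$to), pmax(r$from, r$to))
    expect_setequal(key(rk), key(ork))
    expect_equal(rk$score[order(key(rk))], ork$score[order(key(ork))],
                 tolerance = 1e-9)
    expect_true(all(diff(rk$score) <= 1e-9))
  }
})
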