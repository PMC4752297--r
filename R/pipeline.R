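#' Assemble a pipeline run configuration
#'
#' Collects every convention that can change a number in the analysis into
#' one object, with defaults reproducing the standard disease-map
#' analysis: six allowed molecule classes, undirected analysis, normalised
#' node betweenness, top 50 edges, and a two-hop subnetwork around
#' "Ceramide" and "Inflammation".
#'
#' @param input path to a CellDesigner-dialect SBML file, or `NULL` when
#'   `preset` is given.
#' @param preset name of a synthesis preset (`"alzpathway-like"`) used
#'   instead of an input file.
#' @param out_dir directory the run writes its artifacts into.
#' @param allowed_classes molecule classes admitted to the binary graph.
#' @param directed analyse the graph as directed? Default `FALSE`.
#' @param normalized report normalised node betweenness? Default `TRUE`.
#' @param k size of the top-k edge ranking (default 50).
#' @param seeds seed node labels for the subnetwork stage; `NULL` skips
#'   that stage.
#' @param hops hop budget of the subnetwork (default 2).
#' @param merge_by_name unify same-named species across compartments?
#' @param overwrite allow writing into an existing non-empty `out_dir`?
#'   When `FALSE` (default) the run refuses instead of clobbering.
#' @param seed random seed, used only when synthesising from a preset.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, preset = NULL, out_dir,
                       allowed_classes = DEFAULT_ALLOWED_CLASSES,
                       directed = FALSE, normalized = TRUE, k = 50L,
                       seeds = c("Ceramide", "Inflammation"), hops = 2L,
                       merge_by_name = TRUE, overwrite = FALSE,
                       seed = 1L) {
  if (is.null(input) && is.null(preset)) {
    stop("either an input file or a synthesis preset is required")
  }
  structure(
    list(input = input, preset = preset, out_dir = out_dir,
         allowed_classes = allowed_classes, directed = directed,
         normalized = normalized, k = as.integer(k), seeds = seeds,
         hops = as.integer(hops), merge_by_name = merge_by_name,
         overwrite = overwrite, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full map-to-rankings pipeline
#'
#' Orchestrates every stage end to end: obtain a map (parse the input
#' file, or synthesise from a preset), write the species and reaction
#' census tables, build the binary-relation graph, compute node and edge
#' betweenness, extract the top-k "primary pathway", extract and re-rank
#' the k-hop seed subnetwork, and write a manifest recording every
#' convention together with an MD5 digest of the input. Stages log as they
#' run; any stage error aborts the run with the stage named.
#'
#' Artifacts written into `config$out_dir`:
#' \itemize{
#'   \item `species_census.tsv`, `reaction_census.tsv`
#'   \item `binary_graph.sif`, `binary_graph.graphml`
#'   \item `node_betweenness.tsv`, `edge_betweenness.tsv`
#'   \item `primary_pathway.tsv`, `.sif`, `.graphml` (top-k edges)
#'   \item `subnetwork.sif`, `.graphml`, `subnetwork_top_edges.tsv`
#'   \item `synthetic_input.xml` (+ ledger TSVs) when run from a preset
#'   \item `manifest.json`
#' }
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`map`,
#'   `graph`, `centrality`, `primary`, `subnetwork`) and the artifact
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    message("[pdnet] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  out <- config$out_dir
  if (dir.exists(out) && length(dir(out, all.files = FALSE)) &&
      !isTRUE(config$overwrite)) {
    stop("output directory '", out, "' exists and is not empty; ",
         "set overwrite = TRUE to rerun into it")
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- input -----------------------------------------------------------
  if (!is.null(config$preset)) {
    map <- stage("synthesize", {
      cfg <- switch(config$preset,
        "alzpathway-like" = make_alzpathway_like_config(seed = config$seed),
        stop("unknown preset '", config$preset, "'"))
      syn <- generate_map(cfg)
      paths$synthetic_input <- file.path(out, "synthetic_input.xml")
      write_celldesigner_map(syn$map, paths$synthetic_input)
      paths$synthetic_hubs <- file.path(out, "synthetic_hubs.tsv")
      write_utf8_tsv(syn$ledger$hubs, paths$synthetic_hubs)
      syn$map
    })
    input_for_digest <- paths$synthetic_input
  } else {
    map <- stage("parse", parse_celldesigner_map(config$input))
    input_for_digest <- config$input
  }

  # --- census ----------------------------------------------------------
  stage("census", {
    paths$species_census <- file.path(out, "species_census.tsv")
    write_census_tsv(census_species(map), paths$species_census)
    paths$reaction_census <- file.path(out, "reaction_census.tsv")
    write_census_tsv(census_reactions(map), paths$reaction_census)
  })

  # --- binarize --------------------------------------------------------
  graph <- stage("binarize", {
    g <- build_binary_graph(map, allowed_classes = config$allowed_classes,
                            directed = config$directed,
                            merge_by_name = config$merge_by_name)
    paths$graph_sif <- file.path(out, "binary_graph.sif")
    write_sif(g, paths$graph_sif)
    paths$graph_graphml <- file.path(out, "binary_graph.graphml")
    write_graphml(g, paths$graph_graphml)
    g
  })

  # --- centrality ------------------------------------------------------
  centrality <- stage("centrality", {
    tab <- node_betweenness(graph, normalized = config$normalized)
    paths$node_scores <- file.path(out, "node_betweenness.tsv")
    write_centrality_tsv(tab, paths$node_scores, what = "nodes")
    paths$edge_scores <- file.path(out, "edge_betweenness.tsv")
    write_centrality_tsv(tab, paths$edge_scores, what = "edges")
    tab
  })

  # --- primary pathway -------------------------------------------------
  primary <- stage("primary-pathway", {
    rk <- top_k_edges(centrality, k = config$k)
    paths$primary_tsv <- file.path(out, "primary_pathway.tsv")
    write_ranking_tsv(rk, paths$primary_tsv, graph = graph)
    sub_g <- igraph::subgraph_from_edges(
      graph, igraph::get_edge_ids(graph, as.vector(rbind(rk$from, rk$to))))
    paths$primary_sif <- file.path(out, "primary_pathway.sif")
    write_sif(sub_g, paths$primary_sif)
    paths$primary_graphml <- file.path(out, "primary_pathway.graphml")
    write_graphml(sub_g, paths$primary_graphml)
    rk
  })

  # --- seed subnetwork -------------------------------------------------
  subnet <- NULL
  if (!is.null(config$seeds)) {
    subnet <- stage("subnetwork", {
      sn <- khop_neighborhood(graph, seeds = config$seeds,
                              hops = config$hops)
      paths$subnetwork_sif <- file.path(out, "subnetwork.sif")
      write_sif(sn$graph, paths$subnetwork_sif)
      paths$subnetwork_graphml <- file.path(out, "subnetwork.graphml")
      write_graphml(sn$graph, paths$subnetwork_graphml)
      rk <- rerank_subnetwork(sn, k = config$k)
      paths$subnetwork_ranking <- file.path(out, "subnetwork_top_edges.tsv")
      write_ranking_tsv(rk, paths$subnetwork_ranking, graph = sn$graph)
      sn
    })
  }

  # --- manifest --------------------------------------------------------
  stage("manifest", {
    manifest <- list(
      package = "pdnet",
      version = as.character(utils::packageVersion("pdnet")),
      input = input_for_digest,
      input_md5 = unname(tools::md5sum(input_for_digest)),
      preset = config$preset,
      conventions = list(
        allowed_classes = sort(config$allowed_classes),
        directed = config$directed,
        normalized = config$normalized,
        merge_by_name = config$merge_by_name,
        self_loops = "removed",
        parallel_edges = "collapsed, provenance retained",
        tie_rule = "lexicographic on sorted (source, target) labels",
        hop_distance = "undirected skeleton"
      ),
      k = config$k, seeds = config$seeds, hops = config$hops,
      random_seed = config$seed,
      n_nodes = igraph::vcount(graph), n_edges = igraph::ecount(graph)
    )
    paths$manifest <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  })

  invisible(list(map = map, graph = graph, centrality = centrality,
                 primary = primary, subnetwork = subnet, paths = paths))
}
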