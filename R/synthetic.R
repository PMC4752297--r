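#' Configuration for the synthetic pathway-map generator
#'
#' Describes a synthetic CellDesigner-dialect map: how many species of each
#' molecule class, how many reactions of each type, the arity distribution
#' reactions draw their role counts from, optional planted hubs, and the
#' random seed. The generator records everything it draws in a ground-truth
#' ledger so recovery tests can compare pipeline output against known
#' truth.
#'
#' @param n_species_per_class named integer vector over (a subset of)
#'   [MOLECULE_CLASSES].
#' @param n_reactions_per_type named integer vector over (a subset of)
#'   [REACTION_TYPES].
#' @param arity list with elements `reactants`, `products`, `modifiers`,
#'   each a named numeric vector of sampling weights over role counts
#'   (names are the counts). The default draws 1-3 reactants, 1-2 products
#'   and 0-2 modifiers, skewed toward small reactions; structurally fixed
#'   types (heterodimer association 2-to-1, dissociation 1-to-2, transport
#'   and transcription/translation 1-to-1) override it.
#' @param hub_spec optional list of `list(label =, class =, degree =)`
#'   entries planting named high-degree nodes; the generator keeps wiring
#'   a hub into reactions until its approximate binary-graph degree
#'   reaches `degree`.
#' @param reversible_prob probability that a reaction is marked
#'   reversible. Default 0.1.
#' @param phenotypes_as_products keep phenotype species out of reactant
#'   and modifier roles? Default `TRUE`: phenotypes are outcome states.
#' @param seed integer random seed; identical configs with identical seeds
#'   generate byte-identical maps.
#' @return A `synthetic_map_config`.
#' @export
synthetic_map_config <- function(n_species_per_class,
                                 n_reactions_per_type = integer(),
                                 arity = default_arity(),
                                 hub_spec = NULL,
                                 reversible_prob = 0.1,
                                 phenotypes_as_products = TRUE,
                                 seed = 1L) {
  n_species_per_class <- validate_counts(n_species_per_class,
                                         MOLECULE_CLASSES, "species class")
  n_reactions_per_type <- validate_counts(n_reactions_per_type,
                                          REACTION_TYPES, "reaction type")
  stopifnot(is.list(arity),
            all(c("reactants", "products", "modifiers") %in% names(arity)))
  if (!is.null(hub_spec)) {
    for (h in hub_spec) {
      stopifnot(is.list(h), !is.null(h$label), !is.null(h$degree))
      h$class <- h$class %||% "PROTEIN"
      if (!(h$class %in% MOLECULE_CLASSES)) {
        stop("hub class must be a recognised molecule class: ", h$class)
      }
    }
  }
  if (sum(n_reactions_per_type) > 0L && sum(n_species_per_class) < 2L) {
    stop("infeasible config: reactions requested but fewer than 2 species")
  }
  structure(
    list(n_species_per_class = n_species_per_class,
         n_reactions_per_type = n_reactions_per_type,
         arity = arity, hub_spec = hub_spec,
         reversible_prob = reversible_prob,
         phenotypes_as_products = phenotypes_as_products,
         seed = as.integer(seed)),
    class = "synthetic_map_config"
  )
}

validate_counts <- function(x, levels, what) {
  if (!length(x)) return(stats::setNames(integer(), character()))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("counts per ", what, " must be a named vector")
  }
  bad <- setdiff(names(x), levels)
  if (length(bad)) stop("unknown ", what, "(s): ", paste(bad, collapse = ", "))
  if (any(x < 0) || any(is.na(x))) stop(what, " counts must be non-negative")
  stats::setNames(as.integer(x), names(x))
}

default_arity <- function() {
  list(reactants = c(`1` = 0.6, `2` = 0.3, `3` = 0.1),
       products = c(`1` = 0.8, `2` = 0.2),
       modifiers = c(`0` = 0.6, `1` = 0.3, `2` = 0.1))
}

# Role-count overrides for structurally fixed reaction types.
type_arity <- function(type, arity) {
  switch(type,
    HETERODIMER_ASSOCIATION = list(reactants = c(`2` = 1),
                                   products = c(`1` = 1),
                                   modifiers = arity$modifiers),
    DISSOCIATION = list(reactants = c(`1` = 1), products = c(`2` = 1),
                        modifiers = arity$modifiers),
    TRANSPORT = list(reactants = c(`1` = 1), products = c(`1` = 1),
                     modifiers = c(`0` = 1)),
    TRANSCRIPTION = list(reactants = c(`1` = 1), products = c(`1` = 1),
                         modifiers = arity$modifiers),
    TRANSLATION = list(reactants = c(`1` = 1), products = c(`1` = 1),
                       modifiers = arity$modifiers),
    arity
  )
}

#' Configuration emulating a large curated Alzheimer's disease map
#'
#' Returns a [synthetic_map_config()] whose class and reaction-type
#' composition equals the published census of the AlzPathway 3 map:
#' 721 proteins, 246 complexes, 300 simple molecules, 33 genes, 37 RNAs,
#' 24 ions, 23 degraded products and 138 phenotypes (1,522 species), and
#' 472 state transitions, 22 transcriptions, 30 translations, 184
#' heterodimer associations, 56 dissociations, 106 transports, 22 unknown
#' transitions, 6 unknown negative influences and 226 omitted transitions
#' (1,124 reactions). Only the composition is emulated; the wiring is the
#' generator's preferential-attachment background, not the real topology.
#'
#' Three named nodes are planted so the default end-to-end analysis has
#' its conventional anchors: an "amyloid-β"-like protein hub, a
#' "Ceramide"-like simple-molecule hub, and an "Inflammation" phenotype.
#'
#' @param seed integer random seed for the generator.
#' @return A `synthetic_map_config`.
#' @export
make_alzpathway_like_config <- function(seed = 1L) {
  synthetic_map_config(
    n_species_per_class = c(
      PROTEIN = 721L, COMPLEX = 246L, SIMPLE_MOLECULE = 300L, GENE = 33L,
      RNA = 37L, ION = 24L, DEGRADED = 23L, PHENOTYPE = 138L),
    n_reactions_per_type = c(
      STATE_TRANSITION = 472L, TRANSCRIPTION = 22L, TRANSLATION = 30L,
      HETERODIMER_ASSOCIATION = 184L, DISSOCIATION = 56L, TRANSPORT = 106L,
      UNKNOWN_TRANSITION = 22L, UNKNOWN_NEGATIVE_INFLUENCE = 6L,
      OMITTED_TRANSITION = 226L),
    hub_spec = list(
      list(label = "amyloid-β", class = "PROTEIN", degree = 60L),
      list(label = "Ceramide", class = "SIMPLE_MOLECULE", degree = 40L),
      list(label = "Inflammation", class = "PHENOTYPE", degree = 12L)),
    seed = seed
  )
}

#' Generate a synthetic pathway map with a ground-truth ledger
#'
#' Draws a species population and reaction population exactly per the
#' config counts, wires reaction participants by preferential attachment
#' (sampling probability proportional to 1 + current degree, which yields
#' the heavy-tailed degree structure typical of curated disease maps) and
#' forces planted hubs into reactions until each reaches its target
#' degree. Transcription reads genes into RNAs and translation RNAs into
#' proteins when those classes are available; phenotypes appear only in
#' product roles by default.
#'
#' Generation is fully deterministic given the config (including its
#' seed); writing the map with [write_celldesigner_map()] yields
#' byte-identical files across runs.
#'
#' @param config a [synthetic_map_config()].
#' @return A list of class `synthetic_map` with elements `map` (a
#'   [pathway_map()]) and `ledger` (ground truth: the config, the exact
#'   censuses of the emitted map, and the planted-hub assignments).
#' @export
generate_map <- function(config) {
  stopifnot(inherits(config, "synthetic_map_config"))

  # keep the caller's RNG state untouched
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(config$seed)

  # --- species population ----------------------------------------------
  classes <- names(config$n_species_per_class)
  sp_list <- lapply(classes, function(cl) {
    n <- config$n_species_per_class[[cl]]
    if (!n) return(NULL)
    data.frame(
      name = paste(tolower(gsub("_", " ", cl)), seq_len(n)),
      molecule_class = cl, stringsAsFactors = FALSE)
  })
  species <- do.call(rbind, sp_list)
  if (is.null(species)) species <- data.frame(name = character(),
                                              molecule_class = character(),
                                              stringsAsFactors = FALSE)
  if (nrow(species)) {
    species$id <- sprintf("sp%04d", seq_len(nrow(species)))
    species$compartment <- "default"
  } else {
    species$id <- character()
    species$compartment <- character()
  }

  # plant hubs: relabel the first unclaimed species of the hub's class
  hubs <- data.frame(label = character(), class = character(),
                     target_degree = integer(), species_id = character(),
                     stringsAsFactors = FALSE)
  for (h in config$hub_spec %||% list()) {
    cls <- h$class %||% "PROTEIN"
    cand <- which(species$molecule_class == cls &
                    !(species$id %in% hubs$species_id))
    if (!length(cand)) {
      stop("hub '", h$label, "' requests class ", cls,
           " but the config has no unclaimed species of that class")
    }
    i <- cand[1L]
    species$name[i] <- h$label
    hubs <- rbind(hubs, data.frame(
      label = h$label, class = cls, target_degree = as.integer(h$degree),
      species_id = species$id[i], stringsAsFactors = FALSE))
  }

  # --- reaction population ---------------------------------------------
  types <- rep(names(config$n_reactions_per_type),
               times = config$n_reactions_per_type)
  if (length(types) > 1L) types <- sample(types)

  is_pheno <- species$molecule_class == "PHENOTYPE"
  reactant_pool <- if (config$phenotypes_as_products) {
    species$id[!is_pheno]
  } else species$id
  if (length(types) && length(reactant_pool) < 1L) {
    stop("infeasible config: reactions requested but no species is ",
         "eligible as a reactant")
  }
  if (length(types) && nrow(species) < 2L) {
    stop("infeasible config: reactions requested but fewer than 2 species")
  }

  deg <- stats::setNames(rep(0L, nrow(species)), species$id)
  class_of <- stats::setNames(species$molecule_class, species$id)
  hub_is_product_side <- hubs$class == "PHENOTYPE"

  draw_n <- function(weights) {
    as.integer(sample(names(weights), 1L, prob = weights))
  }
  # preferential attachment: P(species) propto 1 + degree
  pa_sample <- function(pool, k) {
    k <- min(k, length(pool))
    if (k <= 0L) return(character())
    sample(pool, k, prob = 1 + deg[pool])
  }

  reactions <- vector("list", length(types))
  for (i in seq_along(types)) {
    ty <- types[i]
    ar <- type_arity(ty, config$arity)
    n_r <- draw_n(ar$reactants)
    n_p <- draw_n(ar$products)
    n_m <- draw_n(ar$modifiers)

    forced_reactant <- forced_product <- character()
    pending <- which(deg[hubs$species_id] < hubs$target_degree)
    if (length(pending)) {
      # wire in the hub furthest from its target
      deficit <- hubs$target_degree[pending] - deg[hubs$species_id[pending]]
      hsel <- pending[which.max(deficit)]
      if (hub_is_product_side[hsel]) {
        forced_product <- hubs$species_id[hsel]
      } else {
        forced_reactant <- hubs$species_id[hsel]
      }
    }

    # class-aware pools for the genetic-information reactions
    r_pool <- reactant_pool
    p_pool <- species$id
    if (ty == "TRANSCRIPTION" && any(class_of[r_pool] == "GENE")) {
      r_pool <- r_pool[class_of[r_pool] == "GENE"]
    }
    if (ty == "TRANSCRIPTION" && any(class_of == "RNA")) {
      p_pool <- species$id[class_of == "RNA"]
    }
    if (ty == "TRANSLATION" && any(class_of[r_pool] == "RNA")) {
      r_pool <- r_pool[class_of[r_pool] == "RNA"]
    }
    if (ty == "TRANSLATION" && any(class_of == "PROTEIN")) {
      p_pool <- species$id[class_of == "PROTEIN"]
    }

    reactants <- unique(c(
      forced_reactant,
      pa_sample(setdiff(r_pool, forced_reactant),
                n_r - length(forced_reactant))))
    p_cand <- setdiff(p_pool, c(reactants, forced_product))
    if (!length(p_cand)) p_cand <- setdiff(species$id, reactants)
    products <- unique(c(forced_product,
                         pa_sample(p_cand, n_p - length(forced_product))))
    modifiers <- pa_sample(setdiff(reactant_pool, c(reactants, products)),
                           n_m)

    # degree bookkeeping mirrors the relations the reaction will yield
    for (x in c(reactants, modifiers)) deg[x] <- deg[x] + length(products)
    for (x in products) deg[x] <- deg[x] + length(reactants) +
      length(modifiers)

    reactions[[i]] <- list(
      id = sprintf("re%04d", i), reaction_type = ty,
      reversible = stats::runif(1) < config$reversible_prob,
      reactants = reactants, products = products, modifiers = modifiers)
  }

  rx <- data.frame(
    id = vapply(reactions, `[[`, character(1), "id"),
    reaction_type = vapply(reactions, `[[`, character(1), "reaction_type"),
    reversible = vapply(reactions, `[[`, logical(1), "reversible"),
    stringsAsFactors = FALSE)
  rx$reactants <- lapply(reactions, `[[`, "reactants")
  rx$products <- lapply(reactions, `[[`, "products")
  rx$modifiers <- lapply(reactions, `[[`, "modifiers")
  if (!length(types)) rx <- empty_reaction_table()

  map <- pathway_map(
    species[, c("id", "name", "molecule_class", "compartment")], rx,
    source_name = sprintf("synthetic_map_seed%d", config$seed))

  ledger <- list(
    config = config,
    species_census = census_species(map),
    reaction_census = census_reactions(map),
    hubs = hubs,
    final_degrees = deg
  )
  structure(list(map = map, ledger = ledger), class = "synthetic_map")
}

#' @export
print.synthetic_map <- function(x, ...) {
  cat("<synthetic_map> seed ", x$ledger$config$seed, "\n", sep = "")
  print(x$map)
  if (nrow(x$ledger$hubs)) {
    cat("  planted hubs: ",
        paste(x$ledger$hubs$label, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
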