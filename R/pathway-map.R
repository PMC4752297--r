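#' Construct a pathway map
#'
#' A `pathway_map` is the in-memory form of a process-description map: a
#' species table, a reaction table with role lists, and the parse warnings
#' accumulated while building it. Most users obtain one from
#' [parse_celldesigner_map()] or [generate_map()] rather than calling this
#' constructor directly.
#'
#' @param species data frame with columns `id`, `name`, `molecule_class`,
#'   `compartment`. `molecule_class` must be one of [MOLECULE_CLASSES].
#' @param reactions data frame with columns `id`, `reaction_type`,
#'   `reversible`, and list columns `reactants`, `products`, `modifiers`
#'   holding character vectors of species ids. `reaction_type` must be one
#'   of [REACTION_TYPES].
#' @param source_name label recording where the map came from.
#' @param warnings character vector of parse warnings to carry along.
#'
#' @return An object of class `pathway_map`.
#' @export
pathway_map <- function(species = empty_species_table(),
                        reactions = empty_reaction_table(),
                        source_name = "<in-memory>",
                        warnings = character()) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)

  required_sp <- c("id", "name", "molecule_class", "compartment")
  if (!all(required_sp %in% names(species))) {
    stop("species table must have columns: ", paste(required_sp, collapse = ", "))
  }
  required_rx <- c("id", "reaction_type", "reversible",
                   "reactants", "products", "modifiers")
  if (!all(required_rx %in% names(reactions))) {
    stop("reaction table must have columns: ", paste(required_rx, collapse = ", "))
  }

  if (anyDuplicated(species$id)) {
    stop("duplicate species ids: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  }
  bad_class <- setdiff(unique(species$molecule_class), MOLECULE_CLASSES)
  if (length(bad_class)) {
    stop("unrecognised molecule class(es): ", paste(bad_class, collapse = ", "))
  }
  bad_type <- setdiff(unique(reactions$reaction_type), REACTION_TYPES)
  if (length(bad_type)) {
    stop("unrecognised reaction type(s): ", paste(bad_type, collapse = ", "))
  }

  # referential integrity: every role entry must resolve to a species id
  referenced <- unique(unlist(c(reactions$reactants, reactions$products,
                                reactions$modifiers), use.names = FALSE))
  dangling <- setdiff(referenced, species$id)
  if (length(dangling)) {
    stop("reactions reference unknown species id(s): ",
         paste(dangling, collapse = ", "))
  }

  # empty reactant/product lists are tolerated but flagged
  n_react <- lengths(reactions$reactants)
  n_prod <- lengths(reactions$products)
  degenerate <- reactions$id[n_react == 0L | n_prod == 0L]
  if (length(degenerate)) {
    warnings <- c(warnings, paste0(
      "reaction '", degenerate, "' has an empty reactant or product list"))
  }

  structure(
    list(species = species, reactions = reactions,
         source_name = source_name, warnings = warnings),
    class = "pathway_map"
  )
}

empty_species_table <- function() {
  data.frame(id = character(), name = character(),
             molecule_class = character(), compartment = character(),
             stringsAsFactors = FALSE)
}

empty_reaction_table <- function() {
  out <- data.frame(id = character(), reaction_type = character(),
                    reversible = logical(), stringsAsFactors = FALSE)
  out$reactants <- list()
  out$products <- list()
  out$modifiers <- list()
  out
}

#' @export
print.pathway_map <- function(x, ...) {
  cat("<pathway_map> ", x$source_name, "\n", sep = "")
  cat("  species:   ", nrow(x$species), "\n", sep = "")
  cat("  reactions: ", nrow(x$reactions), "\n", sep = "")
  if (length(x$warnings)) {
    cat("  warnings:  ", length(x$warnings),
        " (see $warnings)\n", sep = "")
  }
  invisible(x)
}

#' Count species by molecule class
#'
#' Tabulates the species of a map over the eight molecule classes. The
#' total always equals the number of species rows, so the published
#' "molecules vs phenotypes" split can be recovered by summing subsets of
#' classes.
#'
#' @param map a [pathway_map()].
#' @return An object of class `type_census`: a list with `counts` (named
#'   integer vector over [MOLECULE_CLASSES]) and `total_species`.
#' @export
census_species <- function(map) {
  stopifnot(inherits(map, "pathway_map"))
  counts <- table(factor(map$species$molecule_class, levels = MOLECULE_CLASSES))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, total_species = nrow(map$species)),
            class = "type_census")
}

#' Count reactions by reaction type
#'
#' @param map a [pathway_map()].
#' @return An object of class `reaction_census`: a list with `counts`
#'   (named integer vector over [REACTION_TYPES]) and `total_reactions`.
#' @export
census_reactions <- function(map) {
  stopifnot(inherits(map, "pathway_map"))
  counts <- table(factor(map$reactions$reaction_type, levels = REACTION_TYPES))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, total_reactions = nrow(map$reactions)),
            class = "reaction_census")
}

#' @export
print.type_census <- function(x, ...) {
  cat("<type_census> total species:", x$total_species, "\n")
  print(x$counts)
  invisible(x)
}

#' @export
print.reaction_census <- function(x, ...) {
  cat("<reaction_census> total reactions:", x$total_reactions, "\n")
  print(x$counts)
  invisible(x)
}

#' Write a census as a two-column TSV
#'
#' @param census a `type_census` or `reaction_census`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_census_tsv <- function(census, path) {
  stopifnot(inherits(census, c("type_census", "reaction_census")))
  df <- data.frame(class = names(census$counts),
                   count = unname(census$counts),
                   stringsAsFactors = FALSE)
  write_utf8_tsv(df, path)
}

# Shared TSV writer: UTF-8, no quoting, tab-separated, trailing newline.
write_utf8_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}
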