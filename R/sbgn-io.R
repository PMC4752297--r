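#' Parse an SBML Level 2 file with CellDesigner annotations
#'
#' Reads a CellDesigner-dialect SBML document into a [pathway_map()]. The
#' molecule class of each species is taken from the
#' `celldesigner:speciesIdentity/celldesigner:class` annotation (phenotypes
#' included), and the reaction type from `celldesigner:reactionType`.
#' Reactant, product and modifier roles are preserved in input order.
#'
#' Species whose CellDesigner class is outside the eight recognised classes
#' are remapped through `class_map` when a mapping is given; otherwise they
#' are excluded and a parse warning is recorded. Role references to excluded
#' or unknown species are dropped with a warning rather than failing the
#' whole parse. All warnings are collected on the returned object
#' (`$warnings`), never silently discarded.
#'
#' One species may have several CellDesigner graphical aliases; the parser
#' keys on the SBML species id, so aliases collapse to a single entity.
#' Complexes are read as single species of class `COMPLEX`; their inner
#' composition is ignored.
#'
#' @param path path to the SBML file.
#' @param class_map optional named character vector remapping CellDesigner
#'   classes outside [MOLECULE_CLASSES] to one of them, e.g.
#'   `c(ANTISENSE_RNA = "RNA")`.
#' @return A [pathway_map()].
#' @export
parse_celldesigner_map <- function(path, class_map = NULL) {
  if (!file.exists(path)) {
    stop("cannot read '", path, "': no such file")
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("XML parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )

  ns_uris <- unclass(xml2::xml_ns(doc))
  if (!CELLDESIGNER_NS %in% ns_uris) {
    stop("dialect unsupported: document does not declare the CellDesigner ",
         "annotation namespace '", CELLDESIGNER_NS, "'")
  }
  if (!is.null(class_map)) {
    bad <- setdiff(unname(class_map), MOLECULE_CLASSES)
    if (length(bad)) {
      stop("class_map targets must be recognised molecule classes; got: ",
           paste(bad, collapse = ", "))
    }
  }

  warnings <- character()
  cd_class_xp <- function(local) {
    sprintf(".//*[local-name()='%s' and namespace-uri()='%s']",
            local, CELLDESIGNER_NS)
  }

  sp_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_comp[is.na(sp_comp)] <- "default"
  sp_class <- vapply(sp_nodes, function(nd) {
    cl <- xml2::xml_find_first(nd, cd_class_xp("class"))
    if (inherits(cl, "xml_missing")) NA_character_ else xml2::xml_text(cl)
  }, character(1))

  missing_cls <- is.na(sp_class)
  if (any(missing_cls)) {
    warnings <- c(warnings, paste0(
      "species '", sp_id[missing_cls],
      "' has no celldesigner:class annotation; excluded"))
  }
  # remap or exclude classes outside the recognised eight
  unknown <- !missing_cls & !(sp_class %in% MOLECULE_CLASSES)
  if (any(unknown)) {
    remappable <- unknown & sp_class %in% names(class_map)
    if (any(remappable)) {
      warnings <- c(warnings, paste0(
        "species '", sp_id[remappable], "': class '", sp_class[remappable],
        "' remapped to '", unname(class_map[sp_class[remappable]]), "'"))
      sp_class[remappable] <- unname(class_map[sp_class[remappable]])
    }
    dropped <- unknown & !remappable
    if (any(dropped)) {
      warnings <- c(warnings, paste0(
        "species '", sp_id[dropped], "': unrecognised class '",
        sp_class[dropped], "'; excluded"))
    }
  }
  keep <- !missing_cls & sp_class %in% MOLECULE_CLASSES
  species <- data.frame(id = sp_id[keep], name = sp_name[keep],
                        molecule_class = sp_class[keep],
                        compartment = sp_comp[keep],
                        stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  known_ids <- species$id
  role_refs <- function(nd, list_name, ref_name) {
    refs <- xml2::xml_find_all(nd, sprintf(
      "./*[local-name()='%s']/*[local-name()='%s']", list_name, ref_name))
    xml2::xml_attr(refs, "species")
  }

  rx_id <- xml2::xml_attr(rx_nodes, "id")
  rx_rev <- xml2::xml_attr(rx_nodes, "reversible")
  # SBML Level 2 default for the reversible attribute is "true"
  rx_rev <- ifelse(is.na(rx_rev), TRUE, tolower(rx_rev) == "true")
  rx_type <- vapply(rx_nodes, function(nd) {
    ty <- xml2::xml_find_first(nd, cd_class_xp("reactionType"))
    if (inherits(ty, "xml_missing")) NA_character_ else xml2::xml_text(ty)
  }, character(1))

  reactants <- products <- modifiers <- vector("list", length(rx_nodes))
  keep_rx <- rep(TRUE, length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    if (is.na(rx_type[i]) || !(rx_type[i] %in% REACTION_TYPES)) {
      warnings <- c(warnings, paste0(
        "reaction '", rx_id[i], "': missing or unrecognised ",
        "celldesigner:reactionType '", rx_type[i], "'; excluded"))
      keep_rx[i] <- FALSE
      next
    }
    roles <- list(
      reactants = role_refs(rx_nodes[[i]], "listOfReactants", "speciesReference"),
      products  = role_refs(rx_nodes[[i]], "listOfProducts", "speciesReference"),
      modifiers = role_refs(rx_nodes[[i]], "listOfModifiers", "modifierSpeciesReference")
    )
    for (role in names(roles)) {
      dangling <- setdiff(roles[[role]], known_ids)
      if (length(dangling)) {
        warnings <- c(warnings, paste0(
          "reaction '", rx_id[i], "': ", role, " reference(s) to ",
          "unknown or excluded species dropped: ",
          paste(dangling, collapse = ", ")))
        roles[[role]] <- roles[[role]][roles[[role]] %in% known_ids]
      }
    }
    reactants[[i]] <- roles$reactants
    products[[i]] <- roles$products
    modifiers[[i]] <- roles$modifiers
  }

  reactions <- data.frame(id = rx_id[keep_rx],
                          reaction_type = rx_type[keep_rx],
                          reversible = rx_rev[keep_rx],
                          stringsAsFactors = FALSE)
  reactions$reactants <- reactants[keep_rx]
  reactions$products <- products[keep_rx]
  reactions$modifiers <- modifiers[keep_rx]

  pathway_map(species, reactions, source_name = basename(path),
              warnings = warnings)
}

#' Write a pathway map as CellDesigner-dialect SBML
#'
#' Emits an SBML Level 2 document carrying the CellDesigner annotation
#' namespace, in the same dialect [parse_celldesigner_map()] reads, so that
#' synthetic maps round-trip through the parser. Output is deterministic:
#' the same map always serialises to the same bytes.
#'
#' @param map a [pathway_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_celldesigner_map <- function(map, path) {
  stopifnot(inherits(map, "pathway_map"))

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }

  compartments <- unique(map$species$compartment)
  if (!length(compartments)) compartments <- "default"

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level2\" ",
           "xmlns:celldesigner=\"", CELLDESIGNER_NS, "\" ",
           "level=\"2\" version=\"4\">"),
    paste0("  <model id=\"", esc(sanitize_sbml_id(map$source_name)), "\">"),
    "    <listOfCompartments>",
    paste0("      <compartment id=\"", esc(compartments),
           "\" size=\"1\"/>"),
    "    </listOfCompartments>",
    "    <listOfSpecies>"
  )

  sp <- map$species
  sp_lines <- vapply(seq_len(nrow(sp)), function(i) {
    paste0(
      "      <species id=\"", esc(sp$id[i]), "\" name=\"", esc(sp$name[i]),
      "\" compartment=\"", esc(sp$compartment[i]), "\">\n",
      "        <annotation>\n",
      "          <celldesigner:extension>\n",
      "            <celldesigner:speciesIdentity>\n",
      "              <celldesigner:class>", sp$molecule_class[i],
      "</celldesigner:class>\n",
      "            </celldesigner:speciesIdentity>\n",
      "          </celldesigner:extension>\n",
      "        </annotation>\n",
      "      </species>")
  }, character(1))

  role_block <- function(ids, list_name, ref_name) {
    if (!length(ids)) return(character())
    c(paste0("        <", list_name, ">"),
      paste0("          <", ref_name, " species=\"", esc(ids), "\"/>"),
      paste0("        </", list_name, ">"))
  }

  rx <- map$reactions
  rx_lines <- unlist(lapply(seq_len(nrow(rx)), function(i) {
    c(paste0("      <reaction id=\"", esc(rx$id[i]), "\" reversible=\"",
             tolower(as.character(rx$reversible[i])), "\">"),
      "        <annotation>",
      "          <celldesigner:extension>",
      paste0("            <celldesigner:reactionType>", rx$reaction_type[i],
             "</celldesigner:reactionType>"),
      "          </celldesigner:extension>",
      "        </annotation>",
      role_block(rx$reactants[[i]], "listOfReactants", "speciesReference"),
      role_block(rx$products[[i]], "listOfProducts", "speciesReference"),
      role_block(rx$modifiers[[i]], "listOfModifiers",
                 "modifierSpeciesReference"),
      "      </reaction>")
  }))

  lines <- c(lines, sp_lines, "    </listOfSpecies>",
             "    <listOfReactions>", rx_lines, "    </listOfReactions>",
             "  </model>", "</sbml>")

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

# SBML ids must match SId; squash everything else to underscore.
sanitize_sbml_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  if (!grepl("^[A-Za-z_]", x)) x <- paste0("m_", x)
  x
}
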