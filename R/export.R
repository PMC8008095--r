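#' Export records for a network
#'
#' One row per product structure (seed excluded), carrying both identifier
#' dialects, the systematic Svennerholm, legacy and IUPAC names, the
#' generation at which the structure first appeared, and its
#' classification. Rows are ordered by generation, then identifier.
#'
#' @param network A `ganglio_network`.
#' @return A tibble.
#' @export
export_records <- function(network) {
  stopifnot(inherits(network, "ganglio_network"))
  nodes <- network$nodes[network$nodes$identifier != network$seed, , drop = FALSE]
  if (nrow(nodes) == 0L) {
    out <- glycan_names(character(0))
    out$generation <- integer(0)
    return(out[, export_columns()])
  }
  out <- glycan_names(nodes$identifier)
  out$generation <- nodes$generation
  out <- dplyr::arrange(out, .data$generation, .data$identifier)
  out[, export_columns()]
}

export_columns <- function() {
  c(
    "identifier", "identifier_full", "ssn", "legacy_name", "iupac_name",
    "generation", "sialo_count", "series", "core_number"
  )
}

#' Write a network as CSV
#'
#' RFC-4180 CSV of the [export_records()] table. Output is deterministic
#' (fixed row and column order, no timestamps).
#'
#' @param network A `ganglio_network`.
#' @param path Destination file.
#' @return The number of rows written, invisibly.
#' @export
write_network_csv <- function(network, path) {
  rec <- export_records(network)
  utils::write.csv(rec, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(nrow(rec))
}

# Small-molecule species: the four nucleotide-sugar donors and the two
# nucleotide byproducts, with static ChEBI cross-references.
SMALL_MOLECULES <- tibble::tribble(
  ~code,    ~sbml_id,        ~name,                  ~chebi,
  "UDP-G",  "m_UDP_Glc",     "UDP-alpha-D-glucose",  "CHEBI:46229",
  "UDP-L",  "m_UDP_Gal",     "UDP-alpha-D-galactose","CHEBI:66914",
  "UDP-V",  "m_UDP_GalNAc",  "UDP-N-acetyl-alpha-D-galactosamine", "CHEBI:67138",
  "CMP-S",  "m_CMP_Neu5Ac",  "CMP-N-acetyl-beta-neuraminate", "CHEBI:57812",
  "UDP",    "m_UDP",         "UDP",                  "CHEBI:58223",
  "CMP",    "m_CMP",         "CMP",                  "CHEBI:60377"
)

# Reversible escaping of identifiers into SBML ids: the identifier alphabet
# never contains underscores, so "[" -> "_l" and "]" -> "_r" invert exactly.
sbml_species_id <- function(identifier) {
  paste0("g_", gsub("]", "_r", gsub("[", "_l", identifier, fixed = TRUE), fixed = TRUE))
}

sbml_species_identifier <- function(id) {
  gsub("_r", "]", gsub("_l", "[", sub("^g_", "", id), fixed = TRUE), fixed = TRUE)
}

#' Write a network as SBML Level 3 Version 1
#'
#' Emits an SBML Level 3 Version 1 core document with a single `golgi`
#' compartment; one species per glycan node (seed included) plus the four
#' nucleotide-sugar donors and two nucleotide byproducts (annotated with
#' static ChEBI references); and one irreversible reaction per edge with
#' the donor as co-reactant and the nucleotide as co-product, all
#' stoichiometries 1. Glycan species ids escape brackets reversibly
#' (`[` -> `_l`, `]` -> `_r`), so [read_sbml_network()] reconstructs the
#' edge list exactly.
#'
#' @param network A `ganglio_network`.
#' @param path Destination file.
#' @return The number of species written, invisibly.
#' @export
write_sbml <- function(network, path) {
  stopifnot(inherits(network, "ganglio_network"))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1"
  )
  model <- xml2::xml_add_child(doc, "model", id = "ganglioside_biosynthesis",
                               name = "Ganglioside biosynthesis network")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "golgi", name = "Golgi",
                      spatialDimensions = "3", size = "1", constant = "true")

  species <- xml2::xml_add_child(model, "listOfSpecies")
  add_species <- function(id, name) {
    xml2::xml_add_child(
      species, "species", id = id, name = name, compartment = "golgi",
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false"
    )
  }
  for (i in seq_len(nrow(network$nodes))) {
    id <- network$nodes$identifier[i]
    add_species(sbml_species_id(id), id)
  }
  used <- unique(c(network$edges$donor, network$edges$byproduct))
  sm <- SMALL_MOLECULES[SMALL_MOLECULES$code %in% used | nrow(network$edges) > 0L, , drop = FALSE]
  if (nrow(network$edges) == 0L) sm <- sm[0, ]
  for (i in seq_len(nrow(sm))) {
    node <- add_species(sm$sbml_id[i], sm$name[i])
    ann <- xml2::xml_add_child(node, "annotation")
    xml2::xml_add_child(ann, "chebi", xmlns = "https://identifiers.org/",
                        resource = paste0("https://identifiers.org/", sm$chebi[i]))
  }

  reactions <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    rxn <- xml2::xml_add_child(
      reactions, "reaction",
      id = sprintf("r%03d_e%d", i, e$enzyme),
      name = sprintf("%s -> %s (enzyme %d)", e$substrate, e$product, e$enzyme),
      reversible = "false"
    )
    reactants <- xml2::xml_add_child(rxn, "listOfReactants")
    xml2::xml_add_child(reactants, "speciesReference",
                        species = sbml_species_id(e$substrate),
                        stoichiometry = "1", constant = "true")
    xml2::xml_add_child(reactants, "speciesReference",
                        species = SMALL_MOLECULES$sbml_id[SMALL_MOLECULES$code == e$donor],
                        stoichiometry = "1", constant = "true")
    products <- xml2::xml_add_child(rxn, "listOfProducts")
    xml2::xml_add_child(products, "speciesReference",
                        species = sbml_species_id(e$product),
                        stoichiometry = "1", constant = "true")
    xml2::xml_add_child(products, "speciesReference",
                        species = SMALL_MOLECULES$sbml_id[SMALL_MOLECULES$code == e$byproduct],
                        stoichiometry = "1", constant = "true")
  }
  xml2::write_xml(doc, path)
  invisible(nrow(network$nodes) + nrow(sm))
}

#' Rebuild an edge list from an SBML export
#'
#' Reads a document written by [write_sbml()] and reconstructs the
#' (substrate, enzyme, product) edge list from the glycan species of each
#' reaction, inverting the id escaping.
#'
#' @param path SBML file.
#' @return A tibble `substrate`, `enzyme`, `product`.
#' @export
read_sbml_network <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  rxns <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  rows <- lapply(rxns, function(rxn) {
    id <- xml2::xml_attr(rxn, "id")
    enzyme <- as.integer(sub(".*_e", "", id))
    reactant_ids <- xml2::xml_attr(
      xml2::xml_find_all(rxn, ".//s:listOfReactants/s:speciesReference", ns), "species"
    )
    product_ids <- xml2::xml_attr(
      xml2::xml_find_all(rxn, ".//s:listOfProducts/s:speciesReference", ns), "species"
    )
    tibble(
      substrate = sbml_species_identifier(reactant_ids[startsWith(reactant_ids, "g_")]),
      enzyme = enzyme,
      product = sbml_species_identifier(product_ids[startsWith(product_ids, "g_")])
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$enzyme, .data$substrate, .data$product)
}

# Edge colors by transferred sugar, matching the four transferase classes.
DONOR_COLOR <- c(
  "UDP-G" = "blue",     # glucosyltransferase
  "UDP-L" = "gold",     # galactosyltransferases
  "UDP-V" = "brown",    # N-acetylgalactosaminyltransferase
  "CMP-S" = "magenta"   # sialyltransferases
)

#' Write a network as a Graphviz DOT digraph
#'
#' Nodes are labelled with the SSN where one exists (identifier otherwise);
#' edges are colored by the class of transferred sugar (glucosyl, galactosyl,
#' N-acetylgalactosaminyl, sialyl) and labelled with the enzyme number.
#'
#' @param network A `ganglio_network`.
#' @param path Destination file.
#' @return The number of edges written, invisibly.
#' @export
write_dot <- function(network, path) {
  stopifnot(inherits(network, "ganglio_network"))
  names_tbl <- glycan_names(network$nodes$identifier)
  label <- ifelse(is.na(names_tbl$ssn), names_tbl$identifier, names_tbl$ssn)
  lines <- c(
    "digraph ganglioside_network {",
    "  rankdir=LR;",
    "  node [shape=box, fontsize=10];",
    sprintf('  "%s" [label="%s"];', network$nodes$identifier, label)
  )
  if (nrow(network$edges) > 0L) {
    lines <- c(lines, sprintf(
      '  "%s" -> "%s" [color=%s, label="%d"];',
      network$edges$substrate, network$edges$product,
      DONOR_COLOR[network$edges$donor], network$edges$enzyme
    ))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(nrow(network$edges))
}

#' Write a network as a plain edge list
#'
#' Tab-separated `substrate`, `enzyme`, `ec`, `product`, one reaction per
#' line, with a header.
#'
#' @param network A `ganglio_network`.
#' @param path Destination file.
#' @param ruleset Rule set supplying EC numbers (default
#'   [default_ruleset()]).
#' @return The number of edges written, invisibly.
#' @export
write_edgelist <- function(network, path, ruleset = default_ruleset()) {
  stopifnot(inherits(network, "ganglio_network"))
  ec <- stats::setNames(ruleset$ec, ruleset$enzyme)
  df <- tibble(
    substrate = network$edges$substrate,
    enzyme = network$edges$enzyme,
    ec = unname(ec[as.character(network$edges$enzyme)]),
    product = network$edges$product
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(nrow(df))
}
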