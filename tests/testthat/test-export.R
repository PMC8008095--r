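test_that("CSV export has one deterministic row per product structure", {
  net <- expand_network()
  path <- withr::local_tempfile(fileext = ".csv")
  expect_equal(write_network_csv(net, path), 41L)
  df <- utils::read.csv(path, check.names = FALSE, encoding = "UTF-8")
  expect_equal(nrow(df), 41L)
  expect_equal(
    names(df),
    c("identifier", "identifier_full", "ssn", "legacy_name", "iupac_name",
      "generation", "sialo_count", "series", "core_number")
  )
  # only GlcCer lacks a name
  expect_equal(df$identifier[!nzchar(df$ssn)], "GT")
  # deterministic: rewriting yields byte-identical output
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, path2)
  expect_identical(readLines(path, encoding = "UTF-8"), readLines(path2, encoding = "UTF-8"))

  empty <- expand_network(knockouts = 1:10)
  expect_equal(write_network_csv(empty, withr::local_tempfile()), 0L)
  ko1 <- expand_network(knockouts = 1L)
  expect_equal(write_network_csv(ko1, withr::local_tempfile()), 4L)
})

test_that("SBML export is valid L3V1 structure and round-trips the graph", {
  net <- expand_network()
  path <- withr::local_tempfile(fileext = ".xml")
  n_species <- write_sbml(net, path)
  expect_equal(n_species, 42L + 6L)

  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_ns(doc)[["d1"]], "http://www.sbml.org/sbml/level3/version1/core")
  expect_equal(xml2::xml_attr(doc, "level"), "3")
  expect_equal(xml2::xml_attr(doc, "version"), "1")
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  species <- xml2::xml_find_all(doc, ".//s:species", ns)
  expect_length(species, 48L)
  expect_true(all(nzchar(xml2::xml_attr(species, "compartment"))))
  rxns <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  expect_length(rxns, 49L)
  expect_true(all(xml2::xml_attr(rxns, "reversible") == "false"))
  refs <- xml2::xml_find_all(doc, ".//s:speciesReference", ns)
  expect_true(all(xml2::xml_attr(refs, "stoichiometry") == "1"))
  # every reaction has a donor co-reactant and a nucleotide co-product
  for (r in rxns[1:5]) {
    expect_length(xml2::xml_find_all(r, ".//s:listOfReactants/s:speciesReference", ns), 2L)
    expect_length(xml2::xml_find_all(r, ".//s:listOfProducts/s:speciesReference", ns), 2L)
  }

  rebuilt <- read_sbml_network(path)
  orig <- dplyr::arrange(
    net$edges[, c("substrate", "enzyme", "product")],
    substrate, enzyme, product
  )
  rebuilt <- dplyr::arrange(rebuilt, substrate, enzyme, product)
  expect_equal(rebuilt, orig)
})

test_that("species id escaping of brackets is reversible", {
  for (id in ganglioside_identifiers()) {
    sid <- gangliosim:::sbml_species_id(id)
    expect_match(sid, "^g_[A-Za-z0-9_]+$")
    expect_equal(gangliosim:::sbml_species_identifier(sid), id)
  }
})

test_that("DOT export colors the four transferase classes", {
  net <- expand_network()
  path <- withr::local_tempfile(fileext = ".dot")
  expect_equal(write_dot(net, path), 49L)
  lines <- readLines(path, encoding = "UTF-8")
  edge_lines <- grep("->", lines, value = TRUE)
  expect_length(edge_lines, 49L)
  expect_equal(sum(grepl("color=blue", edge_lines)), 1L) # only one glucosyl transfer
  cols <- unique(sub(".*color=([a-z]+).*", "\\1", edge_lines))
  expect_setequal(cols, c("blue", "gold", "brown", "magenta"))
  # knockout of the alpha-decorating enzyme leaves no edge into alpha structures
  ko10 <- expand_network(knockouts = 10L)
  expect_false(any(grepl("[S6]", ko10$edges$product, fixed = TRUE)))
})

test_that("edge list export carries EC numbers and counts match", {
  net <- expand_network()
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_equal(write_edgelist(net, path), 49L)
  df <- utils::read.delim(path)
  expect_equal(nrow(df), 49L)
  expect_equal(unique(df$ec[df$enzyme == 1]), "EC 2.4.1.80")
})

test_that("export counts agree with the underlying network object", {
  net <- expand_network(knockouts = 7L)
  csv_n <- write_network_csv(net, withr::local_tempfile())
  sbml_path <- withr::local_tempfile()
  write_sbml(net, sbml_path)
  dot_n <- write_dot(net, withr::local_tempfile())
  expect_equal(csv_n, nrow(net$nodes) - 1L)
  expect_equal(nrow(read_sbml_network(sbml_path)), nrow(net$edges))
  expect_equal(dot_n, nrow(net$edges))
})

test_that("network plots build without error", {
  net <- expand_network(knockouts = c(5, 6, 9, 10))
  p <- ggplot2::autoplot(net)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
  scan <- knockout_scan(seed = "L4GT", max_iterations = 5)
  expect_s3_class(plot_knockout_summary(scan), "ggplot")
})
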