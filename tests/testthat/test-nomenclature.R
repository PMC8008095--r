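test_that("systematic Svennerholm names match the classical assignments", {
  for (id in names(KNOWN_SSN)) {
    expect_equal(systematic_svennerholm(id), unname(KNOWN_SSN[id]), info = id)
  }
  # no SSN for ceramide and GlcCer
  expect_true(is.na(systematic_svennerholm("T")))
  expect_true(is.na(systematic_svennerholm("GT")))
  # unclassifiable structures error with the offending feature
  expect_error(systematic_svennerholm("S3L4GT"), "chain residue")
})

test_that("the sialo letter always agrees with the sialic acid count", {
  letters <- c("A", "M", "D", "T", "Q", "P", "H", "S")
  for (id in setdiff(ganglioside_identifiers(include_seed = FALSE), "GT")) {
    ssn <- systematic_svennerholm(id)
    expect_equal(substr(ssn, 2, 2), letters[count_residues(id, "S") + 1L], info = id)
  }
})

test_that("SSN and structure are a bijection over the nameable network nodes", {
  ids <- ganglioside_identifiers(include_seed = FALSE)
  nameable <- setdiff(ids, "GT")
  ssns <- vapply(nameable, systematic_svennerholm, character(1))
  expect_equal(anyDuplicated(ssns), 0L)
  for (i in seq_along(nameable)) {
    expect_equal(as.character(parse_ssn(ssns[i])), nameable[i], info = ssns[i])
  }
})

test_that("alpha-named structures always carry the [S6] branch and a terminal chain", {
  ids <- setdiff(ganglioside_identifiers(include_seed = FALSE), "GT")
  for (id in ids) {
    ssn <- systematic_svennerholm(id)
    if (grepl("α", ssn)) {
      ci <- core_info(id)
      expect_equal(ci$sial_III, 1L, info = id)
      expect_gte(ci$sial_IV, 1L)
      expect_true(grepl("[S6]", id, fixed = TRUE))
    }
  }
  # in particular there is no GT1b-alpha (an [S6] without a terminal chain):
  # rule 10 needs the terminal S3 already in place, so it cannot act on GD1b
  rs <- default_ruleset()
  expect_equal(nrow(apply_rule(rs[10, ], "L3Vb4[S8S3]L4GT")), 0L)
  net <- expand_network()
  expect_false("L3[S6]Vb4[S8S3]L4GT" %in% net$nodes$identifier)
})

test_that("the network partitions into the five series as published", {
  net <- expand_network()
  tbl <- glycan_names(setdiff(net$nodes$identifier, "T"))
  expect_setequal(tbl$ssn[tbl$series %in% "Gala"], c("GA4", "GM4", "GD4", "GT4"))
  counts <- table(tbl$series[tbl$series %in% c("0", "a", "b", "c")])
  expect_equal(unname(counts[c("0", "a", "b", "c")]), rep(7L, 4), ignore_attr = TRUE)
  expect_equal(sum(tbl$series %in% ""), 9L) # GlcCer through GT3, GA2 through GT2
})

test_that("IUPAC ganglioside names render plain and marked-up", {
  expect_equal(iupac_ganglioside_name(GP1CA_ID), "IV3Neu5Ac,III6Neu5Ac,II3(Neu5Ac)3-Gg4Cer")
  expect_equal(
    iupac_ganglioside_name(GP1CA_ID, markup = TRUE),
    "IV^3^Neu5Ac,III^6^Neu5Ac,II^3^(Neu5Ac)_3_-Gg_4_Cer"
  )
  expect_equal(iupac_ganglioside_name(GM1A_ID), "II3Neu5Ac-Gg4Cer")
  expect_equal(iupac_ganglioside_name(GM1A_ID, markup = TRUE), "II^3^Neu5Ac-Gg_4_Cer")
  expect_equal(iupac_ganglioside_name("S3L3[S6]Vb4L4GT"), "IV3Neu5Ac,III6Neu5Ac-Gg4Cer")
  expect_equal(iupac_ganglioside_name("S8S3L3Vb4L4GT"), "IV3(Neu5Ac)2-Gg4Cer")
  expect_equal(iupac_ganglioside_name("[S3]LT"), "I3Neu5Ac-GalCer")
  expect_equal(iupac_ganglioside_name("L3Vb4L4GT"), "Gg4Cer")
  expect_equal(iupac_ganglioside_name("GT"), "GlcCer")
  expect_equal(iupac_ganglioside_name("T"), "Cer")
})

test_that("legacy name mapping applies exactly the four classical rows", {
  expect_equal(legacy_mapping("GM1b", "to_ssn"), "GM1")
  expect_equal(legacy_mapping("GD1c", "to_ssn"), "GD1")
  expect_equal(legacy_mapping("GD1aα", "to_ssn"), "GD1α")
  expect_warning(both <- legacy_mapping("GM1", "to_ssn"), "ambiguous")
  expect_equal(both, c("GM1a", "GM1"))

  expect_equal(legacy_mapping("GM1", "to_legacy"), "GM1b")
  expect_equal(legacy_mapping("GM1a", "to_legacy"), "GM1")
  expect_equal(legacy_mapping("GD1", "to_legacy"), "GD1c")
  expect_equal(legacy_mapping("GD1α", "to_legacy"), "GD1aα")
  # identity outside the table, both directions
  expect_equal(legacy_mapping("GT1b", "to_ssn"), "GT1b")
  expect_equal(legacy_mapping("GT1b", "to_legacy"), "GT1b")
  expect_error(legacy_mapping("frobnicate"), "Unparseable")
})

test_that("inconsistent SSNs are rejected by the parser", {
  expect_error(parse_ssn("GM1b"), "series")
  expect_error(parse_ssn("GA1c"), "series")
  expect_error(parse_ssn("GM2a"), "series letter requires")
  expect_error(parse_ssn("GM2α"), "requires the fully extended core")
  expect_error(parse_ssn("GD1aα"), "terminal sialic acid")
  expect_error(parse_ssn("GQ4"), "cannot sit on GalCer")
  expect_error(parse_ssn("GX1"), "well-formed")
  # alpha may be spelled out
  expect_equal(as.character(parse_ssn("GD1alpha")), as.character(parse_ssn("GD1α")))
})
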