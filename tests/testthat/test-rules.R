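test_that("the default rule set has the documented composition", {
  rs <- default_ruleset()
  expect_equal(nrow(rs), 10L)
  expect_equal(rs$enzyme, 1:10)
  expect_equal(rs$byproduct[c(1, 2, 3, 7, 8)], rep("UDP", 5))
  expect_equal(rs$byproduct[c(4, 5, 6, 9, 10)], rep("CMP", 5))
  expect_equal(rs$category[c(1, 2, 3, 5, 7, 8)], rep("extension", 6))
  expect_equal(rs$category[4], "decoration-with-extension")
  expect_equal(rs$category[10], "decoration")
  expect_equal(rs$category[9], "termination-with-extension")
  expect_equal(rs$category[6], "termination")
  # declared categories are consistent with the rewrite shapes
  for (i in 1:10) expect_equal(classify_activity(rs[i, ]), rs$category[i])
})

test_that("pattern matching honors anchoring and bracket alignment", {
  # prefix anchoring: activity 5 cannot act after GalNAc extension
  expect_equal(nrow(match_pattern("P", "[S3]L4*T", "Vb4[S3]L4GT")), 0L)
  expect_equal(nrow(match_pattern("P", "[S3]L4*T", "[S3]L4GT")), 1L)
  # literal bracket alignment blocks the inner occurrence
  expect_equal(nrow(match_pattern("I", "[S8S3]", "[S8S8S3]L4GT")), 0L)
  expect_equal(nrow(match_pattern("I", "[S8S3]", "[S8S3]L4GT")), 1L)
  # wildcard prefix match through the terminal T
  expect_equal(nrow(match_pattern("P", "S3*T", "S3L3[S6]Vb4L4GT")), 1L)
  expect_equal(nrow(match_pattern("P", "S3*T", "S8S3L3Vb4L4GT")), 0L)
  # malformed patterns are rejected
  expect_error(match_pattern("P", "[S3*]T", "GT"), "Wildcard inside brackets")
  expect_error(match_pattern("P", "[S3T", "GT"), "Unbalanced")
  expect_error(match_pattern("X", "T", "GT"), "anchor")
})

test_that("rule application produces the classical single steps", {
  rs <- default_ruleset()
  expect_equal(apply_rule(rs[4, ], "L4GT")$product, "[S3]L4GT")
  expect_equal(apply_rule(rs[4, ], "LT")$product, "[S3]LT")
  expect_equal(apply_rule(rs[7, ], "L4GT")$product, "Vb4L4GT")
  expect_equal(apply_rule(rs[10, ], "S3L3Vb4L4GT")$product, "S3L3[S6]Vb4L4GT")
  expect_equal(nrow(apply_rule(rs[5, ], "T")), 0L)
  # GT1b is elongated two ways by activity 6: terminal chain or inner branch
  prods <- apply_rule(rs[6, ], "S3L3Vb4[S8S3]L4GT")$product
  expect_setequal(prods, c("S8S3L3Vb4[S8S3]L4GT", "S3L3Vb4[S8S8S3]L4GT"))
})

test_that("a ruleset step pools events over active enzymes and knockouts apply", {
  rs <- default_ruleset()
  step <- apply_ruleset_step(rs, "T")
  expect_setequal(step$product, c("GT", "LT"))
  expect_equal(apply_ruleset_step(rs, "T", knockouts = 1L)$product, "LT")
  expect_equal(nrow(apply_ruleset_step(rs, "GT", knockouts = 3L)), 0L)
  expect_error(apply_ruleset_step(rs, "T", knockouts = 42L), "Invalid knockout")
})

test_that("every reaction event transfers exactly the donor sugar", {
  rs <- default_ruleset()
  sugar <- c("UDP-G" = "G", "UDP-L" = "L", "UDP-V" = "V", "CMP-S" = "S")
  for (id in ganglioside_identifiers()) {
    ev <- apply_ruleset_step(rs, id)
    for (k in seq_len(nrow(ev))) {
      s_sub <- parse_identifier(ev$substrate[k])
      s_prod <- parse_identifier(ev$product[k])
      expect_equal(gangliosim:::n_residues(s_prod), gangliosim:::n_residues(s_sub) + 1L)
      added <- sugar[[ev$donor[k]]]
      expect_equal(count_residues(s_prod, added), count_residues(s_sub, added) + 1L)
    }
  }
})

test_that("rule 5 never fires on GalNAc-extended structures", {
  rs <- default_ruleset()
  ids <- ganglioside_identifiers()
  with_galnac <- ids[grepl("Vb4", ids, fixed = TRUE)]
  for (id in with_galnac) {
    expect_equal(nrow(apply_rule(rs[5, ], id)), 0L)
  }
})

test_that("rule sets round-trip through the plain-text config format", {
  rs <- default_ruleset()
  path <- withr::local_tempfile(fileext = ".txt")
  write_ruleset(rs, path)
  rs2 <- read_ruleset(path)
  expect_equal(as.data.frame(rs2), as.data.frame(rs))
  # a malformed record is rejected
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 | EC | name | UDP-G | UDP | extension", bad)
  expect_error(read_ruleset(bad), "Malformed")
})
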