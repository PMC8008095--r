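test_that("small expansions behave predictably", {
  one <- expand_network(max_iterations = 1)
  expect_setequal(setdiff(one$nodes$identifier, "T"), c("GT", "LT"))
  expect_equal(nrow(one$edges), 2L)
  expect_true(one$truncated)

  asialo <- expand_network(seed = "L4GT", knockouts = c(4, 5, 6, 9, 10))
  expect_setequal(setdiff(asialo$nodes$identifier, "L4GT"), c("Vb4L4GT", "L3Vb4L4GT"))
  expect_equal(nrow(asialo$edges), 2L)
  expect_false(asialo$truncated)

  none <- expand_network(knockouts = 1:10)
  expect_equal(none$nodes$identifier, "T")
  expect_equal(nrow(none$edges), 0L)
  expect_equal(none$iterations_run, 0L)
})

test_that("the wild-type expansion matches the closed-form enumeration exactly", {
  net <- expand_network()
  ref <- reference_enumeration()
  expect_equal(net$nodes, ref$nodes)
  expect_equal(
    net$edges[, c("substrate", "enzyme", "product")],
    ref$edges[, c("substrate", "enzyme", "product")]
  )
  expect_equal(net$iterations_run, ref$iterations_run)
  # closed-form bookkeeping: the fully extended core family has 28 members
  full_core <- grepl("L3(\\[S6\\])?Vb4", net$nodes$identifier)
  expect_equal(sum(full_core), 28L)
})

test_that("expansion is confluent: rule order does not matter", {
  net <- expand_network()
  set.seed(17)
  for (rep in 1:3) {
    perm <- default_ruleset()[sample(10), ]
    net2 <- expand_network(ruleset = perm)
    expect_equal(net2$nodes, net$nodes)
    expect_equal(net2$edges, net$edges)
  }
})

test_that("network diff isolates what a knockout removes", {
  wt <- expand_network()
  expect_length(network_diff(wt, wt)$nodes_lost, 0L)
  expect_length(network_diff(wt, wt)$nodes_gained, 0L)

  ko4 <- expand_network(knockouts = 4L)
  d <- network_diff(wt, ko4)
  expect_length(d$nodes_gained, 0L)
  # every surviving sialylated structure is 0-series (terminal/alpha only)
  survivors <- glycan_names(setdiff(ko4$nodes$identifier, "T"))
  sial <- survivors[survivors$sialo_count > 0, ]
  expect_true(all(sial$series %in% "0"))

  ko6 <- expand_network(knockouts = 6L)
  d6 <- network_diff(wt, ko6)
  all_names <- glycan_names(setdiff(wt$nodes$identifier, "T"))
  c_series <- all_names$identifier[all_names$series %in% "c"]
  expect_true(all(c_series %in% d6$nodes_lost))
  ko6_names <- glycan_names(setdiff(ko6$nodes$identifier, "T"))
  expect_false(any(ko6_names$series %in% "c"))
})

test_that("downstream reachability matches the known arms", {
  net <- expand_network()
  expect_setequal(downstream_products(net, "LT"), c("[S3]LT", "[S8S3]LT", "[S8S8S3]LT"))
  expect_length(downstream_products(net, "GT"), 36L)
  leaf <- "S8S8S3L3[S6]Vb4[S8S8S3]L4GT" # GS1c-alpha
  expect_length(downstream_products(net, leaf), 0L)
  expect_error(downstream_products(net, "S3L4GT"), "not in the network")
})

test_that("knockout monotonicity: more knockouts never add structures or reactions", {
  wt <- expand_network()
  scan <- knockout_scan()
  for (e in as.character(1:10)) {
    ko <- scan[[e]]
    expect_true(all(ko$nodes$identifier %in% wt$nodes$identifier))
    ko_edges <- do.call(paste, ko$edges[, c("substrate", "enzyme", "product")])
    wt_edges <- do.call(paste, wt$edges[, c("substrate", "enzyme", "product")])
    expect_true(all(ko_edges %in% wt_edges))
    # and a deeper knockout set is contained in the shallower one
    ko2 <- expand_network(knockouts = c(as.integer(e), 9L))
    expect_true(all(ko2$nodes$identifier %in% ko$nodes$identifier))
  }
})

test_that("enzyme inference recovers the biosynthetic path and enzyme set", {
  res <- infer_required_enzymes(GM1A_ID)
  expect_true(res$reachable)
  expect_equal(res$enzymes, c(1L, 3L, 4L, 7L, 8L))
  expect_equal(res$path$product[nrow(res$path)], GM1A_ID)
  expect_equal(res$path$substrate[1], "T")

  expect_equal(infer_required_enzymes("GT")$enzymes, 1L)

  un <- infer_required_enzymes("S3L4GT")
  expect_false(un$reachable)
  expect_equal(un$blocked, "S3L4GT")
})

test_that("for every network structure, the inferred enzyme subset regenerates it", {
  net <- expand_network()
  for (id in setdiff(net$nodes$identifier, "T")) {
    res <- infer_required_enzymes(id)
    expect_true(res$reachable, info = id)
    sub_net <- expand_network(knockouts = setdiff(1:10, res$enzymes))
    expect_true(id %in% sub_net$nodes$identifier, info = id)
  }
})

test_that("no product ever carries a sialyl chain longer than three", {
  net <- expand_network()
  expect_false(any(grepl("S8S8S8", net$nodes$identifier, fixed = TRUE)))
  expect_false(any(grepl("S8S8S8", net$edges$product, fixed = TRUE)))
})

test_that("tidy and glance summarize a network", {
  net <- expand_network()
  g <- glance(net)
  expect_equal(g$n_structures, 41L)
  expect_equal(g$n_reactions, 49L)
  expect_equal(g$iterations_run, 11L)
  td <- tidy(net)
  expect_equal(nrow(td), 42L)
  expect_equal(sum(td$is_seed), 1L)
  expect_true(all(c("ssn", "iupac_name", "generation") %in% names(td)))
})
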