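#' Expand a reaction network from a seed structure
#'
#' Breadth-first, generation-synchronous expansion: at each iteration every
#' active enzyme is applied to every structure first produced at the
#' previous iteration; all discovered reactions are kept (including those
#' into already-known products), and the novel products form the next
#' frontier. Expansion stops when an iteration yields no novel structure,
#' or at `max_iterations` (in which case the returned network is flagged
#' `truncated`). From bare ceramide with the default rule set the expansion
#' reaches its fixed point after 11 productive iterations, with 41 product
#' structures and 49 reactions.
#'
#' @param seed Seed structure (identifier string or `glycan_structure`);
#'   default bare ceramide `"T"`.
#' @param ruleset Rule-set tibble; default [default_ruleset()].
#' @param knockouts Integer vector of enzyme numbers to disable.
#' @param max_iterations Positive integer cap on iterations (default 20).
#' @return A `ganglio_network`: list with `nodes` (tibble `identifier`,
#'   `generation`; the seed has generation 0), `edges` (tibble `substrate`,
#'   `enzyme`, `product`, `donor`, `byproduct`), `iterations_run` (number
#'   of iterations that produced at least one novel structure),
#'   `truncated`, `seed`, `knockouts`.
#' @examples
#' net <- expand_network()
#' glance(net)
#' @export
expand_network <- function(seed = "T", ruleset = default_ruleset(),
                           knockouts = integer(0), max_iterations = 20L) {
  if (!is.numeric(max_iterations) || max_iterations < 1L) {
    abort("`max_iterations` must be a positive integer.")
  }
  knockouts <- check_knockouts(knockouts, ruleset)
  seed_id <- canonical_identifier(
    if (inherits(seed, "glycan_structure")) serialize_identifier(seed) else seed
  )
  active <- compile_ruleset(ruleset[!ruleset$enzyme %in% knockouts, , drop = FALSE])
  canon_cache <- new.env(parent = emptyenv())
  canon <- function(x) {
    hit <- canon_cache[[x]]
    if (is.null(hit)) {
      hit <- canonical_identifier(x)
      canon_cache[[x]] <- hit
    }
    hit
  }
  generation <- stats::setNames(0L, seed_id)
  frontier <- seed_id
  e_sub <- e_enz <- e_prod <- list()
  iterations_run <- 0L
  it <- 0L
  while (length(frontier) > 0L && it < max_iterations) {
    it <- it + 1L
    novel <- character(0)
    for (x in frontier) {
      for (cr in active) {
        prods <- compiled_rule_products(cr, x)
        if (length(prods) == 0L) next
        prods <- unique(vapply(prods, canon, character(1), USE.NAMES = FALSE))
        e_sub[[length(e_sub) + 1L]] <- rep(x, length(prods))
        e_enz[[length(e_enz) + 1L]] <- rep(cr$enzyme, length(prods))
        e_prod[[length(e_prod) + 1L]] <- prods
        novel <- c(novel, setdiff(prods, names(generation)))
      }
    }
    novel <- unique(novel)
    if (length(novel) > 0L) {
      iterations_run <- iterations_run + 1L
      generation[novel] <- it
    }
    frontier <- novel
  }
  truncated <- length(frontier) > 0L

  donors <- stats::setNames(ruleset$donor, ruleset$enzyme)
  byproducts <- stats::setNames(ruleset$byproduct, ruleset$enzyme)
  enz <- unlist(e_enz) %||% integer(0)
  edges <- tibble(
    substrate = as.character(unlist(e_sub)),
    enzyme = as.integer(enz),
    product = as.character(unlist(e_prod)),
    donor = as.character(donors[as.character(enz)]),
    byproduct = as.character(byproducts[as.character(enz)])
  )
  edges <- dplyr::distinct(
    edges,
    .data$substrate, .data$enzyme, .data$product, .data$donor, .data$byproduct
  )
  nodes <- tibble(identifier = names(generation), generation = unname(generation))
  nodes <- dplyr::arrange(nodes, .data$generation, .data$identifier)
  edges <- dplyr::arrange(edges, .data$enzyme, .data$substrate, .data$product)
  new_ganglio_network(nodes, edges, iterations_run, truncated, seed_id, knockouts)
}

new_ganglio_network <- function(nodes, edges, iterations_run, truncated, seed, knockouts) {
  structure(
    list(
      nodes = nodes, edges = edges, iterations_run = iterations_run,
      truncated = truncated, seed = seed, knockouts = knockouts
    ),
    class = "ganglio_network"
  )
}

#' @export
format.ganglio_network <- function(x, ...) {
  ko <- if (length(x$knockouts)) paste0("; knockouts {", paste(x$knockouts, collapse = ","), "}") else ""
  sprintf(
    "<ganglio_network> seed %s: %d product structures, %d reactions, %d productive iterations%s%s",
    x$seed, nrow(x$nodes) - sum(x$nodes$identifier == x$seed), nrow(x$edges),
    x$iterations_run, if (x$truncated) " (truncated)" else "", ko
  )
}

#' @export
print.ganglio_network <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Scan single-enzyme knockouts
#'
#' Regenerates the network once per enzyme in the rule set with that
#' enzyme disabled (on top of any baseline knockouts), plus the reference
#' wild-type network.
#'
#' @inheritParams expand_network
#' @return A named list of `ganglio_network`s: `"wild_type"` and one entry
#'   per enzyme number (`"1"` ... `"10"` for the default set).
#' @export
knockout_scan <- function(seed = "T", ruleset = default_ruleset(),
                          knockouts = integer(0), max_iterations = 20L) {
  out <- list(
    wild_type = expand_network(seed, ruleset, knockouts, max_iterations)
  )
  for (e in ruleset$enzyme) {
    out[[as.character(e)]] <-
      expand_network(seed, ruleset, union(knockouts, e), max_iterations)
  }
  out
}

#' Summarize a knockout scan
#'
#' @param scan A list returned by [knockout_scan()].
#' @return A tibble with one row per network: `condition`, `n_structures`
#'   (seed excluded), `n_reactions`, `iterations_run`.
#' @export
knockout_summary <- function(scan) {
  dplyr::bind_rows(lapply(names(scan), function(nm) {
    g <- glance(scan[[nm]])
    dplyr::bind_cols(tibble(condition = nm), g)
  }))
}

#' Difference between two networks
#'
#' @param a,b `ganglio_network`s over the same identifier space.
#' @return A list with `nodes_lost`, `nodes_gained` (character vectors of
#'   identifiers in `a` but not `b`, and vice versa) and `edges_lost`,
#'   `edges_gained` (tibbles of (substrate, enzyme, product) triples).
#' @export
network_diff <- function(a, b) {
  stopifnot(inherits(a, "ganglio_network"), inherits(b, "ganglio_network"))
  ea <- a$edges[, c("substrate", "enzyme", "product")]
  eb <- b$edges[, c("substrate", "enzyme", "product")]
  list(
    nodes_lost = setdiff(a$nodes$identifier, b$nodes$identifier),
    nodes_gained = setdiff(b$nodes$identifier, a$nodes$identifier),
    edges_lost = dplyr::anti_join(ea, eb, by = c("substrate", "enzyme", "product")),
    edges_gained = dplyr::anti_join(eb, ea, by = c("substrate", "enzyme", "product"))
  )
}

#' Structures reachable downstream of a node
#'
#' @param network A `ganglio_network`.
#' @param node Identifier (or `glycan_structure`) of a node in the network.
#' @return Character vector of identifiers reachable from `node` by
#'   directed reactions, excluding `node` itself.
#' @export
downstream_products <- function(network, node) {
  stopifnot(inherits(network, "ganglio_network"))
  id <- canonical_identifier(
    if (inherits(node, "glycan_structure")) serialize_identifier(node) else node
  )
  if (!id %in% network$nodes$identifier) {
    abort(sprintf("Node '%s' is not in the network.", id))
  }
  seen <- id
  frontier <- id
  while (length(frontier) > 0L) {
    nxt <- unique(network$edges$product[network$edges$substrate %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(setdiff(seen, id))
}

#' Infer the enzymes required to synthesize a target glycan
#'
#' Backward decomposition: reaction rewrites are inverted and applied
#' repeatedly to strip the last-added residue until bare ceramide is
#' reached, exploring all removable residues when several inverses apply.
#' Returns the set of enzyme activities used and one witness biosynthetic
#' path from `T` (ties broken toward the lexicographically smallest
#' substrate/enzyme at each step). Re-simulating with exactly the returned
#' enzyme subset regenerates the target.
#'
#' @param target Target structure (identifier string or `glycan_structure`).
#' @param ruleset Rule-set tibble.
#' @return A list with `reachable` (logical), `enzymes` (sorted integer
#'   vector), `path` (tibble `step`, `substrate`, `enzyme`, `product`) and,
#'   when unreachable, `blocked`: the first intermediate with no producing
#'   reaction.
#' @examples
#' infer_required_enzymes("L3Vb4[S3]L4GT")$enzymes # GM1a: 1, 3, 4, 7, 8
#' @export
infer_required_enzymes <- function(target, ruleset = default_ruleset()) {
  id <- canonical_identifier(
    if (inherits(target, "glycan_structure")) serialize_identifier(target) else target
  )
  if (id == "T") {
    return(list(
      reachable = TRUE, enzymes = integer(0),
      path = tibble(step = integer(0), substrate = character(0),
                    enzyme = integer(0), product = character(0))
    ))
  }
  # Backward closure from the target.
  preds <- list() # product -> tibble(substrate, enzyme)
  frontier <- id
  seen <- id
  blocked <- NULL
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (x in frontier) {
      p <- invert_rules(x, ruleset)
      preds[[x]] <- p
      if (nrow(p) == 0L && x != "T" && is.null(blocked)) blocked <- x
      nxt <- c(nxt, setdiff(p$substrate, seen))
    }
    frontier <- unique(nxt)
    seen <- c(seen, frontier)
  }
  if (!"T" %in% seen) {
    return(list(
      reachable = FALSE, enzymes = integer(0), path = NULL,
      blocked = blocked %||% id
    ))
  }
  # Forward reconstruction over the inverted-edge graph, breadth-first from
  # T, preferring lexicographically smaller (substrate, enzyme) parents.
  fwd <- dplyr::bind_rows(lapply(names(preds), function(prod) {
    p <- preds[[prod]]
    if (nrow(p) == 0L) return(NULL)
    tibble(substrate = p$substrate, enzyme = p$enzyme, product = prod)
  }))
  fwd <- dplyr::arrange(fwd, .data$substrate, .data$enzyme)
  parent <- list()
  level <- "T"
  visited <- "T"
  while (length(level) > 0L && !id %in% visited) {
    nxt <- character(0)
    for (s in sort(level)) {
      out_edges <- fwd[fwd$substrate == s, , drop = FALSE]
      for (k in seq_len(nrow(out_edges))) {
        prod <- out_edges$product[k]
        if (!prod %in% visited) {
          parent[[prod]] <- list(substrate = s, enzyme = out_edges$enzyme[k])
          visited <- c(visited, prod)
          nxt <- c(nxt, prod)
        }
      }
    }
    level <- nxt
  }
  path <- list()
  cur <- id
  while (cur != "T") {
    pa <- parent[[cur]]
    path <- c(list(tibble(substrate = pa$substrate, enzyme = pa$enzyme, product = cur)), path)
    cur <- pa$substrate
  }
  path <- dplyr::bind_rows(path)
  path$step <- seq_len(nrow(path))
  path <- path[, c("step", "substrate", "enzyme", "product")]
  list(reachable = TRUE, enzymes = sort(unique(path$enzyme)), path = path)
}

# All (substrate, enzyme) pairs whose forward application yields `x`:
# each rule's rewrite is inverted (replacement matched, pattern restored)
# and the candidate substrate verified by forward application.
invert_rules <- function(x, ruleset) {
  out <- list()
  for (i in seq_len(nrow(ruleset))) {
    rule <- ruleset[i, ]
    pats <- rule$patterns[[1L]]
    for (j in seq_len(nrow(pats))) {
      cand <- character(0)
      if (pats$anchor[j] == "P") {
        rx <- pattern_regex(pats$replacement[j])
        if (grepl(rx, x)) {
          cand <- if (grepl("*", pats$replacement[j], fixed = TRUE)) {
            sub("*", sub(rx, "\\1", x), pats$pattern[j], fixed = TRUE)
          } else {
            pats$pattern[j]
          }
        }
      } else {
        hits <- gregexpr(pats$replacement[j], x, fixed = TRUE)[[1L]]
        if (hits[1L] != -1L) {
          cand <- vapply(seq_along(hits), function(k) {
            paste0(
              substr(x, 1L, hits[k] - 1L), pats$pattern[j],
              substr(x, hits[k] + attr(hits, "match.length")[k], nchar(x))
            )
          }, character(1))
        }
      }
      for (s in cand) {
        s_can <- tryCatch(canonical_identifier(s), error = function(e) NA_character_)
        if (is.na(s_can)) next
        fwd <- apply_rule(rule, s_can)
        if (x %in% fwd$product) {
          out <- c(out, list(tibble(substrate = s_can, enzyme = rule$enzyme)))
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(substrate = character(0), enzyme = integer(0)))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Closed-form enumeration of the wild-type network
#'
#' Constructs the expected wild-type ganglioside network without the
#' rewriting engine, from the explicit parameterization of the grammar:
#' the Gala arm, the glucosylceramide arm with its sialylated and
#' GalNAc-extended intermediates, and the fully extended core family
#' indexed by (position II branch, position IV chain, position III alpha),
#' with edges written out per enzyme family. Generations are assigned by
#' breadth-first traversal of the enumerated edges. Serves as an
#' independent oracle for [expand_network()].
#'
#' @return A `ganglio_network` with 41 product structures and 49 reactions.
#' @export
reference_enumeration <- function() {
  chains <- c("", "S3", "S8S3", "S8S8S3")
  brs <- c("", "[S3]", "[S8S3]", "[S8S8S3]")
  alphas <- c("", "[S6]")
  full_core <- function(p, a, x) paste0(p, "L3", a, "Vb4", x, "L4GT")

  edge <- function(substrate, enzyme, product) {
    tibble(substrate = substrate, enzyme = enzyme, product = product)
  }
  e <- list(
    edge("T", 1L, "GT"),
    edge("T", 2L, "LT"),
    edge("GT", 3L, "L4GT"),
    # Gala arm sialylation
    edge("LT", 4L, "[S3]LT"),
    edge("[S3]LT", 5L, "[S8S3]LT"),
    edge("[S8S3]LT", 6L, "[S8S8S3]LT"),
    # LacCer branch sialylation
    edge("L4GT", 4L, "[S3]L4GT"),
    edge("[S3]L4GT", 5L, "[S8S3]L4GT"),
    edge("[S8S3]L4GT", 6L, "[S8S8S3]L4GT"),
    # GalNAc extension of the four lactosylceramides
    edge(paste0(brs, "L4GT"), 7L, paste0("Vb4", brs, "L4GT")),
    # Core galactose
    edge(paste0("Vb4", brs, "L4GT"), 8L, full_core("", "", brs)),
    # Terminal sialylation and its alpha decoration
    edge(full_core("", "", brs), 9L, full_core("S3", "", brs)),
    edge(full_core("S3", "", brs), 10L, full_core("S3", "[S6]", brs))
  )
  # Terminal-chain elongation by activity 6 (prefix S3 -> S8S3 -> S8S8S3)
  for (p in c("S3", "S8S3")) {
    for (a in alphas) {
      e <- c(e, list(edge(full_core(p, a, brs), 6L, full_core(paste0("S8", p), a, brs))))
    }
  }
  # Inner-branch elongation [S8S3] -> [S8S8S3] by activity 6
  for (p in chains) {
    for (a in alphas) {
      if (a == "[S6]" && p == "") next
      e <- c(e, list(edge(full_core(p, a, "[S8S3]"), 6L, full_core(p, a, "[S8S8S3]"))))
    }
  }
  e <- c(e, list(edge("Vb4[S8S3]L4GT", 6L, "Vb4[S8S8S3]L4GT")))

  edges <- dplyr::bind_rows(e)
  donors <- c("UDP-G", "UDP-L", "UDP-L", "CMP-S", "CMP-S", "CMP-S", "UDP-V", "UDP-L", "CMP-S", "CMP-S")
  byproducts <- c("UDP", "UDP", "UDP", "CMP", "CMP", "CMP", "UDP", "UDP", "CMP", "CMP")
  edges$donor <- donors[edges$enzyme]
  edges$byproduct <- byproducts[edges$enzyme]

  # Generations by breadth-first traversal from the seed.
  generation <- stats::setNames(0L, "T")
  frontier <- "T"
  g <- 0L
  while (length(frontier) > 0L) {
    g <- g + 1L
    nxt <- setdiff(unique(edges$product[edges$substrate %in% frontier]), names(generation))
    generation[nxt] <- g
    frontier <- nxt
  }
  nodes <- tibble(identifier = names(generation), generation = unname(generation))
  nodes <- dplyr::arrange(nodes, .data$generation, .data$identifier)
  edges <- dplyr::arrange(edges, .data$enzyme, .data$substrate, .data$product)
  new_ganglio_network(nodes, edges, iterations_run = max(nodes$generation),
                      truncated = FALSE, seed = "T", knockouts = integer(0))
}
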