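#' The default glycosyltransferase rule set
#'
#' Returns the ten enzyme activities of ganglioside biosynthesis as
#' string-rewrite rules over canonical abbreviated structure identifiers.
#' Each rule is a nucleotide-sugar donor plus one or more acceptor
#' patterns; applying a rule transfers exactly one residue (the donor
#' sugar) and releases the nucleotide. Patterns are either prefix-anchored
#' (`"P"`: must match from the non-reducing end of the whole identifier,
#' through the terminal `T`, with `*` standing for any bracket-balanced
#' stretch) or internal (`"I"`: a literal bracketed branch matched anywhere
#' in the identifier). Prefix anchoring of the GD3 synthase (activity 5)
#' encodes the model assumption that this sialylation occurs before core
#' extension with GalNAc; the internal branch pattern of activity 6 is what
#' elongates an inner `[S8S3]` branch to `[S8S8S3]`.
#'
#' Beyond the classical acceptor list, the set includes the documented
#' generalizations needed to reach the full network: activity 6 also
#' initiates the terminal chain (`S3*T` to `S8S3*T`), activity 5 acts on
#' the sialylated galactocerebroside (`[S3]LT`), and activity 7 accepts
#' the di- and trisialylated lactosylceramides.
#'
#' @return A tibble with one row per enzyme: `enzyme`, `ec`, `short_name`,
#'   `donor`, `byproduct`, `category` and a `patterns` list-column of
#'   tibbles (`anchor`, `pattern`, `replacement`).
#' @examples
#' default_ruleset()
#' apply_rule(default_ruleset()[4, ], "L4GT")
#' @export
default_ruleset <- function() {
  pat <- function(...) {
    rows <- list(...)
    tibble(
      anchor = vapply(rows, `[[`, character(1), 1L),
      pattern = vapply(rows, `[[`, character(1), 2L),
      replacement = vapply(rows, `[[`, character(1), 3L)
    )
  }
  rules <- tibble(
    enzyme = 1:10,
    ec = c(
      "EC 2.4.1.80", "EC 2.4.1.47", "EC 2.4.1.274", "EC 2.4.99.9",
      "EC 2.4.99.8", "EC 2.4.99.-", "EC 2.4.1.92", "EC 2.4.1.68",
      "EC 2.4.99.-", "EC 2.4.99.-"
    ),
    short_name = c(
      "UGCG", "b1Gal-T3", "b4Gal-T6", "ST3Gal-V", "ST8Sia-I",
      "ST8Sia-V", "b4GalNAc-T1", "b3Gal-T4", "ST3Gal-II", "ST6GalNAc-V"
    ),
    donor = c(
      "UDP-G", "UDP-L", "UDP-L", "CMP-S", "CMP-S",
      "CMP-S", "UDP-V", "UDP-L", "CMP-S", "CMP-S"
    ),
    byproduct = c("UDP", "UDP", "UDP", "CMP", "CMP", "CMP", "UDP", "UDP", "CMP", "CMP"),
    category = c(
      "extension", "extension", "extension", "decoration-with-extension",
      "extension", "termination", "extension", "extension",
      "termination-with-extension", "decoration"
    ),
    patterns = list(
      pat(list("P", "T", "GT")),
      pat(list("P", "T", "LT")),
      pat(list("P", "GT", "L4GT")),
      pat(
        list("P", "L4GT", "[S3]L4GT"),
        list("P", "LT", "[S3]LT")
      ),
      pat(
        list("P", "[S3]L4*T", "[S8S3]L4*T"),
        list("P", "[S3]LT", "[S8S3]LT")
      ),
      pat(
        list("P", "S3*T", "S8S3*T"),
        list("P", "S8S3*T", "S8S8S3*T"),
        list("I", "[S8S3]", "[S8S8S3]")
      ),
      pat(
        list("P", "L4*T", "Vb4L4*T"),
        list("P", "[S3]L4*T", "Vb4[S3]L4*T"),
        list("P", "[S8S3]L4*T", "Vb4[S8S3]L4*T"),
        list("P", "[S8S8S3]L4*T", "Vb4[S8S8S3]L4*T")
      ),
      pat(list("P", "Vb4*T", "L3Vb4*T")),
      pat(list("P", "L3Vb4*T", "S3L3Vb4*T")),
      pat(list("P", "S3L3Vb4*T", "S3L3[S6]Vb4*T"))
    )
  )
  rules
}

DONOR_SUGAR <- c("UDP-G" = "G", "UDP-L" = "L", "UDP-V" = "V", "CMP-S" = "S")

validate_pattern <- function(anchor, pattern, replacement) {
  if (!anchor %in% c("P", "I")) abort(sprintf("Unknown anchor '%s' (use 'P' or 'I').", anchor))
  for (p in c(pattern, replacement)) {
    check_brackets(p)
    if (grepl("\\[[^]]*\\*", p)) abort(sprintf("Wildcard inside brackets in pattern '%s'.", p))
    if (stringr::str_count(p, stringr::fixed("*")) > 1L) {
      abort(sprintf("Pattern '%s' has more than one wildcard.", p))
    }
  }
  if (anchor == "P" && !endsWith(pattern, "T")) {
    abort(sprintf("Prefix pattern '%s' must extend to the reducing-end T.", pattern))
  }
  if (anchor == "I" && !(startsWith(pattern, "[") && endsWith(pattern, "]"))) {
    abort(sprintf("Internal pattern '%s' must be a bracketed branch.", pattern))
  }
  invisible(TRUE)
}

pattern_regex <- function(pattern) {
  esc <- gsub("]", "\\]", gsub("[", "\\[", pattern, fixed = TRUE), fixed = TRUE)
  paste0("^", gsub("*", "(.*)", esc, fixed = TRUE), "$")
}

#' Match an acceptor pattern against a structure
#'
#' Prefix-anchored patterns (`anchor = "P"`) yield at most one site: the
#' whole identifier, with `*` capturing a bracket-balanced stretch.
#' Internal patterns (`anchor = "I"`) yield one site per literal occurrence
#' of the bracketed branch, with bracket characters aligned exactly.
#'
#' @param anchor `"P"` or `"I"`.
#' @param pattern Pattern text over the abbreviated alphabet plus `*`.
#' @param acceptor A `glycan_structure` or canonical identifier string.
#' @param replacement Optional rewrite text; when supplied the rewritten
#'   product for each site is returned in the `product` column.
#' @return A tibble with one row per match site: `start`, `end`,
#'   `wildcard` (captured text or `NA`) and, if `replacement` was given,
#'   `product`.
#' @export
match_pattern <- function(anchor, pattern, acceptor, replacement = NULL) {
  validate_pattern(anchor, pattern, replacement %||% pattern)
  acc <- if (inherits(acceptor, "glycan_structure")) serialize_identifier(acceptor) else acceptor
  out <- tibble(start = integer(0), end = integer(0), wildcard = character(0))
  if (anchor == "P") {
    rx <- pattern_regex(pattern)
    if (grepl(rx, acc)) {
      wc <- if (grepl("*", pattern, fixed = TRUE)) sub(rx, "\\1", acc) else NA_character_
      # The wildcard may only stand for a bracket-balanced stretch.
      ok <- is.na(wc) || tryCatch({ check_brackets(paste0("x", wc, "x")); TRUE },
                                  error = function(e) FALSE)
      if (ok) out <- tibble(start = 1L, end = nchar(acc), wildcard = wc)
    }
  } else {
    hits <- gregexpr(pattern, acc, fixed = TRUE)[[1L]]
    if (hits[1L] != -1L) {
      out <- tibble(
        start = as.integer(hits),
        end = as.integer(hits) + attr(hits, "match.length") - 1L,
        wildcard = NA_character_
      )
    }
  }
  if (!is.null(replacement) && nrow(out) > 0L) {
    out$product <- vapply(seq_len(nrow(out)), function(i) {
      if (anchor == "P") {
        repl <- if (!is.na(out$wildcard[i])) {
          sub("*", out$wildcard[i], replacement, fixed = TRUE)
        } else {
          replacement
        }
        repl
      } else {
        paste0(
          substr(acc, 1L, out$start[i] - 1L), replacement,
          substr(acc, out$end[i] + 1L, nchar(acc))
        )
      }
    }, character(1))
  }
  out
}

#' Apply one enzyme rule to an acceptor
#'
#' Applies every acceptor pattern of the rule and returns one reaction
#' event per distinct product; products are canonicalized and duplicates
#' arising from different patterns are collapsed.
#'
#' @param rule A single row of a rule-set tibble (see [default_ruleset()]).
#' @param acceptor A `glycan_structure` or canonical identifier string.
#' @return A tibble of reaction events: `substrate`, `enzyme`, `product`,
#'   `donor`, `byproduct`.
#' @export
apply_rule <- function(rule, acceptor) {
  stopifnot(nrow(rule) == 1L)
  acc <- if (inherits(acceptor, "glycan_structure")) serialize_identifier(acceptor) else acceptor
  pats <- rule$patterns[[1L]]
  products <- character(0)
  for (i in seq_len(nrow(pats))) {
    m <- match_pattern(pats$anchor[i], pats$pattern[i], acc, replacement = pats$replacement[i])
    if (nrow(m) > 0L) products <- c(products, m$product)
  }
  products <- unique(vapply(products, canonical_identifier, character(1), USE.NAMES = FALSE))
  tibble(
    substrate = rep(acc, length(products)),
    enzyme = rep(rule$enzyme, length(products)),
    product = products,
    donor = rep(rule$donor, length(products)),
    byproduct = rep(rule$byproduct, length(products))
  )
}

#' Apply a whole rule set to one acceptor
#'
#' One synchronous step: every active (non-knocked-out) enzyme is offered
#' the acceptor and all resulting reaction events are pooled.
#'
#' @param ruleset A rule-set tibble.
#' @param acceptor A `glycan_structure` or canonical identifier string.
#' @param knockouts Integer vector of enzyme numbers to disable.
#' @return A tibble of reaction events (possibly zero rows).
#' @export
apply_ruleset_step <- function(ruleset, acceptor, knockouts = integer(0)) {
  knockouts <- check_knockouts(knockouts, ruleset)
  active <- ruleset[!ruleset$enzyme %in% knockouts, , drop = FALSE]
  out <- lapply(seq_len(nrow(active)), function(i) apply_rule(active[i, ], acceptor))
  dplyr::bind_rows(out)
}

check_knockouts <- function(knockouts, ruleset) {
  if (length(knockouts) == 0L) return(integer(0))
  knockouts <- as.integer(knockouts)
  bad <- setdiff(knockouts, ruleset$enzyme)
  if (length(bad)) abort(sprintf("Invalid knockout enzyme number(s): %s.", paste(bad, collapse = ", ")))
  unique(knockouts)
}

#' Classify (and validate) an enzyme rule's mode of action
#'
#' Returns the rule's declared category (extension, decoration,
#' decoration-with-extension, termination, termination-with-extension) after
#' checking that every rewrite has the expected shape: exactly one
#' transferred residue, identical to the donor sugar, inserted either
#' linearly (chain growth) or as a new bracketed branch (decoration). A
#' mismatch between the declared category and the rewrite shape is an error.
#'
#' @param rule A single row of a rule-set tibble.
#' @return The category string.
#' @export
classify_activity <- function(rule) {
  stopifnot(nrow(rule) == 1L)
  sugar <- DONOR_SUGAR[[rule$donor]]
  pats <- rule$patterns[[1L]]
  decorating <- rule$category %in% c("decoration", "decoration-with-extension")
  for (i in seq_len(nrow(pats))) {
    ins <- rewrite_insertion(pats$pattern[i], pats$replacement[i])
    res_code <- gsub("[^GLSV]", "", gsub("\\[|\\]", "", ins))
    if (res_code != sugar) {
      abort(sprintf(
        "Rule %d pattern '%s' inserts '%s', not the donor sugar '%s'.",
        rule$enzyme, pats$pattern[i], ins, sugar
      ))
    }
    is_bracketed <- startsWith(ins, "[") && endsWith(ins, "]")
    if (decorating != is_bracketed) {
      abort(sprintf(
        "Rule %d is declared '%s' but pattern '%s' rewrites %s.",
        rule$enzyme, rule$category, pats$pattern[i],
        if (is_bracketed) "as a bracketed decoration" else "as a linear insertion"
      ))
    }
  }
  rule$category
}

# The inserted text of a rewrite: replacement minus the common prefix/suffix
# it shares with the pattern.
rewrite_insertion <- function(pattern, replacement) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  r <- strsplit(replacement, "", fixed = TRUE)[[1L]]
  i <- 0L
  while (i < length(p) && i < length(r) && p[i + 1L] == r[i + 1L]) i <- i + 1L
  j <- 0L
  while (j < length(p) - i && j < length(r) - i && p[length(p) - j] == r[length(r) - j]) j <- j + 1L
  paste(r[seq.int(i + 1L, length(r) - j)], collapse = "")
}

#' Write a rule set to a plain-text configuration file
#'
#' One record per enzyme:
#' `enzyme | EC | short name | donor | byproduct | category | patterns`,
#' where patterns are `;`-separated `anchor:pattern>replacement` triples.
#' [read_ruleset()] reads the format back; the round trip is exact, so users
#' can edit the file to define custom wild-type enzyme sets.
#'
#' @param ruleset A rule-set tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  lines <- c("# gangliosim ruleset v1")
  for (i in seq_len(nrow(ruleset))) {
    pats <- ruleset$patterns[[i]]
    pat_txt <- paste(sprintf("%s:%s>%s", pats$anchor, pats$pattern, pats$replacement), collapse = " ; ")
    lines <- c(lines, sprintf(
      "%d | %s | %s | %s | %s | %s | %s",
      ruleset$enzyme[i], ruleset$ec[i], ruleset$short_name[i],
      ruleset$donor[i], ruleset$byproduct[i], ruleset$category[i], pat_txt
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a rule set from a plain-text configuration file
#'
#' @param path File written by [write_ruleset()] (or hand-edited in the
#'   same format).
#' @return A rule-set tibble; every rule is validated with
#'   [classify_activity()].
#' @export
read_ruleset <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) {
    parts <- trimws(strsplit(ln, "|", fixed = TRUE)[[1L]])
    if (length(parts) != 7L) abort(sprintf("Malformed ruleset record: '%s'.", ln))
    pat_specs <- trimws(strsplit(parts[7L], ";", fixed = TRUE)[[1L]])
    pats <- lapply(pat_specs, function(ps) {
      m <- regmatches(ps, regexec("^([PI]):([^>]+)>(.+)$", ps))[[1L]]
      if (length(m) != 4L) abort(sprintf("Malformed pattern spec: '%s'.", ps))
      validate_pattern(m[2L], m[3L], m[4L])
      tibble(anchor = m[2L], pattern = m[3L], replacement = m[4L])
    })
    tibble(
      enzyme = as.integer(parts[1L]), ec = parts[2L], short_name = parts[3L],
      donor = parts[4L], byproduct = parts[5L], category = parts[6L],
      patterns = list(dplyr::bind_rows(pats))
    )
  })
  rs <- dplyr::bind_rows(rows)
  for (i in seq_len(nrow(rs))) classify_activity(rs[i, ])
  rs
}

# Precompiled form of a rule set for the expansion inner loop: prefix
# patterns as anchored regexes, internal patterns as fixed strings.
compile_ruleset <- function(ruleset) {
  lapply(seq_len(nrow(ruleset)), function(i) {
    pats <- ruleset$patterns[[i]]
    list(
      enzyme = ruleset$enzyme[i],
      anchor = pats$anchor,
      regex = vapply(pats$pattern, pattern_regex, character(1), USE.NAMES = FALSE),
      fixed = pats$pattern,
      replacement = pats$replacement,
      has_wild = grepl("*", pats$pattern, fixed = TRUE)
    )
  })
}

# Raw rewrite products of one compiled rule on one canonical identifier.
# The wildcard capture of a prefix pattern is automatically bracket-balanced
# here (balanced pattern literal removed from a balanced acceptor), so no
# balance re-check is needed; equivalence with apply_rule() is pinned by the
# oracle and confluence tests.
compiled_rule_products <- function(cr, acc) {
  prods <- character(0)
  for (j in seq_along(cr$anchor)) {
    if (cr$anchor[j] == "P") {
      rx <- cr$regex[j]
      if (grepl(rx, acc)) {
        prods <- c(prods, if (cr$has_wild[j]) {
          sub("*", sub(rx, "\\1", acc), cr$replacement[j], fixed = TRUE)
        } else {
          cr$replacement[j]
        })
      }
    } else {
      hits <- gregexpr(cr$fixed[j], acc, fixed = TRUE)[[1L]]
      if (hits[1L] != -1L) {
        ml <- attr(hits, "match.length")
        for (k in seq_along(hits)) {
          prods <- c(prods, paste0(
            substr(acc, 1L, hits[k] - 1L), cr$replacement[j],
            substr(acc, hits[k] + ml[k], nchar(acc))
          ))
        }
      }
    }
  }
  unique(prods)
}
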