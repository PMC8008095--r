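#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Single-letter residue alphabet and default anomeric configurations.
# G = Glc, L = Gal, S = Neu5Ac, V = GalNAc, T = ceramide attachment point.
RESIDUE_CODES <- c("G", "L", "S", "V", "T")
DEFAULT_ANOMER <- c(G = "b", L = "b", S = "a", V = "a")
IUPAC_SYMBOL <- c(G = "Glc", L = "Gal", S = "Neu5Ac", V = "GalNAc", T = "Cer")

new_residue <- function(code, anomer, linkage, branch = FALSE, children = list()) {
  list(
    code = code, anomer = anomer, linkage = linkage,
    branch = branch, children = children
  )
}

#' Parse a glycan structure identifier
#'
#' Reads a single-letter structure identifier (full or abbreviated dialect)
#' into a rooted residue tree. Identifiers are written non-reducing end
#' first and terminate in `T`, the ceramide attachment point; brackets
#' delimit branches that are not the continuation of the main chain, and
#' each residue carries an optional anomer letter (`a`/`b`) and the linkage
#' position on its parent. Missing anomers are filled with the defaults
#' (Glc, Gal beta; Neu5Ac, GalNAc alpha). The bond to ceramide (1-1) is
#' never written.
#'
#' @param text A single identifier string, e.g. `"Lb3Vb4[Sa3]Lb4GbT"` or
#'   its abbreviated equivalent `"L3Vb4[S3]L4GT"`.
#' @return A `glycan_structure` object.
#' @examples
#' gm1a <- parse_identifier("L3Vb4[S3]L4GT")
#' serialize_identifier(gm1a, "full")
#' count_residues(gm1a, "S")
#' @export
parse_identifier <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort("`text` must be a single non-empty identifier string.")
  }
  if (grepl("[^][GLSVTab1-9]", text)) {
    bad <- regmatches(text, regexpr("[^][GLSVTab1-9]", text))
    abort(sprintf("Unknown character '%s' in identifier '%s'.", bad, text))
  }
  n_t <- lengths(regmatches(text, gregexpr("T", text, fixed = TRUE)))
  if (n_t == 0L) abort(sprintf("Identifier '%s' has no ceramide terminus 'T'.", text))
  if (n_t > 1L) abort(sprintf("Identifier '%s' contains more than one 'T' (multiple roots).", text))
  if (!endsWith(text, "T")) abort(sprintf("'T' must be the final character of '%s'.", text))
  check_brackets(text)

  body <- substr(text, 1L, nchar(text) - 1L)
  root <- new_residue("T", NA_character_, NA_integer_)
  if (nzchar(body)) {
    if (endsWith(body, "]")) {
      abort(sprintf("The residue bonded to ceramide in '%s' must be a chain residue, not a bracketed branch.", text))
    }
    child <- parse_chain(body, text)
    if (!is.na(child$linkage)) {
      abort(sprintf(
        "The residue bonded to ceramide carries a linkage digit in '%s'; the 1-1 bond is implicit and never written.",
        text
      ))
    }
    root$children <- list(child)
  }
  new_structure(root)
}

check_brackets <- function(text) {
  depth <- 0L
  for (ch in strsplit(text, "", fixed = TRUE)[[1L]]) {
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") depth <- depth - 1L
    if (depth < 0L) abort(sprintf("Unbalanced brackets in '%s'.", text))
  }
  if (depth != 0L) abort(sprintf("Unbalanced brackets in '%s'.", text))
  invisible(TRUE)
}

# Recursive descent over one chain segment: the segment's rightmost token is
# the residue closest to the reducing end; bracket groups immediately to its
# left are its branches, anything further left is the chain continuation.
parse_chain <- function(s, whole) {
  m <- regexpr("([GLSV])([ab]?)([1-9]?)$", s)
  if (m == -1L) {
    abort(sprintf("Expected a residue code at '...%s' in '%s'.", s, whole))
  }
  tok <- regmatches(s, m)
  code <- substr(tok, 1L, 1L)
  anomer <- if (grepl("[ab]", tok)) regmatches(tok, regexpr("[ab]", tok)) else DEFAULT_ANOMER[[code]]
  linkage <- if (grepl("[1-9]", tok)) as.integer(regmatches(tok, regexpr("[1-9]", tok))) else NA_integer_
  rest <- substr(s, 1L, nchar(s) - attr(m, "match.length"))

  children <- list()
  while (endsWith(rest, "]")) {
    open <- matching_open(rest)
    grp <- substr(rest, open + 1L, nchar(rest) - 1L)
    if (!nzchar(grp)) abort(sprintf("Empty branch '[]' in '%s'.", whole))
    ch <- parse_chain(grp, whole)
    if (is.na(ch$linkage)) {
      abort(sprintf("Bracketed branch '[%s]' in '%s' lacks a linkage position.", grp, whole))
    }
    ch$branch <- TRUE
    children <- c(children, list(ch))
    rest <- substr(rest, 1L, open - 1L)
  }
  if (nzchar(rest)) {
    ch <- parse_chain(rest, whole)
    if (is.na(ch$linkage)) {
      abort(sprintf("Chain residue '%s' in '%s' lacks a linkage position.", rest, whole))
    }
    ch$branch <- FALSE
    children <- c(children, list(ch))
  }
  new_residue(code, anomer, linkage, children = order_children(children))
}

# Scan backwards from a trailing "]" to its matching "[".
matching_open <- function(s) {
  depth <- 0L
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (i in rev(seq_along(chars))) {
    if (chars[i] == "]") depth <- depth + 1L
    if (chars[i] == "[") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  abort(sprintf("Unbalanced brackets in '%s'.", s))
}

# Canonical sibling order: bracketed branches by ascending linkage (ties by
# serialized form), then the unbracketed chain continuation.
order_children <- function(children) {
  if (length(children) <= 1L) return(children)
  br <- Filter(function(x) x$branch, children)
  chain <- Filter(function(x) !x$branch, children)
  if (length(chain) > 1L) abort("A residue can have at most one unbracketed chain continuation.")
  if (length(br) > 1L) {
    key <- vapply(br, function(x) sprintf("%d%s", x$linkage, serialize_node(x, full = TRUE)), character(1))
    br <- br[order(key)]
  }
  c(br, chain)
}

new_structure <- function(root) {
  structure(list(root = root), class = "glycan_structure")
}

#' Serialize a glycan structure to its identifier string
#'
#' Produces the canonical identifier. In the abbreviated dialect default
#' anomer letters are dropped, except for GalNAc whose `b` is always
#' retained (it occurs as the beta anomer in gangliosides, opposite to its
#' default). Branches are written with the lowest linkage first, reading
#' from right to left, and the main-chain continuation leftmost.
#'
#' @param s A `glycan_structure`.
#' @param dialect `"abbreviated"` (default) or `"full"`.
#' @return A single identifier string.
#' @export
serialize_identifier <- function(s, dialect = c("abbreviated", "full")) {
  dialect <- match.arg(dialect)
  s <- as_structure(s)
  body <- if (length(s$root$children)) {
    serialize_node(s$root$children[[1L]], full = dialect == "full")
  } else {
    ""
  }
  paste0(body, "T")
}

serialize_node <- function(node, full) {
  kids <- node$children
  chain <- Filter(function(x) !x$branch, kids)
  br <- Filter(function(x) x$branch, kids)
  if (length(br) > 1L) {
    key <- vapply(br, function(x) x$linkage, integer(1))
    br <- br[order(-key)] # highest linkage leftmost: lowest ends up rightmost
  }
  chain_txt <- if (length(chain)) serialize_node(chain[[1L]], full) else ""
  br_txt <- paste(vapply(br, function(x) paste0("[", serialize_node(x, full), "]"), character(1)), collapse = "")
  write_anomer <- full || node$code == "V" || !identical(node$anomer, DEFAULT_ANOMER[[node$code]])
  tok <- paste0(
    node$code,
    if (write_anomer) node$anomer else "",
    if (!is.na(node$linkage)) node$linkage else ""
  )
  paste0(chain_txt, br_txt, tok)
}

#' @export
as.character.glycan_structure <- function(x, ...) serialize_identifier(x, "abbreviated")

#' @export
format.glycan_structure <- function(x, ...) {
  sprintf(
    "<glycan_structure> %s (%d residues)",
    serialize_identifier(x), n_residues(x)
  )
}

#' @export
print.glycan_structure <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Accept either a glycan_structure or an identifier string everywhere.
as_structure <- function(x) {
  if (inherits(x, "glycan_structure")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_identifier(x))
  abort("Expected a glycan_structure or a single identifier string.")
}

walk_residues <- function(node, f) {
  f(node)
  for (ch in node$children) walk_residues(ch, f)
  invisible(NULL)
}

#' Count residues of a given code
#'
#' @param s A `glycan_structure` or identifier string.
#' @param code One of `"G"`, `"L"`, `"S"`, `"V"`, `"T"`.
#' @return Integer count.
#' @export
count_residues <- function(s, code) {
  if (!is.character(code) || length(code) != 1L || !code %in% RESIDUE_CODES) {
    abort("`code` must be one of G, L, S, V, T.")
  }
  s <- as_structure(s)
  n <- 0L
  walk_residues(s$root, function(node) {
    if (node$code == code) n <<- n + 1L
  })
  n
}

n_residues <- function(s) {
  s <- as_structure(s)
  n <- 0L
  walk_residues(s$root, function(node) n <<- n + 1L)
  n
}

#' Canonicalize structure identifiers
#'
#' Vectorized parse-and-reserialize: accepts identifiers in either dialect
#' (and any sibling branch order) and returns the canonical form.
#'
#' @param x Character vector of identifiers.
#' @param dialect Output dialect, `"abbreviated"` or `"full"`.
#' @return Character vector of canonical identifiers.
#' @export
canonical_identifier <- function(x, dialect = c("abbreviated", "full")) {
  dialect <- match.arg(dialect)
  vapply(x, function(id) serialize_identifier(parse_identifier(id), dialect), character(1), USE.NAMES = FALSE)
}

#' All structures of the ganglioside grammar
#'
#' Enumerates, in closed form and without the rewriting engine, the canonical
#' abbreviated identifiers of every structure the ganglioside grammar can
#' produce: ceramide, the galactocerebroside (Gala) arm, the
#' glucosylceramide arm with its sialylated and GalNAc-extended
#' intermediates, and the fully extended core family parameterized by the
#' position II branch (0-3 sialic acids), the position IV terminal chain
#' (0-3) and the optional alpha2-6 sialic acid on position III (only when a
#' terminal chain is present).
#'
#' @param include_seed Include the bare ceramide `"T"`? Default `TRUE`.
#' @return Character vector of canonical abbreviated identifiers (42 with
#'   the seed, 41 without).
#' @export
ganglioside_identifiers <- function(include_seed = TRUE) {
  sial_chain <- function(k) paste(rev(c("S3", "S8", "S8")[seq_len(k)]), collapse = "")
  chains <- vapply(0:3, sial_chain, character(1)) # "", "S3", "S8S3", "S8S8S3"
  brs <- ifelse(nzchar(chains), paste0("[", chains, "]"), "")

  gala <- paste0(brs, "LT")
  glc_arm <- c("GT", "L4GT", paste0(brs[-1], "L4GT"), paste0("Vb4", brs, "L4GT"))
  full_core <- character(0)
  for (p in chains) {
    for (a in c("", "[S6]")) {
      if (a == "[S6]" && p == "") next
      full_core <- c(full_core, paste0(p, "L3", a, "Vb4", brs, "L4GT"))
    }
  }
  out <- c(if (include_seed) "T", gala, glc_arm, full_core)
  unname(out)
}

#' Sample grammar-valid structures
#'
#' Draws identifiers uniformly (with replacement) from the full ganglioside
#' grammar, for property-style testing.
#'
#' @param n Number of draws.
#' @param include_seed Allow the bare ceramide to be drawn.
#' @return Character vector of length `n`.
#' @export
sample_ganglioside_identifiers <- function(n, include_seed = FALSE) {
  pool <- ganglioside_identifiers(include_seed = include_seed)
  sample(pool, n, replace = TRUE)
}
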