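#' Convert a structure to IUPAC condensed notation
#'
#' Writes the carbohydrate in condensed linear IUPAC form, e.g. GM1a becomes
#' `"Galb1-3GalNAcb1-4[Neu5Aca2-3]Galb1-4GlcCer"`. Sugar names follow the
#' single-letter code table (Glc, Gal, Neu5Ac, GalNAc, Cer); sialic acid
#' linkages are written with the `a2-` prefix; the residue bonded to
#' ceramide is written bare (the 1-1 bond is implicit).
#'
#' @param s A `glycan_structure` or identifier string.
#' @return IUPAC condensed string.
#' @export
to_iupac_condensed <- function(s) {
  s <- as_structure(s)
  if (length(s$root$children) == 0L) return("Cer")
  paste0(iupac_node(s$root$children[[1L]]), "Cer")
}

iupac_node <- function(node) {
  kids <- node$children
  chain <- Filter(function(x) !x$branch, kids)
  br <- Filter(function(x) x$branch, kids)
  if (length(br) > 1L) br <- br[order(-vapply(br, function(x) x$linkage, integer(1)))]
  chain_txt <- if (length(chain)) iupac_node(chain[[1L]]) else ""
  br_txt <- paste(vapply(br, function(x) paste0("[", iupac_node(x), "]"), character(1)), collapse = "")
  anomeric_c <- if (node$code == "S") 2L else 1L
  tok <- if (is.na(node$linkage)) {
    IUPAC_SYMBOL[[node$code]]
  } else {
    sprintf("%s%s%d-%d", IUPAC_SYMBOL[[node$code]], node$anomer, anomeric_c, node$linkage)
  }
  paste0(chain_txt, br_txt, tok)
}

#' Parse IUPAC condensed notation to a structure
#'
#' Inverse of [to_iupac_condensed()]: reads strings such as
#' `"Galb1-3GalNAcb1-4[Neu5Aca2-3]Galb1-4GlcCer"` or `"GlcCer"` into a
#' `glycan_structure`. The round trip through both functions is lossless.
#'
#' @param text IUPAC condensed string ending in `"Cer"`.
#' @return A `glycan_structure`.
#' @export
from_iupac_condensed <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort("`text` must be a single IUPAC condensed string.")
  }
  if (!endsWith(text, "Cer")) abort(sprintf("IUPAC condensed string '%s' must end in 'Cer'.", text))
  check_brackets(text)
  body <- substr(text, 1L, nchar(text) - 3L)
  root <- new_residue("T", NA_character_, NA_integer_)
  if (nzchar(body)) {
    child <- parse_iupac_chain(body, text)
    if (!is.na(child$linkage)) {
      abort(sprintf("The residue bonded to Cer in '%s' must not carry a linkage.", text))
    }
    root$children <- list(child)
  }
  new_structure(root)
}

IUPAC_CODE <- c(Glc = "G", Gal = "L", Neu5Ac = "S", GalNAc = "V")

parse_iupac_chain <- function(s, whole) {
  m <- regexpr("(GalNAc|Neu5Ac|Glc|Gal)(([ab])([12])-([1-9]))?$", s)
  if (m == -1L) abort(sprintf("Unknown sugar token at '...%s' in '%s'.", s, whole))
  tok <- regmatches(s, m)
  name <- regmatches(tok, regexpr("^(GalNAc|Neu5Ac|Glc|Gal)", tok))
  code <- IUPAC_CODE[[name]]
  rest_tok <- substr(tok, nchar(name) + 1L, nchar(tok))
  if (nzchar(rest_tok)) {
    anomer <- substr(rest_tok, 1L, 1L)
    anomeric_c <- as.integer(substr(rest_tok, 2L, 2L))
    linkage <- as.integer(substr(rest_tok, 4L, 4L))
    expected_c <- if (code == "S") 2L else 1L
    if (anomeric_c != expected_c) {
      abort(sprintf("Malformed linkage '%s' in '%s': %s links from carbon %d.", rest_tok, whole, name, expected_c))
    }
  } else {
    anomer <- DEFAULT_ANOMER[[code]]
    linkage <- NA_integer_
  }
  rest <- substr(s, 1L, nchar(s) - attr(m, "match.length"))
  children <- list()
  while (endsWith(rest, "]")) {
    open <- matching_open(rest)
    grp <- substr(rest, open + 1L, nchar(rest) - 1L)
    if (!nzchar(grp)) abort(sprintf("Empty branch '[]' in '%s'.", whole))
    ch <- parse_iupac_chain(grp, whole)
    if (is.na(ch$linkage)) abort(sprintf("Branch '[%s]' in '%s' lacks a linkage.", grp, whole))
    ch$branch <- TRUE
    children <- c(children, list(ch))
    rest <- substr(rest, 1L, open - 1L)
  }
  if (nzchar(rest)) {
    ch <- parse_iupac_chain(rest, whole)
    if (is.na(ch$linkage)) abort(sprintf("Chain residue before '%s' in '%s' lacks a linkage.", tok, whole))
    ch$branch <- FALSE
    children <- c(children, list(ch))
  }
  new_residue(code, anomer, linkage, children = order_children(children))
}

# Fixed export symbol map for Linear Code output.
LINEAR_CODE_SYMBOL <- c(L = "A", G = "G", V = "GN", S = "NN")

#' Export a structure as Linear Code
#'
#' Deterministic export-only rendering in Linear Code style: Gal is `A`,
#' Glc is `G`, GalNAc is `GN`, Neu5Ac is `NN`; branches are parenthesized;
#' the ceramide is the suffix `Cer`. GM1a renders as
#' `"Ab3GNb4(NNa3)Ab4GCer"`. There is no importer for this notation.
#'
#' @param s A `glycan_structure` or identifier string.
#' @return Linear Code string.
#' @export
to_linear_code <- function(s) {
  s <- as_structure(s)
  if (length(s$root$children) == 0L) return("Cer")
  paste0(linear_code_node(s$root$children[[1L]]), "Cer")
}

linear_code_node <- function(node) {
  if (!node$code %in% names(LINEAR_CODE_SYMBOL)) {
    abort(sprintf("Residue '%s' has no Linear Code symbol.", node$code))
  }
  kids <- node$children
  chain <- Filter(function(x) !x$branch, kids)
  br <- Filter(function(x) x$branch, kids)
  if (length(br) > 1L) br <- br[order(-vapply(br, function(x) x$linkage, integer(1)))]
  chain_txt <- if (length(chain)) linear_code_node(chain[[1L]]) else ""
  br_txt <- paste(vapply(br, function(x) paste0("(", linear_code_node(x), ")"), character(1)), collapse = "")
  tok <- paste0(
    LINEAR_CODE_SYMBOL[[node$code]],
    if (!is.na(node$linkage)) paste0(node$anomer, node$linkage) else ""
  )
  paste0(chain_txt, br_txt, tok)
}
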