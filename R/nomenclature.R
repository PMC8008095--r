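# Sialic-acid count letters: Asialo, Mono, Di, Tri, tetra (Q), Penta,
# Hexa, Septa.
SIALO_LETTERS <- c("A", "M", "D", "T", "Q", "P", "H", "S")
SERIES_LETTERS <- c("a", "b", "c")

#' Systematic Svennerholm name of a structure
#'
#' Assembles the systematic Svennerholm name (SSN):
#' `"G"` + sialic-acid-count letter (A = 0, M = 1, D = 2, T = 3, Q = 4,
#' P = 5, H = 6, S = 7) + core number (`4 - n + 1`, where `n` is the core
#' length and GalCer counts as core number 4) + series letter a/b/c when
#' the core is fully extended and position II carries 1/2/3 sialic acids +
#' a trailing `α` when an alpha2-6 Neu5Ac sits on position III.
#' Bare ceramide and GlcCer have no SSN (the system starts at
#' LacCer/GalCer) and yield `NA`.
#'
#' @param s A `glycan_structure` or identifier string.
#' @return The SSN as a string, or `NA_character_` for the two unnamed
#'   structures.
#' @examples
#' systematic_svennerholm("S3L3[S6]Vb4[S8S8S3]L4GT") # "GP1cα"
#' systematic_svennerholm("L3Vb4[S3]L4GT") # "GM1a"
#' @export
systematic_svennerholm <- function(s) {
  s <- as_structure(s)
  ci <- core_info(s)
  if (!ci$classifiable) {
    abort(sprintf("No Svennerholm name: %s.", ci$reason))
  }
  if (ci$base_kind == "ceramide" || (ci$base_kind == "Glc" && ci$n == 1L)) {
    return(NA_character_) # no SSN defined for T or GlcCer
  }
  total <- count_residues(s, "S")
  if (total > 7L) {
    abort(sprintf("Sialic acid count %d exceeds the supported letters (A through S, 0-7).", total))
  }
  letter <- SIALO_LETTERS[total + 1L]
  series <- if (ci$base_kind == "Glc" && ci$n == 4L && ci$sial_II >= 1L) {
    SERIES_LETTERS[ci$sial_II]
  } else {
    ""
  }
  alpha <- if (ci$sial_III == 1L) "α" else ""
  paste0("G", letter, ci$core_number, series, alpha)
}

#' IUPAC ganglioside name of a structure
#'
#' Lists the sialylation sites from the non-reducing end (position IV, then
#' III, then II as Roman numerals, each with its superscripted linkage and
#' `Neu5Ac`, chains as parenthesized `(Neu5Ac)` with a subscripted count),
#' followed by a hyphen and the core descriptor `Gg` with the core length
#' subscripted (`GalCer` for the Gal-based core, with its sialylation on
#' position I). By default super/subscripts are rendered flat
#' (`"II3(Neu5Ac)3-Gg4Cer"`); with `markup = TRUE` they use caret and
#' underscore markup (`"II^3^(Neu5Ac)_3_-Gg_4_Cer"`).
#'
#' @param s A `glycan_structure` or identifier string.
#' @param markup Use `^..^`/`_.._` markup for super/subscripts?
#' @return The IUPAC name as a string (`"Cer"` and `"GlcCer"` for the two
#'   structures outside the naming system).
#' @examples
#' iupac_ganglioside_name("S3L3[S6]Vb4[S8S8S3]L4GT")
#' @export
iupac_ganglioside_name <- function(s, markup = FALSE) {
  s <- as_structure(s)
  ci <- core_info(s)
  if (!ci$classifiable) {
    abort(sprintf("No IUPAC ganglioside name: %s.", ci$reason))
  }
  sup <- function(x) if (markup) paste0("^", x, "^") else as.character(x)
  sub_ <- function(x) if (markup) paste0("_", x, "_") else as.character(x)
  term <- function(roman, linkage, k) {
    if (k == 0L) return(NULL)
    if (k == 1L) {
      paste0(roman, sup(linkage), "Neu5Ac")
    } else {
      paste0(roman, sup(linkage), "(Neu5Ac)", sub_(k))
    }
  }
  if (ci$base_kind == "ceramide") return("Cer")
  if (ci$base_kind == "Gal") {
    terms <- term("I", 3L, ci$sial_I)
    core <- "GalCer"
    return(if (is.null(terms)) core else paste0(terms, "-", core))
  }
  if (ci$n == 1L) return("GlcCer")
  terms <- c(
    term("IV", 3L, ci$sial_IV),
    term("III", 6L, ci$sial_III),
    term("II", 3L, ci$sial_II)
  )
  core <- paste0("Gg", sub_(ci$n), "Cer")
  if (length(terms) == 0L) core else paste0(paste(terms, collapse = ","), "-", core)
}

# The four names whose common usage differs from the systematic form.
LEGACY_TO_SSN <- c(
  "GM1b" = "GM1", "GM1" = "GM1a", "GD1c" = "GD1", "GD1aα" = "GD1α"
)
SSN_TO_LEGACY <- stats::setNames(names(LEGACY_TO_SSN), unname(LEGACY_TO_SSN))

#' Map between legacy and systematic Svennerholm names
#'
#' Applies the four classical discrepancies (GM1b <-> GM1, GM1 <-> GM1a,
#' GD1c <-> GD1, GD1a alpha <-> GD1 alpha); every other well-formed name is
#' its own image. The legacy name `"GM1"` is ambiguous -- as commonly used
#' it means GM1a, but it is also itself a valid SSN (commonly written
#' GM1b) -- so mapping it toward the SSN returns both candidates with a
#' warning, most likely first.
#'
#' @param name A Svennerholm-style name.
#' @param direction `"to_ssn"` (legacy to systematic, default) or
#'   `"to_legacy"`.
#' @return Character vector of mapped name(s) (length 2 only for the
#'   ambiguous legacy `"GM1"`).
#' @export
legacy_mapping <- function(name, direction = c("to_ssn", "to_legacy")) {
  direction <- match.arg(direction)
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    abort("`name` must be a single name string.")
  }
  if (!grepl("^G[AMDTQPHS][1-4][abc]?(α|alpha)?$", name)) {
    abort(sprintf("Unparseable Svennerholm-style name '%s'.", name))
  }
  name <- sub("alpha$", "α", name)
  if (direction == "to_ssn") {
    if (name == "GM1") {
      warn("Legacy 'GM1' is ambiguous: commonly GM1a, but also the SSN GM1 (legacy GM1b); returning both.")
      return(c("GM1a", "GM1"))
    }
    unname(LEGACY_TO_SSN[name] %|na|% name)
  } else {
    unname(SSN_TO_LEGACY[name] %|na|% name)
  }
}

`%|na|%` <- function(x, y) if (length(x) == 0L || is.na(x)) y else x

#' Reconstruct a structure from its systematic Svennerholm name
#'
#' Inverts [systematic_svennerholm()]: the series letter gives the
#' position II branch (1-3 sialic acids), the trailing alpha the single
#' position III Neu5Ac, and the remainder of the total count the terminal
#' position IV chain. Core numbers 2 and 3 put the whole count on position
#' II; core number 4 is the Gal-based core with its chain on position I.
#' Inconsistent names (e.g. `"GM1b"`, whose series letter implies two
#' sialic acids but whose letter M says one) are errors.
#'
#' @param name An SSN string such as `"GP1cα"`.
#' @return A `glycan_structure`.
#' @examples
#' as.character(parse_ssn("GP1cα")) # "S3L3[S6]Vb4[S8S8S3]L4GT"
#' @export
parse_ssn <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    abort("`name` must be a single SSN string.")
  }
  m <- regmatches(name, regexec("^G([AMDTQPHS])([1-4])([abc]?)(α|alpha)?$", name))[[1L]]
  if (length(m) == 0L) abort(sprintf("Not a well-formed SSN: '%s'.", name))
  total <- match(m[2L], SIALO_LETTERS) - 1L
  core_number <- as.integer(m[3L])
  series <- m[4L]
  alpha <- !is.na(m[5L]) && nzchar(m[5L])

  sial_chain <- function(k) paste(rev(c("S3", "S8", "S8")[seq_len(k)]), collapse = "")
  br <- function(k) if (k == 0L) "" else paste0("[", sial_chain(k), "]")

  if (core_number != 1L && nzchar(series)) {
    abort(sprintf("'%s': a series letter requires the fully extended core (core number 1).", name))
  }
  if (core_number != 1L && alpha) {
    abort(sprintf("'%s': α requires the fully extended core (core number 1).", name))
  }
  if (core_number == 1L) {
    ii <- if (nzchar(series)) match(series, SERIES_LETTERS) else 0L
    iii <- as.integer(alpha)
    iv <- total - ii - iii
    if (iv < 0L) {
      abort(sprintf(
        "Inconsistent SSN '%s': series/α imply %d sialic acids but the letter %s gives only %d.",
        name, ii + iii, m[2L], total
      ))
    }
    if (iv > 3L) {
      abort(sprintf("Inconsistent SSN '%s': implied position IV chain of %d exceeds 3.", name, iv))
    }
    if (alpha && iv == 0L) {
      abort(sprintf("Inconsistent SSN '%s': α requires a terminal sialic acid on position IV.", name))
    }
    id <- paste0(sial_chain(iv), "L3", if (alpha) "[S6]", "Vb4", br(ii), "L4GT")
  } else if (core_number == 2L) {
    if (total > 3L) abort(sprintf("Inconsistent SSN '%s': %d sialic acids cannot sit on position II.", name, total))
    id <- paste0("Vb4", br(total), "L4GT")
  } else if (core_number == 3L) {
    if (total > 3L) abort(sprintf("Inconsistent SSN '%s': %d sialic acids cannot sit on position II.", name, total))
    id <- paste0(br(total), "L4GT")
  } else {
    if (total > 3L) abort(sprintf("Inconsistent SSN '%s': %d sialic acids cannot sit on GalCer.", name, total))
    id <- paste0(br(total), "LT")
  }
  parse_identifier(id)
}

# Series classification used in exports and figures: full-core structures
# by position II count, the Gal-based arm as "Gala", precursors blank.
series_of <- function(ci) {
  if (!ci$classifiable) return(NA_character_)
  if (ci$base_kind == "Gal") return("Gala")
  if (ci$base_kind == "Glc" && ci$n == 4L) {
    return(c("0", "a", "b", "c")[ci$sial_II + 1L])
  }
  ""
}

#' Name table for a set of structures
#'
#' Tidy, vectorized naming: one row per identifier with both identifier
#' dialects, the SSN, its common legacy form, the IUPAC ganglioside name,
#' and classification columns. Structures without an SSN (ceramide,
#' GlcCer) get `NA` names; unclassifiable identifiers get `NA` throughout
#' rather than an error.
#'
#' @param ids Character vector of structure identifiers (either dialect).
#' @return A tibble with columns `identifier`, `identifier_full`, `ssn`,
#'   `legacy_name`, `iupac_name`, `sialo_count`, `core_number`, `series`,
#'   `alpha`.
#' @examples
#' glycan_names(c("L3Vb4[S3]L4GT", "[S3]LT", "GT"))
#' @export
glycan_names <- function(ids) {
  if (length(ids) == 0L) {
    return(tibble(
      identifier = character(0), identifier_full = character(0),
      ssn = character(0), legacy_name = character(0), iupac_name = character(0),
      sialo_count = integer(0), core_number = integer(0),
      series = character(0), alpha = logical(0)
    ))
  }
  rows <- lapply(ids, function(id) {
    s <- parse_identifier(id)
    ci <- core_info(s)
    ssn <- tryCatch(systematic_svennerholm(s), error = function(e) NA_character_)
    legacy <- if (is.na(ssn)) NA_character_ else legacy_mapping(ssn, "to_legacy")
    iupac <- tryCatch(iupac_ganglioside_name(s), error = function(e) NA_character_)
    tibble(
      identifier = serialize_identifier(s, "abbreviated"),
      identifier_full = serialize_identifier(s, "full"),
      ssn = ssn,
      legacy_name = legacy,
      iupac_name = iupac,
      sialo_count = count_residues(s, "S"),
      core_number = ci$core_number,
      series = series_of(ci),
      alpha = identical(ci$sial_III, 1L)
    )
  })
  dplyr::bind_rows(rows)
}
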