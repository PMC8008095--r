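#' Classify a structure against the ganglioside core grammar
#'
#' Identifies the core (Glc-based ganglio backbone Glc-Gal-GalNAc-Gal at
#' Roman-numeral positions I-IV, or the Gal-based galactocerebroside core),
#' the core length `n` (number of backbone residues present), the derived
#' core number `4 - n + 1`, and the three sialylation counts: the bracketed
#' Neu5Ac chain on position II (0-3), the terminal unbracketed Neu5Ac chain
#' on position IV (0-3), and the single alpha2-6 Neu5Ac on position III
#' (0 or 1). Structures outside the grammar are flagged unclassifiable
#' with a reason, never silently misassigned.
#'
#' @param s A `glycan_structure` or identifier string.
#' @return A list of class `core_info` with fields `classifiable`, `reason`,
#'   `base_kind` (`"ceramide"`, `"Glc"` or `"Gal"`), `n`, `core_number`,
#'   `positions` (named character vector, Roman numerals to residue codes),
#'   `sial_I` (Gal-based chain), `sial_II`, `sial_III`, `sial_IV`.
#' @examples
#' core_info("L3Vb4[S3]L4GT") # GM1a: n = 4, II branch = 1
#' @export
core_info <- function(s) {
  s <- as_structure(s)
  res <- tryCatch(core_info_impl(s), core_info_error = function(e) {
    empty_core_info(classifiable = FALSE, reason = conditionMessage(e))
  })
  res
}

unclassifiable <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "core_info_error")
}

empty_core_info <- function(classifiable, reason = NA_character_) {
  structure(
    list(
      classifiable = classifiable, reason = reason,
      base_kind = NA_character_, n = NA_integer_, core_number = NA_integer_,
      positions = character(0),
      sial_I = 0L, sial_II = 0L, sial_III = 0L, sial_IV = 0L
    ),
    class = "core_info"
  )
}

core_info_impl <- function(s) {
  out <- empty_core_info(classifiable = TRUE)
  root <- s$root
  if (length(root$children) == 0L) {
    out$base_kind <- "ceramide"
    out$n <- 0L
    out$core_number <- NA_integer_
    return(out)
  }
  base <- root$children[[1L]]

  if (base$code == "L") {
    # Galactocerebroside core: Gal on ceramide, optionally one bracketed
    # sialyl chain at position 3. Denoted core number 4.
    out$base_kind <- "Gal"
    out$n <- 1L
    out$core_number <- 4L
    out$positions <- c(I = "L")
    extra <- base$children
    if (length(extra) > 1L) unclassifiable("GalCer carries more than one substituent")
    if (length(extra) == 1L) {
      out$sial_I <- sialyl_chain_length(extra[[1L]], expect_branch = TRUE, expect_linkage = 3L, where = "GalCer")
    }
    return(out)
  }
  if (base$code != "G") {
    unclassifiable("residue '%s' bonded to ceramide is neither Glc nor Gal", base$code)
  }

  out$base_kind <- "Glc"
  out$positions <- c(I = "G")
  out$n <- 1L
  out$core_number <- 4L

  gal2 <- expect_chain_child(base, code = "L", linkage = 4L, where = "position I Glc",
                             allowed_branches = 0L)
  if (is.null(gal2)) return(out)
  out$positions <- c(out$positions, II = "L")
  out$n <- 2L
  out$core_number <- 3L

  # Position II galactose: optional bracketed sialyl chain at 3, optional
  # chain GalNAc at 4.
  br <- Filter(function(x) x$branch, gal2$children)
  if (length(br) > 1L) unclassifiable("position II Gal carries more than one branch")
  if (length(br) == 1L) {
    out$sial_II <- sialyl_chain_length(br[[1L]], expect_branch = TRUE, expect_linkage = 3L, where = "position II Gal")
  }
  galnac <- expect_chain_child(gal2, code = "V", linkage = 4L, where = "position II Gal",
                               allowed_branches = length(br))
  if (is.null(galnac)) return(out)
  if (!identical(galnac$anomer, "b")) unclassifiable("core GalNAc must be the beta anomer")
  out$positions <- c(out$positions, III = "V")
  out$n <- 3L
  out$core_number <- 2L

  # Position III GalNAc: optional single bracketed Neu5Ac at 6, optional
  # chain Gal at 3.
  br3 <- Filter(function(x) x$branch, galnac$children)
  if (length(br3) > 1L) unclassifiable("position III GalNAc carries more than one branch")
  if (length(br3) == 1L) {
    k <- sialyl_chain_length(br3[[1L]], expect_branch = TRUE, expect_linkage = 6L, where = "position III GalNAc")
    if (k != 1L) unclassifiable("position III carries a sialyl chain of length %d; only a single alpha2-6 Neu5Ac is allowed", k)
    out$sial_III <- 1L
  }
  gal4 <- expect_chain_child(galnac, code = "L", linkage = 3L, where = "position III GalNAc",
                             allowed_branches = length(br3))
  if (is.null(gal4)) return(out)
  out$positions <- c(out$positions, IV = "L")
  out$n <- 4L
  out$core_number <- 1L

  # Position IV galactose: optional terminal (unbracketed) sialyl chain at 3.
  kids <- gal4$children
  if (any(vapply(kids, function(x) x$branch, logical(1)))) {
    unclassifiable("position IV Gal carries a bracketed branch; only a terminal sialyl chain is allowed")
  }
  if (length(kids) > 1L) unclassifiable("position IV Gal has more than one substituent")
  if (length(kids) == 1L) {
    out$sial_IV <- sialyl_chain_length(kids[[1L]], expect_branch = FALSE, expect_linkage = 3L, where = "position IV Gal")
  }
  out
}

# The chain continuation of `node` must (if present) be `code` at `linkage`;
# returns it or NULL if the core stops here. Any other chain residue is an
# error. `allowed_branches` is how many branch children have already been
# accounted for.
expect_chain_child <- function(node, code, linkage, where, allowed_branches) {
  chain <- Filter(function(x) !x$branch, node$children)
  n_br <- sum(vapply(node$children, function(x) x$branch, logical(1)))
  if (n_br > allowed_branches) {
    unclassifiable("unexpected branch on %s", where)
  }
  if (length(chain) == 0L) return(NULL)
  ch <- chain[[1L]]
  if (ch$code != code || !identical(ch$linkage, linkage)) {
    unclassifiable(
      "unexpected chain residue %s%d on %s (expected %s at position %d or nothing)",
      ch$code, ch$linkage, where, code, linkage
    )
  }
  ch
}

# Validate an S3(-S8)* sialyl chain hanging off `node`'s attachment point
# and return its length (1-3).
sialyl_chain_length <- function(node, expect_branch, expect_linkage, where) {
  if (node$code != "S") unclassifiable("substituent on %s is %s, expected Neu5Ac", where, node$code)
  if (!identical(node$branch, expect_branch)) {
    unclassifiable("sialyl chain on %s has unexpected %s form", where, if (expect_branch) "unbracketed" else "bracketed")
  }
  if (!identical(node$linkage, expect_linkage)) {
    unclassifiable("sialic acid on %s is linked at %d, expected %d", where, node$linkage, expect_linkage)
  }
  k <- 1L
  cur <- node
  while (length(cur$children) > 0L) {
    if (length(cur$children) > 1L) unclassifiable("branched sialyl chain on %s", where)
    nxt <- cur$children[[1L]]
    if (nxt$code != "S" || !identical(nxt$linkage, 8L) || nxt$branch) {
      unclassifiable("sialyl chain on %s is extended by %s%s, expected S8", where, nxt$code, nxt$linkage)
    }
    k <- k + 1L
    cur <- nxt
  }
  if (k > 3L) unclassifiable("sialyl chain of length %d on %s exceeds the maximum of 3", k, where)
  k
}

#' @export
format.core_info <- function(x, ...) {
  if (!x$classifiable) return(sprintf("<core_info> unclassifiable: %s", x$reason))
  sprintf(
    "<core_info> %s-based, n = %d (core number %s); sialylation I/II/III/IV = %d/%d/%d/%d",
    x$base_kind, x$n, ifelse(is.na(x$core_number), "-", x$core_number),
    x$sial_I, x$sial_II, x$sial_III, x$sial_IV
  )
}

#' @export
print.core_info <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
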