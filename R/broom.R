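#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a ganglioside network
#'
#' One row per structure with names and classification (the
#' [export_records()] table plus the seed row).
#'
#' @param x A `ganglio_network`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ganglio_network <- function(x, ...) {
  out <- glycan_names(x$nodes$identifier)
  out$generation <- x$nodes$generation
  out$is_seed <- out$identifier == x$seed
  dplyr::arrange(out, .data$generation, .data$identifier)
}

#' One-row summary of a ganglioside network
#'
#' @param x A `ganglio_network`.
#' @param ... Unused.
#' @return A tibble with `n_structures` (seed excluded), `n_reactions`,
#'   `iterations_run`, `truncated`, `n_enzymes_used`.
#' @export
glance.ganglio_network <- function(x, ...) {
  tibble(
    n_structures = nrow(x$nodes) - sum(x$nodes$identifier == x$seed),
    n_reactions = nrow(x$edges),
    iterations_run = x$iterations_run,
    truncated = x$truncated,
    n_enzymes_used = length(unique(x$edges$enzyme))
  )
}
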