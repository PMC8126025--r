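#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a localization result
#'
#' @param x An `ffe_localization` object.
#' @param ... Unused.
#' @return The per-protein calls tibble: assignment, best score, margin,
#'   population count, dual and discordance flags.
#' @export
tidy.ffe_localization <- function(x, ...) {
  as_tibble(x$calls)
}

#' One-row summary of a localization result
#'
#' @param x An `ffe_localization` object.
#' @param ... Unused.
#' @return A one-row tibble with protein, compartment, assignment, dual and
#'   discordance counts.
#' @export
glance.ffe_localization <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$calls),
    n_compartments = dplyr::n_distinct(x$consensus$compartment),
    n_assigned = sum(x$calls$assigned != "unassigned"),
    n_unassigned = sum(x$calls$assigned == "unassigned"),
    n_dual = sum(x$calls$dual_flag),
    n_discordant = sum(x$calls$discordant),
    median_best_score = median(x$calls$best_score, na.rm = TRUE)
  )
}
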