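# Digital-western rendering: per-protein bar profiles across the analysis
# window, with compartment characteristic windows shaded.

#' Plot digital-western profiles
#'
#' Bar profile of relative abundance across the analysis window for one or
#' more proteins, one panel per protein — the plot read like a western blot
#' across FFE fractions. Compartment characteristic windows can be shaded
#' behind the bars for orientation.
#'
#' @param westerns Digital-western tibble ([digital_westerns()]).
#' @param proteins Character vector of protein IDs to draw; default all
#'   (use with care on large sets). Unknown IDs are skipped with a warning.
#' @param windows Optional [compartment_windows()] tibble to shade.
#' @param ncol Panels per row (default 1).
#' @return A ggplot object.
#' @export
plot_digital_western <- function(westerns, proteins = NULL, windows = NULL,
                                 ncol = 1L) {
  if (!is.null(proteins)) {
    unknown <- setdiff(proteins, unique(westerns$protein_id))
    if (length(unknown) > 0) {
      warn(paste0("unknown protein ID(s) skipped: ",
                  paste(unknown, collapse = ", ")))
    }
    westerns <- filter(westerns, .data$protein_id %in% proteins)
    if (nrow(westerns) == 0) abort_usage("no known protein IDs to plot")
  }
  p <- ggplot2::ggplot(westerns,
                       ggplot2::aes(x = .data$sample, y = .data$rel_abundance))
  if (!is.null(windows)) {
    p <- p + ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(xmin = .data$start_sample - 0.5,
                   xmax = .data$end_sample + 0.5,
                   fill = .data$compartment),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~protein_id, ncol = ncol, scales = "free_y") +
    ggplot2::labs(x = "FFE sample", y = "relative abundance",
                  fill = "compartment") +
    ggplot2::theme_minimal()
}

#' Plot compartment consensus profiles
#'
#' @param consensus Consensus tibble ([build_consensus()]).
#' @return A ggplot object, one panel per compartment.
#' @export
plot_consensus <- function(consensus) {
  ggplot2::ggplot(consensus,
                  ggplot2::aes(x = .data$sample, y = .data$consensus)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "FFE sample", y = "consensus relative abundance") +
    ggplot2::theme_minimal()
}

#' Plot a localization-category summary
#'
#' @param summary Tibble from [category_summary()].
#' @return A ggplot bar chart of category percentages.
#' @export
plot_category_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$category,
                                                  -.data$percent),
                               y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a localization result
#'
#' Draws the digital westerns of the requested proteins with the
#' compartment windows shaded.
#'
#' @param object An `ffe_localization` object.
#' @param westerns The digital-western tibble the object was built from.
#' @param proteins Protein IDs to draw.
#' @param ... Passed to [plot_digital_western()].
#' @return A ggplot object.
#' @export
autoplot.ffe_localization <- function(object, westerns, proteins, ...) {
  plot_digital_western(westerns, proteins = proteins,
                       windows = object$windows, ...)
}
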