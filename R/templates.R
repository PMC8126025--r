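#' Default compartment mobility templates
#'
#' Returns the per-compartment FFE mobility model used by the synthetic-data
#' generator: each subcellular compartment is described by one or two Gaussian
#' peaks on the pooled-sample axis (1--48). Peak centers follow the fraction
#' windows in which the corresponding marker proteins are observed:
#' tonoplast membranes run anodic (samples 13--19) with a smaller second
#' population at sample 24; the ER splits between samples 18--20 and 23--25;
#' Golgi, TGN, chloroplast-envelope and the main mitochondrial population all
#' sit in the 23--25 region; thylakoids add a distinct population at sample
#' 20; and the plasma membrane runs most cathodic, samples 24--30 with its
#' peak at 25. Peak widths and mixture weights are model parameters chosen so
#' that the eight templates are mutually distinguishable at marker grade.
#'
#' @return A tibble with columns `compartment`, `peak_center`, `peak_width`
#'   and `peak_weight`, one row per Gaussian component. Weights sum to 1
#'   within each compartment.
#' @export
#' @examples
#' compartment_templates()
compartment_templates <- function() {
  path <- system.file("extdata", "compartment_templates.tsv",
                      package = "ffeprof", mustWork = TRUE)
  tpl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_templates(tpl)
  tpl
}

validate_templates <- function(templates, n_samples = 48L) {
  req <- c("compartment", "peak_center", "peak_width", "peak_weight")
  missing_cols <- setdiff(req, names(templates))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("template table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(templates$peak_center < 1 | templates$peak_center > n_samples)) {
    abort(
      sprintf("template peak centers must lie in 1..%d", n_samples),
      class = "ffeprof_template_error"
    )
  }
  if (any(templates$peak_width <= 0)) {
    abort("template peak widths must be > 0", class = "ffeprof_template_error")
  }
  if (any(templates$peak_weight <= 0)) {
    abort("template peak weights must be > 0", class = "ffeprof_template_error")
  }
  wsum <- tapply(templates$peak_weight, templates$compartment, sum)
  if (any(abs(wsum - 1) > 1e-9)) {
    abort("template peak weights must sum to 1 within each compartment",
          class = "ffeprof_template_error")
  }
  invisible(templates)
}

# Discrete Gaussian bump evaluated at integer sample indices, renormalized to
# the given weight. width -> 0 degenerates to a point mass at round(center).
discrete_gauss <- function(center, width, weight, n_samples) {
  x <- seq_len(n_samples)
  if (width < 1e-8) {
    d <- as.numeric(x == round(center))
  } else {
    d <- exp(-(x - center)^2 / (2 * width^2))
  }
  weight * d / sum(d)
}

#' Noise-free abundance profile of a compartment template
#'
#' Evaluates the Gaussian mixture of a compartment template on the integer
#' pooled-sample grid and renormalizes to unit mass, giving the expected
#' (noise-free) shape of a protein resident in that compartment.
#'
#' @param templates Template tibble as returned by [compartment_templates()],
#'   or any tibble with the same columns (possibly for several compartments).
#' @param compartment Optional character vector restricting which
#'   compartments to evaluate; default all present.
#' @param n_samples Number of pooled samples on the axis (default 48).
#' @return A tibble with columns `compartment`, `sample` and `density`;
#'   `density` is non-negative and sums to 1 within each compartment.
#' @export
#' @examples
#' pm <- template_profile(compartment_templates(), "PM")
#' pm$sample[which.max(pm$density)]  # peak of abundance at sample 25
template_profile <- function(templates, compartment = NULL, n_samples = 48L) {
  validate_templates(templates, n_samples = n_samples)
  if (!is.null(compartment)) {
    unknown <- setdiff(compartment, templates$compartment)
    if (length(unknown) > 0) {
      abort(
        paste0("no template for compartment(s): ",
               paste(unknown, collapse = ", ")),
        class = "ffeprof_template_error"
      )
    }
    templates <- templates[templates$compartment %in% compartment, ]
  }
  templates %>%
    group_by(.data$compartment) %>%
    summarise(
      density = list(Reduce(`+`, purrr::pmap(
        list(.data$peak_center, .data$peak_width, .data$peak_weight),
        discrete_gauss, n_samples = n_samples
      ))),
      .groups = "drop"
    ) %>%
    mutate(density = purrr::map(.data$density, ~ .x / sum(.x))) %>%
    tidyr::unnest_longer("density", indices_to = "sample") %>%
    select("compartment", "sample", "density") %>%
    arrange(.data$compartment, .data$sample)
}
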