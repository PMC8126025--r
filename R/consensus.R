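# Compartment consensus profiles from curated marker proteins, plus a
# marker-coherence quality control.

marker_westerns <- function(westerns, markers) {
  hits <- markers %>%
    distinct(.data$gene, .data$compartment) %>%
    dplyr::inner_join(westerns, by = c(gene = "protein_id")) %>%
    filter(!.data$zero_profile)
  hits
}

#' Build compartment consensus profiles from markers
#'
#' For each compartment, takes the element-wise median of its detected
#' markers' unit-sum profiles and renormalizes to unit sum. The median (not
#' the mean) is used because curated marker lists contain documented
#' outliers — e.g. V-ATPase subunits whose profile sits almost entirely in
#' the cathodic population while the rest of the tonoplast set runs anodic —
#' and the consensus should not be dragged by them. Compartments with no
#' detected marker are omitted with a warning.
#'
#' @param westerns Digital-western tibble from [digital_westerns()].
#' @param markers Marker tibble (`gene`, `compartment`), e.g. from
#'   [read_marker_table()].
#' @param robust If `TRUE`, markers flagged as outliers by
#'   [marker_coherence()] (median pairwise correlation below
#'   `coherence_floor`) are excluded before taking the median. Default
#'   `FALSE`: curated lists are used as-is.
#' @param coherence_floor Pearson floor used when `robust = TRUE`
#'   (default 0.5).
#' @return Tibble with columns `compartment`, `sample`, `consensus` (unit
#'   sum within compartment) and `n_markers`.
#' @export
build_consensus <- function(westerns, markers, robust = FALSE,
                            coherence_floor = 0.5) {
  if (nrow(markers) == 0) {
    abort_config("marker set is empty; cannot build consensus profiles")
  }
  hits <- marker_westerns(westerns, markers)
  absent <- setdiff(unique(markers$compartment), unique(hits$compartment))
  if (length(absent) > 0) {
    warn(paste0("no detected markers for compartment(s): ",
                paste(absent, collapse = ", "), "; omitted"))
  }
  if (nrow(hits) == 0) {
    abort_config("no marker protein present in the profile set")
  }
  if (robust) {
    coh <- marker_coherence(westerns, markers, floor = coherence_floor)
    outliers <- unlist(coh$outliers)
    hits <- filter(hits, !(.data$gene %in% outliers))
  }
  hits %>%
    group_by(.data$compartment, .data$sample) %>%
    summarise(
      consensus = median(.data$rel_abundance),
      n_markers = dplyr::n(),
      .groups = "drop_last"
    ) %>%
    mutate(consensus = .data$consensus / sum(.data$consensus)) %>%
    ungroup() %>%
    arrange(.data$compartment, .data$sample)
}

#' Marker coherence quality control
#'
#' Reports, per compartment, the median and minimum pairwise Pearson
#' correlation among its detected markers' profiles, and lists markers whose
#' median correlation to the other markers of their compartment falls below
#' `floor`. Single-marker compartments have no pairwise structure and are
#' reported with `NA` coherence.
#'
#' @inheritParams build_consensus
#' @param floor Coherence floor below which a marker is listed as an outlier
#'   (default 0.5).
#' @return Tibble with columns `compartment`, `n_markers`, `median_r`,
#'   `min_r` and `outliers` (list column of gene IDs).
#' @export
marker_coherence <- function(westerns, markers, floor = 0.5) {
  hits <- marker_westerns(westerns, markers)
  hits %>%
    tidyr::nest(data = -"compartment") %>%
    mutate(stats = purrr::map(.data$data, function(d) {
      m <- d %>%
        tidyr::pivot_wider(id_cols = "sample", names_from = "gene",
                           values_from = "rel_abundance") %>%
        arrange(.data$sample) %>%
        select(-"sample") %>%
        as.matrix()
      ng <- ncol(m)
      if (ng < 2) {
        return(tibble(n_markers = ng, median_r = NA_real_,
                      min_r = NA_real_, outliers = list(character())))
      }
      r <- suppressWarnings(cor(m))
      off <- r[upper.tri(r)]
      # outliers are judged against the compartment's median profile, which
      # is robust to the outlier itself (unlike pairwise medians at n = 3)
      med_prof <- apply(m, 1, median)
      r_to_med <- suppressWarnings(as.vector(cor(m, med_prof)))
      tibble(
        n_markers = ng,
        median_r = median(off),
        min_r = min(off),
        outliers = list(colnames(m)[!is.na(r_to_med) & r_to_med < floor])
      )
    })) %>%
    select("compartment", "stats") %>%
    tidyr::unnest("stats") %>%
    arrange(.data$compartment)
}
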