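# Compartment assignment by profile correlation, one- vs two-population
# detection, dual-localization and annotation-discordance flags.

#' Score proteins against compartment consensus profiles
#'
#' Pearson correlation of each protein's unit-sum profile with each
#' compartment consensus over the shared analysis window. Correlation is
#' invariant to positive rescaling of the raw profile, so scores depend on
#' profile shape only. All-zero (or otherwise constant) profiles receive
#' `NA` scores and end up unassigned.
#'
#' @param westerns Digital-western tibble ([digital_westerns()]).
#' @param consensus Consensus tibble ([build_consensus()]).
#' @return Tibble with columns `protein_id`, `compartment`, `score`.
#' @export
score_proteins <- function(westerns, consensus) {
  w_samples <- sort(unique(westerns$sample))
  c_samples <- sort(unique(consensus$sample))
  if (!identical(w_samples, c_samples)) {
    abort_usage("profiles and consensus are on different analysis windows")
  }
  pm <- westerns %>%
    tidyr::pivot_wider(id_cols = "sample", names_from = "protein_id",
                       values_from = "rel_abundance") %>%
    arrange(.data$sample)
  cm <- consensus %>%
    tidyr::pivot_wider(id_cols = "sample", names_from = "compartment",
                       values_from = "consensus") %>%
    arrange(.data$sample)
  r <- suppressWarnings(cor(
    as.matrix(pm[, -1, drop = FALSE]),
    as.matrix(cm[, -1, drop = FALSE])
  ))
  as_tibble(r, rownames = "protein_id") %>%
    tidyr::pivot_longer(-"protein_id", names_to = "compartment",
                        values_to = "score") %>%
    arrange(.data$protein_id, .data$compartment)
}

#' Assign each protein to a compartment from its scores
#'
#' A protein is assigned to its best-scoring compartment when the best
#' Pearson score reaches `r_min` and leads the runner-up by at least
#' `margin_min`; otherwise it is `"unassigned"`. Exact score ties are never
#' broken arbitrarily: the protein is unassigned with `tie = TRUE`.
#'
#' @param scores Tibble from [score_proteins()].
#' @param r_min Minimum best score (default 0.8).
#' @param margin_min Minimum lead over the runner-up (default 0.1).
#' @return Tibble with columns `protein_id`, `assigned`, `best_compartment`,
#'   `best_score`, `margin`, `tie`.
#' @export
assign_compartments <- function(scores, r_min = 0.8, margin_min = 0.1) {
  scores %>%
    group_by(.data$protein_id) %>%
    summarise(
      best_compartment = if (all(is.na(.data$score))) NA_character_ else
        .data$compartment[which.max(.data$score)],
      best_score = if (all(is.na(.data$score))) NA_real_ else
        max(.data$score, na.rm = TRUE),
      second_score = if (sum(!is.na(.data$score)) < 2) NA_real_ else
        sort(.data$score, decreasing = TRUE)[2],
      .groups = "drop"
    ) %>%
    mutate(
      margin = .data$best_score - .data$second_score,
      tie = !is.na(.data$margin) & .data$margin == 0,
      assigned = case_when(
        is.na(.data$best_score) ~ "unassigned",
        .data$tie ~ "unassigned",
        .data$best_score < r_min ~ "unassigned",
        !is.na(.data$margin) & .data$margin < margin_min ~ "unassigned",
        TRUE ~ .data$best_compartment
      )
    ) %>%
    select("protein_id", "assigned", "best_compartment", "best_score",
           "margin", "tie")
}

# centered triangular (binomial-style) moving average: weights fall off
# linearly with distance, so 2-sample valleys between adjacent populations
# are not filled in the way a flat window would; edge windows renormalize
# over the available samples
smooth_profile <- function(x, width) {
  if (width %% 2 == 0) abort_usage("`smooth_width` must be odd")
  half <- (width - 1L) / 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    wts <- half + 1 - abs(idx - i)
    sum(x[idx] * wts) / sum(wts)
  }, numeric(1))
}

# local maxima of s (leftmost index of plateaus); boundaries count as -Inf
local_maxima <- function(s) {
  n <- length(s)
  prev <- c(-Inf, s[-n])
  nxt <- c(s[-1], -Inf)
  which(s > prev & s >= nxt)
}

# topographic prominence of peak i: on each side, find the running minimum
# until a strictly higher sample (or the edge); prominence is the height
# above the higher of the two side minima
peak_prominence <- function(s, peaks) {
  vapply(peaks, function(i) {
    side_min <- function(idx) {
      m <- s[i]
      for (j in idx) {
        if (s[j] > s[i]) return(m)
        m <- min(m, s[j])
      }
      m
    }
    left <- if (i > 1) side_min((i - 1):1) else s[i]
    right <- if (i < length(s)) side_min((i + 1):length(s)) else s[i]
    s[i] - max(left, right)
  }, numeric(1))
}

detect_populations_vec <- function(x, samples, smooth_width = 3L,
                                   prominence_frac = 0.10, mass_min = 0.15) {
  if (all(x == 0)) {
    return(tibble(peak_sample = integer(), mass = numeric()))
  }
  s <- smooth_profile(x, smooth_width)
  peaks <- local_maxima(s)
  prom <- peak_prominence(s, peaks)
  peaks <- peaks[prom >= prominence_frac * max(s)]
  if (length(peaks) == 0) {
    return(tibble(peak_sample = integer(), mass = numeric()))
  }
  peaks <- sort(peaks)
  # watershed boundaries: leftmost minimum of the smoothed profile between
  # consecutive retained peaks
  bounds <- integer(0)
  if (length(peaks) > 1) {
    bounds <- vapply(seq_len(length(peaks) - 1), function(j) {
      idx <- (peaks[j] + 1L):(peaks[j + 1L] - 1L)
      idx[which.min(s[idx])]
    }, integer(1))
  }
  # valley samples belong to neither basin (the watershed ridge), which
  # keeps the decomposition exactly symmetric under profile reversal
  lo <- c(1L, bounds + 1L)
  hi <- c(bounds - 1L, length(x))
  mass <- vapply(seq_along(peaks),
                 function(j) sum(x[lo[j]:hi[j]]), numeric(1))
  # report the raw within-basin maximum: smoothing is for segmentation only
  # and can displace narrow peaks by a sample
  peak_at <- vapply(seq_along(peaks), function(j) {
    idx <- lo[j]:hi[j]
    idx[which.max(x[idx])]
  }, integer(1))
  keep <- mass >= mass_min
  tibble(peak_sample = samples[peak_at[keep]], mass = mass[keep])
}

#' Detect abundance populations in digital-western profiles
#'
#' Identifies the distinct population(s) of each profile: the profile is
#' smoothed with a centered moving average, local maxima with topographic
#' prominence of at least `prominence_frac` of the smoothed global maximum
#' are retained, each retained peak receives the raw profile mass of its
#' watershed basin (delimited by, and excluding, the smoothed minima
#' between neighbouring peaks), its position is reported as the raw
#' within-basin maximum, and populations carrying less than `mass_min` of
#' the total mass are discarded. Populations are reported in sample order.
#'
#' @param westerns Digital-western tibble, or any tibble with columns
#'   `protein_id`, `sample` and `rel_abundance` (unit sum per protein).
#' @param smooth_width Odd moving-average width (default 3).
#' @param prominence_frac Minimum prominence as a fraction of the global
#'   maximum (default 0.10).
#' @param mass_min Minimum mass share of a reported population
#'   (default 0.15).
#' @return Tibble with columns `protein_id`, `peak_sample`, `mass`; mass
#'   shares per protein sum to at most 1. Proteins whose profile yields no
#'   qualifying population are absent from the result.
#' @export
detect_populations <- function(westerns, smooth_width = 3L,
                               prominence_frac = 0.10, mass_min = 0.15) {
  westerns %>%
    arrange(.data$protein_id, .data$sample) %>%
    tidyr::nest(data = -"protein_id") %>%
    mutate(pops = purrr::map(.data$data, function(d) {
      detect_populations_vec(d$rel_abundance, d$sample,
                             smooth_width = smooth_width,
                             prominence_frac = prominence_frac,
                             mass_min = mass_min)
    })) %>%
    select("protein_id", "pops") %>%
    tidyr::unnest("pops")
}

#' Characteristic sample windows of compartment consensus profiles
#'
#' A compartment's characteristic windows are the contiguous runs of
#' samples where its consensus exceeds half of its own maximum. Bimodal
#' compartments (e.g. tonoplast) contribute one window per population.
#'
#' @param consensus Consensus tibble from [build_consensus()].
#' @return Tibble with columns `compartment`, `window_id`, `start_sample`,
#'   `end_sample`.
#' @export
compartment_windows <- function(consensus) {
  consensus %>%
    arrange(.data$compartment, .data$sample) %>%
    group_by(.data$compartment) %>%
    mutate(above = .data$consensus > max(.data$consensus) / 2) %>%
    mutate(window_id = cumsum(.data$above & !dplyr::lag(.data$above,
                                                        default = FALSE))) %>%
    filter(.data$above) %>%
    group_by(.data$compartment, .data$window_id) %>%
    summarise(start_sample = min(.data$sample),
              end_sample = max(.data$sample), .groups = "drop")
}

in_windows <- function(peak, windows_c) {
  any(peak >= windows_c$start_sample & peak <= windows_c$end_sample)
}

#' Flag candidate dual-localized proteins
#'
#' Maps each detected population to the compartments whose characteristic
#' windows contain its peak, then asks whether the protein's best-matching
#' compartment can explain the full population pattern on its own: every
#' window-mapped population must sit within `pos_tol` samples of one of
#' that compartment's native populations, and the observed mass attributed
#' to each native population must not exceed the native mass share by more
#' than `excess_min`. A protein is flagged dual when at least two of its
#' populations map to compartment windows and its reference compartment
#' cannot account for them — the situation of, e.g., a V-ATPase subunit
#' present far beyond the tonoplast's native share in the Golgi window.
#' When no reference compartment is supplied for a protein, every
#' compartment covering one of its populations is tried and the protein is
#' flagged only if none explains the pattern. Populations outside every
#' compartment window are mapped to `"none"` (e.g. unbound soluble protein
#' running fully anodic) and do not count as dual evidence.
#'
#' @param populations Tibble from [detect_populations()].
#' @param windows Tibble from [compartment_windows()].
#' @param native_populations Populations of the consensus profiles
#'   themselves: [detect_populations()] applied to the consensus (with
#'   `protein_id` = compartment label renamed to `compartment`).
#' @param reference Optional tibble (`protein_id`, `compartment`) giving
#'   each protein's reference compartment to test against — normally the
#'   best-scoring compartment from [assign_compartments()].
#' @param excess_min Tolerated excess of observed over native mass share
#'   (default 0.10).
#' @param pos_tol Maximum distance, in samples, between an observed
#'   population and the native population accounting for it (default 2).
#' @return Tibble with one row per population: `protein_id`, `peak_sample`,
#'   `mass`, `mapped` (comma-joined compartments or `"none"`), and the
#'   per-protein `dual_flag` repeated on each row.
#' @export
flag_dual <- function(populations, windows, native_populations,
                      reference = NULL, excess_min = 0.10, pos_tol = 2L) {
  comps <- unique(windows$compartment)
  win_by_comp <- split(windows, windows$compartment)
  native_by_comp <- split(native_populations, native_populations$compartment)
  ref_of <- character(0)
  if (!is.null(reference)) {
    ref_of <- setNames(reference$compartment, reference$protein_id)
  }

  explained_by <- function(pops, comp) {
    nat <- native_by_comp[[comp]]
    if (is.null(nat) || nrow(nat) == 0) return(FALSE)
    dist <- vapply(pops$peak_sample, function(p) {
      min(abs(nat$peak_sample - p))
    }, numeric(1))
    if (any(dist > pos_tol)) return(FALSE)
    nearest <- vapply(pops$peak_sample, function(p) {
      which.min(abs(nat$peak_sample - p))
    }, integer(1))
    obs <- tapply(pops$mass, factor(nearest, levels = seq_len(nrow(nat))),
                  sum, default = 0)
    all(obs <= nat$mass + excess_min)
  }

  populations %>%
    tidyr::nest(pops = -"protein_id") %>%
    mutate(res = purrr::map2(.data$pops, .data$protein_id, function(d, id) {
      mapped <- purrr::map(d$peak_sample, function(p) {
        comps[vapply(comps, function(cc) in_windows(p, win_by_comp[[cc]]),
                     logical(1))]
      })
      d$mapped <- purrr::map_chr(mapped,
                                 ~ if (length(.x) == 0) "none"
                                   else paste(.x, collapse = ","))
      is_mapped <- d$mapped != "none"
      dual <- FALSE
      if (sum(is_mapped) >= 2) {
        dm <- d[is_mapped, ]
        ref <- ref_of[id]
        candidates <- if (!is.na(ref) && length(ref) == 1 && !is.null(ref)) {
          ref
        } else {
          unique(unlist(mapped[is_mapped]))
        }
        dual <- !any(vapply(candidates, explained_by, logical(1),
                            pops = dm))
      }
      d$dual_flag <- dual
      d
    })) %>%
    select("protein_id", "res") %>%
    tidyr::unnest("res") %>%
    select("protein_id", "peak_sample", "mass", "mapped", "dual_flag")
}

#' Flag disagreement between profile assignment and prior annotation
#'
#' Compares the profile-based assignment with the annotation table,
#' preferring the high-confidence marker (HCM) compartment over the
#' consensus prediction when both are present (a comma-separated consensus
#' entry counts as agreeing when it contains the assignment). Unassigned
#' and unannotated proteins are never flagged.
#'
#' @param assignments Tibble from [assign_compartments()] (or the calls of
#'   [localize_proteins()]), with columns `protein_id`, `assigned`.
#' @param annotation Annotation tibble from [read_annotation_table()].
#' @return `assignments` with added logical columns `annotated` and
#'   `discordant`, plus `annotation_compartment`.
#' @export
flag_discordant <- function(assignments, annotation) {
  ann <- annotation %>%
    mutate(
      annotation_compartment = dplyr::coalesce(
        dplyr::na_if(as.character(.data$hcm_compartment), ""),
        dplyr::na_if(as.character(.data$consensus_compartment), "")
      )
    ) %>%
    select("protein_id", "annotation_compartment")
  assignments %>%
    left_join(ann, by = "protein_id") %>%
    mutate(
      annotated = !is.na(.data$annotation_compartment),
      discordant = .data$annotated &
        .data$assigned != "unassigned" &
        !purrr::map2_lgl(
          .data$assigned, .data$annotation_compartment,
          ~ .x %in% strsplit(.y, ",", fixed = TRUE)[[1]]
        )
    )
}

#' Full localization analysis of a profile set
#'
#' Builds marker consensus profiles, scores and assigns every protein,
#' detects populations, flags candidate dual-localized proteins and (when
#' an annotation table is given) discordance with prior annotation.
#'
#' @param westerns Digital-western tibble from [digital_westerns()].
#' @param markers Marker tibble (`gene`, `compartment`).
#' @param annotation Optional annotation tibble.
#' @param r_min,margin_min Assignment thresholds (see
#'   [assign_compartments()]).
#' @param smooth_width,prominence_frac,mass_min Population-detection
#'   parameters (see [detect_populations()]).
#' @param excess_min Dual-flag mass tolerance (see [flag_dual()]).
#' @param robust,coherence_floor Marker handling (see [build_consensus()]).
#' @return An object of class `ffe_localization`: a list with `calls` (one
#'   row per protein), `scores`, `populations`, `consensus`, `windows`,
#'   `coherence` and `params`. Use [tidy()] for the calls and [glance()]
#'   for a one-row summary.
#' @export
#' @examples
#' sim <- simulate_ffe_run(sim_config(n_proteins_per_compartment = 4, seed = 2))
#' dw <- digital_westerns(sim$quant, sim$od280)
#' loc <- localize_proteins(dw, sim_marker_set(sim$truth))
#' glance(loc)
localize_proteins <- function(westerns, markers, annotation = NULL,
                              r_min = 0.8, margin_min = 0.1,
                              smooth_width = 3L, prominence_frac = 0.10,
                              mass_min = 0.15, excess_min = 0.10,
                              robust = FALSE, coherence_floor = 0.5) {
  consensus <- build_consensus(westerns, markers, robust = robust,
                               coherence_floor = coherence_floor)
  coherence <- marker_coherence(westerns, markers, floor = coherence_floor)
  windows <- compartment_windows(consensus)
  native <- consensus %>%
    rename(protein_id = "compartment", rel_abundance = "consensus") %>%
    detect_populations(smooth_width = smooth_width,
                       prominence_frac = prominence_frac,
                       mass_min = mass_min) %>%
    rename(compartment = "protein_id")

  scores <- score_proteins(westerns, consensus)
  assignments <- assign_compartments(scores, r_min = r_min,
                                     margin_min = margin_min)
  populations <- detect_populations(westerns, smooth_width = smooth_width,
                                    prominence_frac = prominence_frac,
                                    mass_min = mass_min)
  duals <- flag_dual(
    populations, windows, native,
    reference = assignments %>%
      filter(!is.na(.data$best_compartment)) %>%
      select("protein_id", compartment = "best_compartment"),
    excess_min = excess_min
  )

  calls <- assignments %>%
    left_join(
      duals %>%
        group_by(.data$protein_id) %>%
        summarise(n_populations = dplyr::n(),
                  dual_flag = .data$dual_flag[1], .groups = "drop"),
      by = "protein_id"
    ) %>%
    mutate(
      n_populations = tidyr::replace_na(.data$n_populations, 0L),
      dual_flag = tidyr::replace_na(.data$dual_flag, FALSE)
    )
  if (!is.null(annotation)) {
    calls <- flag_discordant(calls, annotation)
  } else {
    calls$annotated <- FALSE
    calls$discordant <- FALSE
    calls$annotation_compartment <- NA_character_
  }

  structure(
    list(
      calls = calls, scores = scores, populations = duals,
      consensus = consensus, windows = windows, coherence = coherence,
      params = list(r_min = r_min, margin_min = margin_min,
                    smooth_width = smooth_width,
                    prominence_frac = prominence_frac, mass_min = mass_min,
                    excess_min = excess_min, robust = robust,
                    coherence_floor = coherence_floor)
    ),
    class = "ffe_localization"
  )
}

#' @export
print.ffe_localization <- function(x, ...) {
  n <- nrow(x$calls)
  cat(sprintf("<ffe_localization> %d proteins, %d compartments\n",
              n, dplyr::n_distinct(x$consensus$compartment)))
  cat(sprintf("  assigned: %d  unassigned: %d  dual-flagged: %d  discordant: %d\n",
              sum(x$calls$assigned != "unassigned"),
              sum(x$calls$assigned == "unassigned"),
              sum(x$calls$dual_flag), sum(x$calls$discordant)))
  invisible(x)
}

#' Marker set drawn from simulation ground truth
#'
#' Selects the first `n_per_compartment` single-compartment proteins of each
#' compartment as markers, mirroring the role of curated marker lists when
#' analysing synthetic runs.
#'
#' @param truth Ground-truth tibble from [simulate_ffe_run()].
#' @param n_per_compartment Markers per compartment (default 3).
#' @return Tibble with columns `gene` and `compartment`.
#' @export
sim_marker_set <- function(truth, n_per_compartment = 3L) {
  truth %>%
    filter(is.na(.data$secondary)) %>%
    group_by(.data$primary) %>%
    dplyr::slice_head(n = n_per_compartment) %>%
    ungroup() %>%
    select(gene = "protein_id", compartment = "primary")
}

#' Recovery metrics against simulation ground truth
#'
#' @param loc An `ffe_localization` object.
#' @param truth Ground-truth tibble from [simulate_ffe_run()].
#' @return One-row tibble: `n_proteins`, `n_singleton`, `n_dual_planted`,
#'   `accuracy` (singleton proteins assigned to their true compartment;
#'   unassigned counts as incorrect), `unassigned_rate`,
#'   `population_count_match` (singletons whose detected population count
#'   equals their template peak count), `dual_sensitivity` (planted duals
#'   flagged) and `false_dual_rate` (singletons flagged).
#' @export
localization_metrics <- function(loc, truth) {
  j <- dplyr::inner_join(loc$calls, truth, by = "protein_id")
  singles <- filter(j, is.na(.data$secondary))
  duals <- filter(j, !is.na(.data$secondary))
  tibble(
    n_proteins = nrow(j),
    n_singleton = nrow(singles),
    n_dual_planted = nrow(duals),
    accuracy = mean(singles$assigned == singles$primary),
    unassigned_rate = mean(j$assigned == "unassigned"),
    population_count_match =
      mean(singles$n_populations == singles$n_template_peaks),
    dual_sensitivity = if (nrow(duals) > 0) mean(duals$dual_flag) else NA_real_,
    false_dual_rate = mean(singles$dual_flag)
  )
}
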