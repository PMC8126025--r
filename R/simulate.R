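#' Configuration for a synthetic FFE fractionation run
#'
#' Bundles and validates all parameters of the synthetic-data generator.
#' The generator emulates a 96-fraction free flow electrophoresis separation
#' of microsomal membranes quantified by SWATH-style peak areas: each protein
#' inherits the mobility profile of its compartment template, scaled by a
#' per-protein abundance factor, observed across biological replicates under
#' multiplicative lognormal noise, with sporadic non-detections reported as
#' zero.
#'
#' @param templates Compartment template tibble; default
#'   [compartment_templates()].
#' @param n_proteins_per_compartment Number of simulated proteins per
#'   compartment (default 10).
#' @param dual_fraction Proportion of each compartment's proteins planted
#'   with a second compartment (default 0).
#' @param mixture_weight Mass share of the secondary compartment in dual
#'   proteins (default 0.3).
#' @param min_dual_separation Minimum distance, in pooled samples, between
#'   the major peak centers of the two compartments of a planted dual
#'   protein (default 5); secondaries are drawn uniformly among eligible
#'   compartments.
#' @param n_replicates Number of biological replicates (default 3).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise, applied independently per protein x fraction x
#'   replicate cell (default 0.2).
#' @param missing_rate Probability that a cell is zeroed, emulating SWATH
#'   non-detection (default 0.02).
#' @param od280_window Inclusive fraction range with positive OD280
#'   (default `c(15, 70)`).
#' @param od280_noise_cv Coefficient of variation of lognormal noise on the
#'   OD280 trace inside the window (default 0.05).
#' @param abundance_log10_range Range of `log10` per-protein abundance
#'   factors, drawn log-uniformly (default `c(4, 6)`, i.e. two orders of
#'   magnitude).
#' @param seed Integer random seed; the same seed reproduces the run
#'   byte-identically.
#' @return A validated list of class `ffe_sim_config`.
#' @export
sim_config <- function(templates = compartment_templates(),
                       n_proteins_per_compartment = 10L,
                       dual_fraction = 0,
                       mixture_weight = 0.3,
                       min_dual_separation = 5,
                       n_replicates = 3L,
                       noise_cv = 0.2,
                       missing_rate = 0.02,
                       od280_window = c(15L, 70L),
                       od280_noise_cv = 0.05,
                       abundance_log10_range = c(4, 6),
                       seed = 1L) {
  validate_templates(templates)
  if (dual_fraction < 0 || dual_fraction > 1) {
    abort_config("`dual_fraction` must be in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    abort_config("`missing_rate` must be in [0, 1]")
  }
  if (noise_cv < 0) abort_config("`noise_cv` must be >= 0")
  if (od280_noise_cv < 0) abort_config("`od280_noise_cv` must be >= 0")
  if (n_replicates < 1) abort_config("`n_replicates` must be >= 1")
  if (mixture_weight <= 0 || mixture_weight >= 1) {
    abort_config("`mixture_weight` must be in (0, 1)")
  }
  if (length(od280_window) != 2 || od280_window[1] >= od280_window[2] ||
      od280_window[1] < 1 || od280_window[2] > 96) {
    abort_config("`od280_window` must be an increasing pair within 1..96")
  }
  structure(
    list(
      templates = templates,
      n_proteins_per_compartment = as.integer(n_proteins_per_compartment),
      dual_fraction = dual_fraction,
      mixture_weight = mixture_weight,
      min_dual_separation = min_dual_separation,
      n_replicates = as.integer(n_replicates),
      noise_cv = noise_cv,
      missing_rate = missing_rate,
      od280_window = as.integer(od280_window),
      od280_noise_cv = od280_noise_cv,
      abundance_log10_range = abundance_log10_range,
      seed = as.integer(seed)
    ),
    class = "ffe_sim_config"
  )
}

# Major peak center per compartment (highest weight; ties -> first listed).
template_major_centers <- function(templates) {
  templates %>%
    group_by(.data$compartment) %>%
    slice_max(.data$peak_weight, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("compartment", major_center = "peak_center")
}

#' Compartment pairs eligible for dual planting
#'
#' An ordered (primary, secondary) pair is eligible when the two
#' compartments' major peak centers are at least `min_separation` samples
#' apart and the dual protein is identifiable in principle: on the
#' noise-free mixture profile, the detected population pattern must not be
#' attributable to any single compartment template (same window and
#' native-mass test as [flag_dual()]), with the populations themselves
#' surviving strictened detection thresholds (`prominence_margin` times the
#' prominence floor, `mass_margin` above the mass floor), so that planted
#' evidence does not sit on the detection boundary. Pairs failing these
#' conditions — e.g. two compartments whose populations co-locate, or a
#' mixture that reproduces a third compartment's native two-population
#' shape — cannot be resolved by profile position and mass at all and are
#' not planted.
#'
#' @param templates Template tibble ([compartment_templates()]).
#' @param mixture_weight Secondary mass share (default 0.3).
#' @param min_separation Minimum distance between major peak centers
#'   (default 5 samples).
#' @param window Analysis-window samples the mixture is evaluated on
#'   (default 8:35).
#' @param mass_margin Required clearance above `mass_min` (default 0.03).
#' @param prominence_margin Multiplier on `prominence_frac` the noise-free
#'   populations must survive (default 1.5).
#' @param smooth_width,prominence_frac,mass_min,excess_min Population and
#'   explanation parameters, as in [detect_populations()] and
#'   [flag_dual()].
#' @return Tibble with columns `primary` and `secondary`.
#' @export
eligible_dual_pairs <- function(templates, mixture_weight = 0.3,
                                min_separation = 5, window = 8:35,
                                mass_margin = 0.03, prominence_margin = 1.5,
                                smooth_width = 3L,
                                prominence_frac = 0.10, mass_min = 0.15,
                                excess_min = 0.10) {
  profs <- template_profile(templates) %>%
    filter(.data$sample %in% window) %>%
    group_by(.data$compartment) %>%
    mutate(density = .data$density / sum(.data$density)) %>%
    ungroup()
  cons_like <- rename(profs, consensus = "density")
  windows <- compartment_windows(cons_like)
  native <- profs %>%
    rename(protein_id = "compartment", rel_abundance = "density") %>%
    detect_populations(smooth_width = smooth_width,
                       prominence_frac = prominence_frac,
                       mass_min = mass_min) %>%
    rename(compartment = "protein_id")
  pm <- profs %>%
    tidyr::pivot_wider(names_from = "compartment", values_from = "density") %>%
    arrange(.data$sample)
  samples <- pm$sample
  pmat <- as.matrix(pm[, -1, drop = FALSE])

  maj <- template_major_centers(templates)
  majc <- setNames(maj$major_center, maj$compartment)
  pairs <- tidyr::expand_grid(primary = maj$compartment,
                              secondary = maj$compartment) %>%
    filter(.data$primary != .data$secondary,
           abs(majc[.data$primary] - majc[.data$secondary]) >= min_separation)

  ok <- purrr::map2_lgl(pairs$primary, pairs$secondary, function(a, b) {
    mix <- (1 - mixture_weight) * pmat[, a] + mixture_weight * pmat[, b]
    pops <- detect_populations_vec(mix, samples,
                                   smooth_width = smooth_width,
                                   prominence_frac = prominence_frac,
                                   mass_min = mass_min)
    strict <- detect_populations_vec(
      mix, samples, smooth_width = smooth_width,
      prominence_frac = prominence_frac * prominence_margin,
      mass_min = mass_min + mass_margin
    )
    if (nrow(pops) < 2 || nrow(strict) < nrow(pops)) {
      return(FALSE)
    }
    pops$protein_id <- "mix"
    res <- flag_dual(pops, windows, native, excess_min = excess_min)
    res$dual_flag[1]
  })
  pairs[ok, ]
}

#' Simulate a synthetic FFE fractionation run
#'
#' Generates a complete 96-fraction experiment with known ground truth:
#' a quantification matrix (protein x fraction x replicate peak areas), an
#' OD280 trace positive exactly inside the configured fraction window, and a
#' ground-truth table recording every protein's compartment(s), mixture
#' weights and template peak positions. The OD280 trace is a trapezoid:
#' linear ramps over the first and last eight window fractions and a flat
#' plateau between, so OD normalization is exercised without reshaping
#' in-window profiles.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `ffe_sim` with elements `quant` (tibble:
#'   `protein_id`, `sample` = fraction 1--96, `replicate`, `peak_area`),
#'   `od280` (tibble: `fraction`, `od280`), `truth` (tibble: `protein_id`,
#'   `primary`, `secondary`, `weight_primary`, `weight_secondary`,
#'   `n_template_peaks`, `peak_samples`) and `config`.
#' @export
#' @examples
#' sim <- simulate_ffe_run(sim_config(n_proteins_per_compartment = 2, seed = 7))
#' dplyr::count(sim$truth, primary)
simulate_ffe_run <- function(config) {
  if (!inherits(config, "ffe_sim_config")) {
    abort_config("`config` must be created by sim_config()")
  }
  withr::with_seed(config$seed, simulate_ffe_run_impl(config))
}

simulate_ffe_run_impl <- function(config) {
  tpl <- config$templates
  comps <- unique(tpl$compartment)
  n_per <- config$n_proteins_per_compartment
  n_frac <- 96L
  n_pool <- 48L

  profiles <- template_profile(tpl, n_samples = n_pool)
  prof_mat <- profiles %>%
    tidyr::pivot_wider(names_from = "compartment", values_from = "density") %>%
    arrange(.data$sample)
  prof_mat <- as.matrix(prof_mat[, comps, drop = FALSE])

  peaks_of <- function(comp) {
    rows <- tpl[tpl$compartment == comp, ]
    round(rows$peak_center)
  }

  # ground truth -------------------------------------------------------------
  truth <- tidyr::expand_grid(compartment = comps, idx = seq_len(n_per)) %>%
    mutate(
      protein_id = sprintf("prot%04d", row_number()),
      primary = .data$compartment,
      secondary = NA_character_
    ) %>%
    select("protein_id", "primary", "secondary")

  n_dual_per <- round(config$dual_fraction * n_per)
  if (n_dual_per > 0) {
    partners <- eligible_dual_pairs(
      tpl, mixture_weight = config$mixture_weight,
      min_separation = config$min_dual_separation
    )
    for (comp in comps) {
      elig <- partners$secondary[partners$primary == comp]
      rows <- which(truth$primary == comp)[seq_len(n_dual_per)]
      if (length(elig) == 0) {
        warn(sprintf(
          "no dual partner at separation >= %s for compartment %s; skipped",
          config$min_dual_separation, comp
        ))
        next
      }
      truth$secondary[rows] <- sample(elig, n_dual_per, replace = TRUE)
    }
  }

  truth <- truth %>%
    mutate(
      weight_primary = if_else(is.na(.data$secondary), 1,
                               1 - config$mixture_weight),
      weight_secondary = if_else(is.na(.data$secondary), 0,
                                 config$mixture_weight),
      n_template_peaks = purrr::map2_int(
        .data$primary, .data$secondary,
        ~ length(peaks_of(.x)) + if (is.na(.y)) 0L else length(peaks_of(.y))
      ),
      peak_samples = purrr::map2_chr(
        .data$primary, .data$secondary,
        ~ paste(c(peaks_of(.x), if (!is.na(.y)) peaks_of(.y)), collapse = ",")
      )
    )

  n_prot <- nrow(truth)

  # expected pooled profile per protein (rows: pooled sample, cols: protein)
  pooled_expect <- prof_mat[, truth$primary, drop = FALSE] %*%
    diag(truth$weight_primary, n_prot)
  has_sec <- which(!is.na(truth$secondary))
  if (length(has_sec) > 0) {
    pooled_expect[, has_sec] <- pooled_expect[, has_sec] +
      prof_mat[, truth$secondary[has_sec], drop = FALSE] %*%
      diag(truth$weight_secondary[has_sec], length(has_sec))
  }

  abundance <- 10^runif(n_prot, config$abundance_log10_range[1],
                        config$abundance_log10_range[2])

  # fraction-level expansion: each pooled sample's mass splits over its two
  # member fractions with a uniform split, independently per cell
  n_rep <- config$n_replicates
  n_cells <- n_prot * n_pool * n_rep
  split <- runif(n_cells, 0.4, 0.6)

  grid <- tidyr::expand_grid(
    protein_id = truth$protein_id,
    pooled = seq_len(n_pool),
    replicate = seq_len(n_rep)
  )
  expect_cell <- pooled_expect[cbind(grid$pooled,
                                     match(grid$protein_id, truth$protein_id))] *
    abundance[match(grid$protein_id, truth$protein_id)]

  frac <- tibble(
    protein_id = rep(grid$protein_id, each = 2L),
    sample = as.integer(rep(2L * grid$pooled, each = 2L) - c(1L, 0L)),
    replicate = rep(grid$replicate, each = 2L),
    peak_area = rep(expect_cell, each = 2L) *
      as.vector(rbind(split, 1 - split))
  )

  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    frac$peak_area <- frac$peak_area *
      rlnorm(nrow(frac), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  if (config$missing_rate > 0) {
    frac$peak_area[runif(nrow(frac)) < config$missing_rate] <- 0
  }

  frac <- arrange(frac, .data$protein_id, .data$replicate, .data$sample)

  # OD280 trace: trapezoidal plateau, strictly positive exactly inside the
  # configured window
  w <- config$od280_window
  f <- seq_len(n_frac)
  ramp <- pmin(1, (f - (w[1] - 1)) / 8, ((w[2] + 1) - f) / 8)
  od <- 0.8 * pmax(0, ramp)
  inside <- f >= w[1] & f <= w[2]
  od[inside] <- pmax(od[inside], 0.8 / 8)  # keep edges strictly positive
  if (config$od280_noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$od280_noise_cv^2))
    od[inside] <- od[inside] *
      rlnorm(sum(inside), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  od280 <- tibble(fraction = f, od280 = od)

  structure(
    list(quant = frac, od280 = od280, truth = truth, config = config),
    class = "ffe_sim"
  )
}

#' @export
print.ffe_sim <- function(x, ...) {
  cat(sprintf(
    "<ffe_sim> %d proteins x 96 fractions x %d replicates (seed %d)\n",
    dplyr::n_distinct(x$quant$protein_id), x$config$n_replicates,
    x$config$seed
  ))
  cat(sprintf("  dual-localized proteins: %d\n", sum(!is.na(x$truth$secondary))))
  invisible(x)
}
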