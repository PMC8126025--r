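# From 96 raw FFE fractions to per-protein digital-western profiles:
# pool adjacent fractions, select the OD280-positive analysis window,
# normalize peak areas to per-sample protein amount, average replicates,
# and unit-normalize.

quant_sample_level <- function(quant) {
  lvl <- attr(quant, "sample_level")
  if (!is.null(lvl)) return(lvl)
  if (max(quant$sample) > 48) "fraction" else "pooled"
}

#' Pool adjacent FFE fractions into analysis samples
#'
#' Combines every `k` consecutive fractions by summation (pooled sample `s`
#' aggregates fractions `k(s-1)+1 ... ks`), emulating the physical pooling of
#' adjacent fractions: material adds, so per-protein, per-replicate total
#' signal is conserved exactly.
#'
#' @param quant Fraction-level quant matrix (columns `protein_id`, `sample`,
#'   `replicate`, `peak_area`; samples 1--96).
#' @param k Pooling width (default 2, giving 48 samples); must divide 96.
#' @return A pooled-level quant matrix tibble with `sample` in
#'   `1..96/k` and attribute `sample_level = "pooled"`.
#' @export
pool_fractions <- function(quant, k = 2L) {
  if (quant_sample_level(quant) != "fraction") {
    abort_usage("`quant` is not fraction-level; pooling applies to 96-fraction input")
  }
  if (96L %% k != 0) abort_usage("`k` must divide 96")
  if (max(quant$sample) > 96 || min(quant$sample) < 1) {
    abort_usage("fraction indices must lie in 1..96")
  }
  out <- quant %>%
    mutate(sample = as.integer(ceiling(.data$sample / k))) %>%
    group_by(.data$protein_id, .data$sample, .data$replicate) %>%
    summarise(peak_area = sum(.data$peak_area), .groups = "drop") %>%
    arrange(.data$protein_id, .data$replicate, .data$sample)
  attr(out, "sample_level") <- "pooled"
  out
}

#' Pool a per-fraction OD280 trace
#'
#' @param od280 Tibble with columns `fraction` (1--96) and `od280`.
#' @param k Pooling width (default 2); must divide 96.
#' @return Tibble with columns `sample` and `od280`, where pooled OD is the
#'   sum of member-fraction readings.
#' @export
pool_od280 <- function(od280, k = 2L) {
  if (96L %% k != 0) abort_usage("`k` must divide 96")
  od280 %>%
    mutate(sample = as.integer(ceiling(.data$fraction / k))) %>%
    group_by(.data$sample) %>%
    summarise(od280 = sum(.data$od280), .groups = "drop") %>%
    arrange(.data$sample)
}

#' Select the analysis window from a pooled OD280 trace
#'
#' Returns the largest contiguous run of pooled samples whose OD280 exceeds
#' `threshold` (strictly), the range of samples carrying measurable protein.
#' Ties between equally long runs resolve to the leftmost (most anodic) run.
#'
#' @param pooled_od Tibble with columns `sample` and `od280`.
#' @param threshold Strict lower bound on OD280 (default 0).
#' @return An integer vector of consecutive sample indices (inclusive range).
#' @export
#' @examples
#' od <- tibble::tibble(fraction = 1:96,
#'                      od280 = ifelse(dplyr::between(1:96, 15, 70), 0.5, 0))
#' select_analysis_window(pool_od280(od))  # samples 8..35
select_analysis_window <- function(pooled_od, threshold = 0) {
  pooled_od <- arrange(pooled_od, .data$sample)
  pos <- pooled_od$od280 > threshold
  if (!any(pos)) {
    abort("no samples with OD280 above threshold; empty analysis window",
          class = "ffeprof_empty_window_error")
  }
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pos_runs <- which(runs$values)
  best <- pos_runs[which.max(runs$lengths[pos_runs])]
  pooled_od$sample[starts[best]]:pooled_od$sample[ends[best]]
}

#' Normalize pooled peak areas to per-sample OD280
#'
#' Divides each (protein, sample, replicate) peak area by the pooled OD280 of
#' its sample — converting raw signal to abundance per unit protein — and
#' restricts the matrix to the analysis window.
#'
#' @param pooled_quant Pooled-level quant matrix.
#' @param pooled_od Pooled OD280 tibble (`sample`, `od280`).
#' @param window Integer vector of analysis-window samples, e.g. from
#'   [select_analysis_window()].
#' @return A normalized quant matrix restricted to `window`.
#' @export
normalize_to_od280 <- function(pooled_quant, pooled_od, window) {
  od_in <- pooled_od[pooled_od$sample %in% window, ]
  if (length(setdiff(window, pooled_od$sample)) > 0) {
    abort_usage("`window` contains samples absent from the OD280 trace")
  }
  if (any(od_in$od280 <= 0)) {
    abort_integrity("OD280 must be strictly positive inside the analysis window")
  }
  pooled_quant %>%
    filter(.data$sample %in% window) %>%
    left_join(od_in, by = "sample") %>%
    mutate(peak_area = .data$peak_area / .data$od280) %>%
    select(-"od280")
}

#' Average biological replicates
#'
#' Arithmetic mean and standard deviation per (protein, sample) over all
#' replicates. Zero (non-detected) cells are included in the mean rather
#' than dropped — dropping would bias two-population profiles toward the
#' better-covered population. Replicates in which a protein is entirely
#' undetected are counted and reported as a low-coverage message.
#'
#' @param quant Quant matrix (any level), complete over its grid.
#' @return Tibble with columns `protein_id`, `sample`, `mean_area`,
#'   `sd_area` and `n_replicates`.
#' @export
average_replicates <- function(quant) {
  zero_reps <- quant %>%
    group_by(.data$protein_id, .data$replicate) %>%
    summarise(all_zero = all(.data$peak_area == 0), .groups = "drop") %>%
    filter(.data$all_zero)
  if (nrow(zero_reps) > 0) {
    inform(sprintf(
      "%d protein x replicate combinations entirely undetected (mean still taken over all replicates)",
      nrow(zero_reps)
    ))
  }
  quant %>%
    group_by(.data$protein_id, .data$sample) %>%
    summarise(
      mean_area = mean(.data$peak_area),
      sd_area = if (dplyr::n() > 1) sd(.data$peak_area) else 0,
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$protein_id, .data$sample)
}

#' Scale per-protein profiles to unit sum
#'
#' Rescales each protein's averaged profile so it sums to 1, putting all
#' proteins on a common shape scale regardless of absolute abundance.
#' All-zero profiles pass through unchanged and are flagged in the
#' `zero_profile` column.
#'
#' @param profiles Tibble with columns `protein_id`, `sample`, `mean_area`
#'   (other columns preserved).
#' @return The input with added columns `rel_abundance` and `zero_profile`.
#' @export
unit_normalize <- function(profiles) {
  profiles %>%
    group_by(.data$protein_id) %>%
    mutate(
      zero_profile = sum(.data$mean_area) == 0,
      rel_abundance = if_else(.data$zero_profile, 0,
                              .data$mean_area / sum(.data$mean_area))
    ) %>%
    ungroup()
}

#' Build digital-western profiles from a raw run
#'
#' Runs the full preprocessing chain: pool fractions (when the input is at
#' fraction level), pool the OD280 trace, select or accept the analysis
#' window, normalize to OD280, average replicates, and unit-normalize,
#' yielding one replicate-averaged, OD-normalized, unit-sum profile per
#' protein over the analysis window — the "digital western" read like an
#' antibody blot across FFE fractions.
#'
#' @param quant Quant matrix tibble (fraction- or pooled-level).
#' @param od280 Per-fraction OD280 tibble (`fraction`, `od280`), or an
#'   already pooled trace (`sample`, `od280`).
#' @param k Pooling width (default 2).
#' @param window Optional explicit analysis window (integer samples);
#'   default recomputed from the pooled OD280 trace.
#' @return Tibble of class `ffe_westerns`: `protein_id`, `sample`,
#'   `rel_abundance`, `mean_area`, `sd_area`, `zero_profile`, with the
#'   window stored in attribute `window`.
#' @export
#' @examples
#' sim <- simulate_ffe_run(sim_config(n_proteins_per_compartment = 2, seed = 1))
#' dw <- digital_westerns(sim$quant, sim$od280)
#' range(dw$sample)
digital_westerns <- function(quant, od280, k = 2L, window = NULL) {
  if (quant_sample_level(quant) == "fraction") {
    quant <- pool_fractions(quant, k = k)
  }
  if ("fraction" %in% names(od280)) {
    pod <- pool_od280(od280, k = k)
  } else {
    pod <- od280
  }
  if (is.null(window)) {
    window <- select_analysis_window(pod)
  }
  out <- quant %>%
    normalize_to_od280(pod, window) %>%
    average_replicates() %>%
    unit_normalize() %>%
    select("protein_id", "sample", "rel_abundance", "mean_area",
           "sd_area", "zero_profile")
  attr(out, "window") <- window
  class(out) <- c("ffe_westerns", class(out))
  out
}
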