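# Readers and writers for the pipeline's tabular artifacts. All files are
# tab-separated UTF-8 with '#' comment lines; readers validate their schema
# and raise typed errors (ffeprof_schema_error / ffeprof_integrity_error)
# rather than silently coercing.

read_checked_tsv <- function(path, col_types, what) {
  if (!file.exists(path)) {
    abort_usage(sprintf("%s file not found: %s", what, path))
  }
  x <- suppressWarnings(
    readr::read_tsv(path, comment = "#", col_types = col_types,
                    progress = FALSE)
  )
  missing_cols <- setdiff(names(col_types$cols), names(x))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "%s file %s is missing column(s): %s",
      what, path, paste(missing_cols, collapse = ", ")
    ))
  }
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort_schema(sprintf(
      "%s file %s has malformed values at line(s): %s",
      what, path, paste(unique(probs$row), collapse = ", ")
    ))
  }
  x
}

#' Read a protein quantification matrix
#'
#' Reads a long-format TSV of SWATH-style peak areas with columns
#' `protein_id`, `sample`, `replicate`, `peak_area`. The sample axis may be
#' at fraction level (1--96) or pooled level (1--48); the level is
#' auto-detected from the axis range and recorded in the `sample_level`
#' attribute, or set explicitly via `level` when the range is ambiguous
#' (all samples within 1--48 could be either). Absent
#' (protein, sample, replicate) combinations are materialized as zero peak
#' areas, matching SWATH non-detection semantics; the number of filled cells
#' is reported as a message.
#'
#' @param path Path to a TSV file.
#' @param level `"auto"` (default), `"fraction"` or `"pooled"`.
#' @return A tibble with the four columns above, complete over the observed
#'   protein x sample x replicate grid, with attribute `sample_level`.
#' @export
read_quant_matrix <- function(path, level = c("auto", "fraction", "pooled")) {
  level <- match.arg(level)
  x <- read_checked_tsv(
    path,
    readr::cols(
      protein_id = readr::col_character(),
      sample = readr::col_integer(),
      replicate = readr::col_integer(),
      peak_area = readr::col_double()
    ),
    "quant matrix"
  )
  validate_quant_matrix(x, path = path)
  detected <- if (max(x$sample) > 48) "fraction" else "pooled"
  if (level == "auto") {
    if (detected == "pooled" && max(x$sample) <= 48 && min(x$sample) >= 1) {
      inform(sprintf(
        "sample axis spans %d..%d; treating as %s-level (override with `level`)",
        min(x$sample), max(x$sample), detected
      ))
    }
    level <- detected
  } else if (level == "pooled" && detected == "fraction") {
    abort_usage("samples exceed 48; file cannot be pooled-level")
  }
  x <- complete_quant_grid(x)
  attr(x, "sample_level") <- level
  x
}

validate_quant_matrix <- function(x, path = "<quant>") {
  if (any(!is.finite(x$peak_area))) {
    bad <- which(!is.finite(x$peak_area))
    abort_schema(sprintf("%s has non-finite peak_area at data row(s): %s",
                         path, paste(head(bad, 5), collapse = ", ")))
  }
  if (any(x$peak_area < 0)) {
    bad <- which(x$peak_area < 0)
    abort_integrity(sprintf(
      "%s has negative peak_area at data row(s): %s",
      path, paste(head(bad, 5), collapse = ", ")
    ))
  }
  dup <- duplicated(x[c("protein_id", "sample", "replicate")])
  if (any(dup)) {
    abort_integrity(sprintf(
      "%s has duplicate (protein_id, sample, replicate) at data row(s): %s",
      path, paste(head(which(dup), 5), collapse = ", ")
    ))
  }
  samp <- sort(unique(x$sample))
  if (length(samp) > 0 && !identical(samp, seq(min(samp), max(samp)))) {
    abort_integrity(sprintf("%s sample axis is not contiguous", path))
  }
  invisible(x)
}

complete_quant_grid <- function(x) {
  before <- nrow(x)
  x <- tidyr::complete(
    x,
    .data$protein_id,
    sample = tidyr::full_seq(.data$sample, 1),
    .data$replicate,
    fill = list(peak_area = 0)
  ) %>%
    mutate(sample = as.integer(.data$sample)) %>%
    arrange(.data$protein_id, .data$replicate, .data$sample)
  filled <- nrow(x) - before
  if (filled > 0) {
    inform(sprintf("filled %d absent cells with peak_area 0", filled))
  }
  x
}

#' Read a per-fraction OD280 trace
#'
#' @param path TSV with columns `fraction` (1--96, complete and unique) and
#'   `od280` (non-negative absorbance).
#' @return A tibble with 96 rows.
#' @export
read_od280 <- function(path) {
  x <- read_checked_tsv(
    path,
    readr::cols(fraction = readr::col_integer(),
                od280 = readr::col_double()),
    "OD280"
  )
  if (nrow(x) != 96 || !identical(sort(x$fraction), 1:96)) {
    abort_integrity(sprintf(
      "%s must contain exactly fractions 1..96 (found %d rows)", path, nrow(x)
    ))
  }
  if (any(!is.finite(x$od280)) || any(x$od280 < 0)) {
    abort_integrity(sprintf("%s has negative or non-finite od280 values", path))
  }
  arrange(x, .data$fraction)
}

#' Read a marker table
#'
#' Markers are well-characterized proteins whose FFE profile anchors a
#' compartment. Each protein must appear under exactly one compartment
#' (repeats across source tables are allowed), and compartment labels must
#' come from the controlled vocabulary TP, ER, GA, TGN, Chl-envelope, TLK,
#' MT, PM.
#'
#' @param path TSV with columns `gene`, `compartment` and optionally
#'   `source_table`.
#' @return A tibble of marker entries.
#' @export
#' @examples
#' markers <- read_marker_table(ffe_marker_fixture())
#' dplyr::count(markers, compartment)
read_marker_table <- function(path) {
  x <- read_checked_tsv(
    path,
    readr::cols(gene = readr::col_character(),
                compartment = readr::col_character()),
    "marker table"
  )
  bad <- setdiff(unique(x$compartment), ffe_compartments)
  if (length(bad) > 0) {
    abort_integrity(sprintf(
      "%s has compartment label(s) outside the controlled vocabulary: %s",
      path, paste(bad, collapse = ", ")
    ))
  }
  multi <- x %>%
    distinct(.data$gene, .data$compartment) %>%
    count(.data$gene) %>%
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort_integrity(sprintf(
      "%s lists protein(s) under more than one compartment: %s",
      path, paste(multi$gene, collapse = ", ")
    ))
  }
  x
}

#' Path to the packaged marker fixture
#'
#' The curated marker list (tonoplast, ER, Golgi, TGN, chloroplast
#' envelope, thylakoid, mitochondria and plasma membrane markers) shipped
#' with the package.
#'
#' @param which `"markers"` (default) for the marker list, or
#'   `"unexpected"` for the list of PM-annotated proteins with anodic
#'   (tonoplast-overlapping) profiles.
#' @return A file path.
#' @export
ffe_marker_fixture <- function(which = c("markers", "unexpected")) {
  which <- match.arg(which)
  fname <- switch(which,
                  markers = "markers_tables1-6.tsv",
                  unexpected = "unexpected_table7.tsv")
  system.file("extdata", fname, package = "ffeprof", mustWork = TRUE)
}

#' Read a protein annotation table
#'
#' Maps protein IDs to an ortholog accession (AGI), a high-confidence marker
#' (HCM) compartment where available, and a consensus-prediction compartment
#' (possibly several, comma-separated). Empty strings are read as missing.
#'
#' @param path TSV with columns `protein_id`, `agi`, `hcm_compartment`,
#'   `consensus_compartment`.
#' @return A tibble, one row per protein.
#' @export
read_annotation_table <- function(path) {
  x <- read_checked_tsv(
    path,
    readr::cols(
      protein_id = readr::col_character(),
      agi = readr::col_character(),
      hcm_compartment = readr::col_character(),
      consensus_compartment = readr::col_character()
    ),
    "annotation table"
  )
  if (any(duplicated(x$protein_id))) {
    abort_integrity(sprintf("%s has duplicate protein_id entries", path))
  }
  has_agi <- !is.na(x$agi) & x$agi != ""
  bad <- has_agi & !grepl("^At[1-5CM]g\\d{5}$", x$agi)
  if (any(bad)) {
    abort_integrity(sprintf(
      "%s has malformed AGI accession(s): %s",
      path, paste(head(x$agi[bad], 5), collapse = ", ")
    ))
  }
  x
}

#' Read a transmembrane-domain prediction table
#'
#' One row per protein with the predicted TMD count from each prediction
#' program (two helix predictors and two beta-barrel predictors in the
#' standard layout). Missing counts are treated as 0.
#'
#' @param path TSV with column `protein_id` plus one integer column per
#'   program.
#' @return A tibble with NA counts replaced by 0.
#' @export
read_tm_table <- function(path) {
  x <- read_checked_tsv(
    path, readr::cols(protein_id = readr::col_character(),
                      .default = readr::col_integer()),
    "TM table"
  )
  prog <- setdiff(names(x), "protein_id")
  if (length(prog) == 0) {
    abort_schema(sprintf("%s has no prediction-program columns", path))
  }
  if (any(duplicated(x$protein_id))) {
    abort_integrity(sprintf("%s has duplicate protein_id entries", path))
  }
  x <- mutate(x, across(dplyr::all_of(prog), ~ tidyr::replace_na(.x, 0L)))
  if (any(purrr::map_lgl(x[prog], ~ any(.x < 0)))) {
    abort_integrity(sprintf("%s has negative TMD counts", path))
  }
  x
}

# writers --------------------------------------------------------------------

write_commented_tsv <- function(x, path, comments = character()) {
  if (length(comments) > 0) {
    writeLines(paste0("# ", comments), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a quantification matrix to TSV
#'
#' @param x Quant matrix tibble.
#' @param path Output path.
#' @param comments Optional character vector of header comment lines
#'   (written prefixed with `#`).
#' @return The path, invisibly.
#' @export
write_quant_matrix <- function(x, path, comments = character()) {
  validate_quant_matrix(x)
  write_commented_tsv(x, path, comments)
}

#' Write a simulated run to a directory
#'
#' Emits `quant.tsv`, `od280.tsv` and `ground_truth.tsv`, each with the
#' generator seed recorded in a header comment, so a run is reproducible
#' from its outputs alone.
#'
#' @param sim An `ffe_sim` object from [simulate_ffe_run()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ffe_run <- function(sim, dir) {
  if (!inherits(sim, "ffe_sim")) abort_usage("`sim` must be an ffe_sim object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_note <- sprintf("seed: %d", sim$config$seed)
  write_commented_tsv(sim$quant, file.path(dir, "quant.tsv"),
                      c("synthetic FFE quantification matrix", seed_note))
  write_commented_tsv(sim$od280, file.path(dir, "od280.tsv"),
                      c("synthetic OD280 trace", seed_note))
  write_commented_tsv(sim$truth, file.path(dir, "ground_truth.tsv"),
                      c("synthetic ground truth", seed_note))
  invisible(dir)
}

#' Write a localization report
#'
#' One row per protein with its per-compartment correlation scores, assigned
#' compartment, detected population count and peaks, and flags, in a
#' deterministic column order.
#'
#' @param loc An `ffe_localization` object from [localize_proteins()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_localization_report <- function(loc, path) {
  if (!inherits(loc, "ffe_localization")) {
    abort_usage("`loc` must come from localize_proteins()")
  }
  wide_scores <- loc$scores %>%
    tidyr::pivot_wider(names_from = "compartment", values_from = "score",
                       names_prefix = "score_")
  pops <- loc$populations %>%
    group_by(.data$protein_id) %>%
    summarise(
      peak_samples = paste(.data$peak_sample, collapse = ";"),
      peak_masses = paste(signif(.data$mass, 4), collapse = ";"),
      .groups = "drop"
    )
  out <- loc$calls %>%
    left_join(wide_scores, by = "protein_id") %>%
    left_join(pops, by = "protein_id") %>%
    mutate(
      peak_samples = tidyr::replace_na(.data$peak_samples, ""),
      peak_masses = tidyr::replace_na(.data$peak_masses, "")
    ) %>%
    arrange(.data$protein_id)
  write_commented_tsv(out, path, "per-protein localization report")
}
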