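# Transmembrane-domain consensus rule and localization-category summaries.

#' Transmembrane consensus classification
#'
#' A protein is classified as an integral membrane protein when any of the
#' prediction programs reports at least one transmembrane domain; proteins
#' with no predicted TMD from any program are considered peripheral or
#' membrane-associated.
#'
#' @param tm TM-prediction tibble ([read_tm_table()]): `protein_id` plus one
#'   count column per program. `NA` counts are treated as 0.
#' @return The input with added columns `max_tmd` and `is_membrane`.
#' @export
#' @examples
#' tm <- tibble::tibble(protein_id = c("a", "b"),
#'                      hmmtop = c(1L, 0L), tmhmm = c(0L, 0L),
#'                      mcmbb = c(0L, 0L), tmbetadisc = c(0L, 0L))
#' tm_consensus(tm)$is_membrane
tm_consensus <- function(tm) {
  prog <- setdiff(names(tm), c("protein_id", "max_tmd", "is_membrane"))
  if (length(prog) == 0) abort_schema("no prediction-program columns in `tm`")
  counts <- as.matrix(mutate(tm[prog],
                             across(dplyr::everything(),
                                    ~ tidyr::replace_na(as.integer(.x), 0L))))
  if (any(counts < 0)) abort_integrity("TMD counts must be >= 0")
  tm %>%
    mutate(
      max_tmd = apply(counts, 1, max),
      is_membrane = .data$max_tmd >= 1L
    )
}

#' Summary of the membrane / peripheral split
#'
#' @param tmc Output of [tm_consensus()].
#' @return One-row tibble: `n_proteins`, `n_membrane`, `membrane_fraction`.
#' @export
tm_summary <- function(tmc) {
  tibble(
    n_proteins = nrow(tmc),
    n_membrane = sum(tmc$is_membrane),
    membrane_fraction = mean(tmc$is_membrane)
  )
}

#' Histogram of predicted TMD counts for one program
#'
#' @param tm TM-prediction tibble.
#' @param program Name of the program column.
#' @return Tibble with columns `tmd` (0..max observed) and `n`; bin counts
#'   sum to the number of proteins.
#' @export
tmd_histogram <- function(tm, program) {
  if (!program %in% names(tm)) {
    abort_usage(sprintf("no column `%s` in the TM table", program))
  }
  x <- tidyr::replace_na(as.integer(tm[[program]]), 0L)
  if (length(x) == 0) {
    return(tibble(tmd = integer(), n = integer()))
  }
  tibble(tmd = x) %>%
    count(.data$tmd) %>%
    tidyr::complete(tmd = 0:max(x), fill = list(n = 0L)) %>%
    arrange(.data$tmd)
}

#' Localization-category percentages from an annotation table
#'
#' Percentage of distinct proteins per annotated compartment, in either
#' high-confidence-marker (`"hcm"`) or consensus-prediction
#' (`"consensus"`) mode. Unannotated proteins fall into an `"unassigned"`
#' bucket; in consensus mode, proteins predicted in several locations are
#' counted once under `"multiple"`.
#'
#' @param annotation Annotation tibble ([read_annotation_table()]).
#' @param mode `"hcm"` or `"consensus"`.
#' @return Tibble with columns `category`, `n` and `percent`; percentages
#'   sum to 100.
#' @export
category_summary <- function(annotation, mode = c("hcm", "consensus")) {
  mode <- match.arg(mode)
  col <- if (mode == "hcm") "hcm_compartment" else "consensus_compartment"
  x <- annotation %>%
    distinct(.data$protein_id, .keep_all = TRUE) %>%
    mutate(
      raw = dplyr::na_if(as.character(.data[[col]]), ""),
      category = case_when(
        is.na(.data$raw) ~ "unassigned",
        grepl(",", .data$raw, fixed = TRUE) ~ "multiple",
        TRUE ~ .data$raw
      )
    )
  x %>%
    count(.data$category) %>%
    mutate(percent = 100 * .data$n / sum(.data$n)) %>%
    arrange(dplyr::desc(.data$n))
}
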