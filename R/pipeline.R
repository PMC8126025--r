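#' Run the full membrane-profiling pipeline
#'
#' Orchestrates the whole analysis: preprocessing into digital westerns,
#' marker consensus construction, compartment assignment, population and
#' dual-localization detection, optional annotation discordance and
#' transmembrane/category summaries, and (optionally) writing the standard
#' set of report files to a directory.
#'
#' @param quant Quant matrix tibble or path to a quant TSV.
#' @param od280 OD280 tibble or path to an OD280 TSV.
#' @param markers Marker tibble or path; default the packaged marker
#'   fixture.
#' @param annotation Optional annotation tibble or path.
#' @param tm Optional TM-prediction tibble or path.
#' @param truth Optional ground-truth tibble (for synthetic runs); when
#'   given, recovery metrics are computed.
#' @param out_dir Optional output directory; when given, writes
#'   `localization.tsv`, `consensus_profiles.tsv`, `populations.tsv`,
#'   `tm_summary.tsv`, `category_summary.tsv`, `metrics.json` and
#'   `run.log`.
#' @param k Pooling width (default 2).
#' @param window Optional explicit analysis window.
#' @param ... Localization parameters passed to [localize_proteins()].
#' @return A list with elements `westerns`, `localization`, `tm`,
#'   `categories` and `metrics` (each `NULL` when its input is absent),
#'   invisibly when `out_dir` is given.
#' @export
run_ffe_pipeline <- function(quant, od280, markers = ffe_marker_fixture(),
                             annotation = NULL, tm = NULL, truth = NULL,
                             out_dir = NULL, k = 2L, window = NULL, ...) {
  if (is.character(quant)) quant <- read_quant_matrix(quant)
  if (is.character(od280)) od280 <- read_od280(od280)
  if (is.character(markers)) markers <- read_marker_table(markers)
  if (is.character(annotation)) annotation <- read_annotation_table(annotation)
  if (is.character(tm)) tm <- read_tm_table(tm)

  dw <- digital_westerns(quant, od280, k = k, window = window)
  loc <- localize_proteins(dw, markers, annotation = annotation, ...)

  tmc <- NULL
  tms <- NULL
  if (!is.null(tm)) {
    tmc <- tm_consensus(tm)
    tms <- tm_summary(tmc)
  }
  cats <- NULL
  if (!is.null(annotation)) {
    cats <- list(hcm = category_summary(annotation, "hcm"),
                 consensus = category_summary(annotation, "consensus"))
  }
  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- localization_metrics(loc, truth)
  }

  result <- list(westerns = dw, localization = loc, tm = tmc,
                 tm_summary = tms, categories = cats, metrics = metrics)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_localization_report(loc, file.path(out_dir, "localization.tsv"))
    write_commented_tsv(loc$consensus,
                        file.path(out_dir, "consensus_profiles.tsv"),
                        "compartment consensus profiles")
    write_commented_tsv(loc$populations,
                        file.path(out_dir, "populations.tsv"),
                        "detected populations with compartment mapping")
    if (!is.null(tms)) {
      write_commented_tsv(tms, file.path(out_dir, "tm_summary.tsv"),
                          "transmembrane consensus summary")
    }
    if (!is.null(cats)) {
      write_commented_tsv(
        bind_rows(hcm = cats$hcm, consensus = cats$consensus, .id = "mode"),
        file.path(out_dir, "category_summary.tsv"),
        "localization-category percentages"
      )
    }
    if (!is.null(metrics)) {
      jsonlite::write_json(as.list(metrics),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    log_lines <- c(
      sprintf("ffeprof run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("proteins: %d", dplyr::n_distinct(quant$protein_id)),
      sprintf("analysis window: %d-%d", min(attr(dw, "window")),
              max(attr(dw, "window"))),
      paste0("params: ",
             paste(names(loc$params), unlist(loc$params),
                   sep = "=", collapse = " "))
    )
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(invisible(result))
  }
  result
}
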