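#' Per-gene result report
#'
#' Assembles the record backing a gene results page: every association row
#' for the gene (p, per-gene q, Bonferroni), the gene's lambda inflation
#' factor and its QQ-plot coordinates.
#'
#' @param results Association tibble (from [run_phewas()], possibly already
#'   adjusted; q/bonferroni are recomputed on the per-gene axis if absent).
#' @param gene_id Gene to report.
#' @param path Optional JSON output path.
#' @return A list (invisibly written to `path` when given) with elements
#'   `gene_id`, `n_tests`, `lambda`, `associations`, `qq`.
#' @export
export_gene_report <- function(results, gene_id, path = NULL) {
  rows <- results[results$gene_id == gene_id, , drop = FALSE]
  if (nrow(rows) == 0) abort(paste0("unknown gene id: ", gene_id))
  if (!"q" %in% names(rows)) {
    rows <- adjust_results(rows, axis = "per_gene")
  }
  p_ok <- rows$p[!is.na(rows$p)]
  report <- list(
    gene_id = gene_id,
    n_tests = nrow(rows),
    lambda = if (length(p_ok) > 0) inflation_lambda(p_ok) else NA_real_,
    associations = rows[c("phenotype_name", "test", "statistic", "n",
                          "n_pcs", "p", "q", "bonferroni")],
    qq = if (length(p_ok) > 0) qq_points(p_ok) else
      tibble(expected = numeric(), observed = numeric())
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}

#' Write a run manifest
#'
#' Records the configuration, seed and package version of a pipeline run so
#' the run can be re-executed from the manifest alone.
#'
#' @param config Named list of configuration values (paths, thresholds).
#' @param seed Integer seed of the run.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  manifest <- list(
    package = "pcphewas",
    version = as.character(utils::packageVersion("pcphewas")),
    seed = seed,
    config = config,
    config_hash = rlang::hash(config)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
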