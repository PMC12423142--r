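# Report writing: coefficient/group-level summary CSVs, metrics JSON and a
# run manifest for exact re-runs.

#' Write fit and evaluation reports
#'
#' Emits a coefficient-table CSV (intercept, four latent-marker
#' coefficients, five manifest coefficients) and a group-level CSV (four
#' means, four SDs), both at four decimal places, plus an optional metrics
#' JSON (AUC and bootstrap CI per model variant) and a manifest recording
#' the seed and configuration.
#'
#' @param summary a `summary.popfit` data frame (see [summary.popfit()]).
#' @param dir output directory (created if absent).
#' @param metrics optional data frame from [cv_metrics()].
#' @param manifest optional named list (seed, configuration, ...) written
#'   as `manifest.json`.
#' @return Invisibly, the written paths.
#' @export
write_pop_report <- function(summary, dir, metrics = NULL,
                             manifest = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  is_beta <- grepl("^beta", summary$parameter)
  co <- summary[is_beta, ]
  gl <- summary[grepl("^(mu|sigma)_", summary$parameter), ]
  num <- vapply(co, is.numeric, logical(1L))
  co[num] <- lapply(co[num], function(x) sprintf("%.4f", x))
  gl[num] <- lapply(gl[num], function(x) sprintf("%.4f", x))
  paths <- file.path(dir, c("coefficients.csv", "group_level.csv"))
  write.csv(co, paths[1L], row.names = FALSE)
  write.csv(gl, paths[2L], row.names = FALSE)
  if (!is.null(metrics)) {
    mp <- file.path(dir, "metrics.json")
    jsonlite::write_json(split(metrics, metrics$variant), mp,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    paths <- c(paths, mp)
  }
  if (!is.null(manifest)) {
    manifest$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    fp <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, fp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, fp)
  }
  invisible(paths)
}
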