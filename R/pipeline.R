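# End-to-end pipeline: read + validate -> site summaries -> stratum and
# reporting-unit estimates, with machine-readable outputs. This is the
# programmatic core behind the command-line entry point.

.write_commented_csv <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  write.csv(df, con, row.names = FALSE)
}

#' Run the full processing chain
#'
#' Reads an observation file, validates it, computes site summaries under the
#' observation-type filter, and pools them to stratum and reporting-unit
#' scale with hard-bottom area weights. All CSV outputs open with a `#`
#' comment block stating the filter and weight provenance (read them back
#' with `comment.char = "#"`).
#'
#' @param input Path to an observation CSV in the published dialect, or a
#'   data frame already read with [read_spc_csv()].
#' @param area_table Path to a stratum area CSV or a data frame (see
#'   [read_area_table()]). When `NULL` only validation and site summaries are
#'   produced.
#' @param out_dir Output directory (created if needed). When `NULL`, nothing
#'   is written and results are only returned.
#' @param include Observation-type filter (default `c("I","N")`, the routine
#'   density-reporting filter).
#' @param metrics Site metric columns to estimate.
#' @param permissive Keep going when validation finds errors (the offending
#'   records are still excluded from analysis); default `FALSE` stops.
#' @param single_site Single-site stratum variance handling (see
#'   [pool_estimates()]).
#' @return Invisible list: `validation`, `sites`, `stratum_estimates`,
#'   `domain_estimates`, `weights`.
#' @export
run_pipeline <- function(input, area_table = NULL, out_dir = NULL,
                         include = c("I", "N"),
                         metrics = c("biomass_g_m2", "abundance_m2",
                                     "richness"),
                         permissive = FALSE,
                         single_site = c("impute", "strict")) {
  single_site <- match.arg(single_site)
  records <- if (is.character(input)) read_spc_csv(input) else input
  report <- validate_spc(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    validation_to_json(report, file.path(out_dir, "validation.json"))
  }
  if (length(report$error_rows) && !permissive) {
    stop("validation found ", length(report$error_rows),
         " record(s) with errors; rerun with permissive = TRUE to drop them",
         " and continue")
  }
  records <- valid_records(records, report)
  if (!nrow(records)) stop("no valid records remain")

  sites <- site_summaries(records, include = include)
  provenance <- paste0("obs-type filter: ", paste(include, collapse = ","),
                       "; weights: hard-bottom area share per reporting unit")
  if (!is.null(out_dir)) {
    .write_commented_csv(sites, file.path(out_dir, "site_summaries.csv"),
                         provenance)
  }

  strat <- dom <- wts <- NULL
  if (!is.null(area_table)) {
    at <- if (is.character(area_table)) read_area_table(area_table)
          else area_table
    strat <- do.call(rbind, lapply(metrics, function(m)
      stratum_estimates(sites, m)))
    wts <- compute_weights(at, strat)
    dom <- do.call(rbind, lapply(split(strat, strat$metric), function(e)
      pool_estimates(e, compute_weights(at, e), single_site = single_site)))
    rownames(dom) <- NULL
    if (!is.null(out_dir)) {
      .write_commented_csv(strat,
                           file.path(out_dir, "stratum_estimates.csv"),
                           provenance)
      .write_commented_csv(dom, file.path(out_dir, "domain_estimates.csv"),
                           provenance)
      writeLines(jsonlite::toJSON(dom, dataframe = "rows", auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE),
                 file.path(out_dir, "domain_estimates.json"))
    }
  }
  invisible(list(validation = report, sites = sites,
                 stratum_estimates = strat, domain_estimates = dom,
                 weights = wts))
}
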