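# Run orchestration helpers used by the analysis scripts: full base-case
# report and provenance manifests for reproducible outputs.

#' Full base-case report
#'
#' Runs every strategy, then the pairwise comparison against the reference
#' and the efficiency frontier at the configured willingness-to-pay
#' threshold.
#'
#' @param config A `cea_config`.
#' @param reference Reference strategy for the pairwise table.
#' @return List: `summary`, `comparison`, `frontier`, `results` (per-strategy
#'   traces and breakdowns), `wtp`.
#' @export
base_case_report <- function(config, reference = "docetaxel") {
  bc <- run_base_case(config)
  wtp <- config$settings$wtp_per_qaly
  list(summary = bc$summary,
       comparison = compare_strategies(bc$summary, reference, wtp),
       frontier = icer_frontier(bc$summary, wtp),
       results = bc$results, wtp = wtp)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: config path and MD5 hash, the
#' command label, seed, package version, timestamp and the output file list.
#'
#' @param path Manifest file path (JSON).
#' @param config_path Path of the consumed configuration file.
#' @param command Free-text label of the run.
#' @param seed Seed used (or `NA`).
#' @param outputs Character vector of output files written.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config_path, command, seed = NA, outputs) {
  manifest <- list(
    command = command,
    config_path = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("nsclcCEA")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = as.list(outputs))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}
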