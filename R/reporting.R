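#' Render an experiment summary table
#'
#' Lays out per-method aggregates in the comparison-table format: one row
#' per method (numbered in the canonical order, the six neuron-glia rules
#' then the plain network), with the mean generation of best, training
#' error and its standard deviation, validation accuracy as a percentage
#' with its standard deviation, and mean wall time in seconds. Accuracies
#' are stored internally as fractions and converted to percent only here.
#'
#' @param result an [experiment_result][run_experiment()].
#' @param style `"mux_table"` / `"iris_table"` (identical layout) or
#'   `"tally"` for the best-count table.
#' @return a data frame ready for printing or `write.csv`.
#' @export
render_summary <- function(result,
                           style = c("mux_table", "iris_table", "tally")) {
  style <- match.arg(style)
  if (style == "tally") return(tally_best(result))
  s <- result$summary
  data.frame(
    method = match(s$algorithm, .method_order),
    name = s$algorithm,
    generation = s$generation,
    training_error = s$train_mse,
    training_sd = s$train_sd,
    validation_accuracy_pct = 100 * s$val_accuracy,
    validation_sd_pct = 100 * s$val_sd,
    time_s = s$time
  )
}

#' Write experiment outputs to a run directory
#'
#' Writes `summary.csv` (the rendered comparison table), `runs.csv` (every
#' run), `best.csv` (the kept run per method and seed), `tally.csv` when
#' two or more methods are present, and `ledger.json` recording the
#' configuration, seeds, package version and timestamp so any output can
#' be regenerated.
#'
#' @param result an [experiment_result][run_experiment()].
#' @param dir output directory; created if missing.
#' @param config optional raw configuration list echoed into the ledger.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(render_summary(result), file.path(dir, "summary.csv"),
            row.names = FALSE)
  write.csv(result$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  write.csv(result$best, file.path(dir, "best.csv"), row.names = FALSE)
  if (length(unique(result$best$algorithm)) >= 2L) {
    write.csv(tally_best(result), file.path(dir, "tally.csv"),
              row.names = FALSE)
  }
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  ledger <- list(
    package_version = as.character(utils::packageVersion("angn")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seeds = result$plan$seeds,
    split_seed = result$plan$split_seed,
    algorithms = result$plan$algorithms,
    combos = result$plan$combos,
    ga = strip(result$plan$ga),
    config = strip(config)
  )
  jsonlite::write_json(ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
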