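#' Write a per-trial log to CSV
#'
#' @param run a run object with a `trials` tibble (`gonogo_run`,
#'   `reversal_run`, `bandit_run`) or a bare tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(run, path) {
  trials <- if (is.data.frame(run)) run else run$trials
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Write spike times to a two-column CSV
#'
#' @param spikes tibble with `trial` and `time_s` (e.g. collected from
#'   [run_trial()] records).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.csv(spikes[, c("trial", "time_s")], path, row.names = FALSE)
  invisible(path)
}

#' Write run metadata (calibration, configuration) to JSON
#'
#' @param config a named list (e.g. a run's `$config` plus `m`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
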