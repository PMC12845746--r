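#' Write a synthetic study to plain-text files
#'
#' Serialises a [simulate_kick_study()] object to the documented interchange
#' schema, which is also the interface for real recordings: a long-format EMG
#' CSV (`subject_id`, `group`, `timepoint`, `muscle`, `sample_index`,
#' `value_uV`), an events CSV (`subject_id`, `timepoint`, `event`, `time_s`),
#' an MVC CSV (`subject_id`, `muscle`, `trial`, `sample_index`, `value_uV`)
#' and a ground-truth JSON sidecar for test harnesses.
#'
#' @param study a `kick_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_kick_study <- function(study, dir) {
  stopifnot(inherits(study, "kick_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emg <- purrr::pmap(study$recordings, function(subject_id, group, timepoint,
                                                emg, events, ...) {
    tibble(subject_id = subject_id, group = group, timepoint = timepoint,
           muscle = rep(rownames(emg), each = ncol(emg)),
           sample_index = rep(seq_len(ncol(emg)) - 1L, nrow(emg)),
           value_uV = as.vector(t(emg)))
  }) |> dplyr::bind_rows()
  readr::write_csv(emg, file.path(dir, "emg.csv"))
  events <- purrr::pmap(study$recordings, function(subject_id, group,
                                                   timepoint, emg, events,
                                                   ...) {
    dplyr::mutate(events, subject_id = subject_id, timepoint = timepoint,
                  .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_csv(events, file.path(dir, "events.csv"))
  mvc <- purrr::pmap(study$mvc, function(subject_id, muscle, trial, signal) {
    tibble(subject_id = subject_id, muscle = muscle, trial = trial,
           sample_index = seq_along(signal) - 1L, value_uV = signal)
  }) |> dplyr::bind_rows()
  readr::write_csv(mvc, file.path(dir, "mvc.csv"))
  base <- study$truth$base
  jsonlite::write_json(
    list(muscles = base$muscles, n_syn = base$n_syn,
         weights = base$weights, activations = base$activations,
         centers = base$centers, widths = base$widths,
         phase_bounds = base$phase_bounds, noise_sd = base$noise_sd,
         fs = study$config$fs, seed = study$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study back from the plain-text interchange files
#'
#' Reconstructs the nested recording/MVC tibbles written by
#' [write_kick_study()]. The returned object carries the supplied analysis
#' `config`; the ground-truth sidecar is reloaded when present.
#'
#' @param dir directory holding `emg.csv`, `events.csv`, `mvc.csv`.
#' @param config a [kick_config()] describing the acquisition.
#' @return a `kick_study` (without per-session truth unless the sidecar
#'   exists).
#' @export
read_kick_study <- function(dir, config = kick_config()) {
  emg <- readr::read_csv(file.path(dir, "emg.csv"),
                         show_col_types = FALSE)
  events <- readr::read_csv(file.path(dir, "events.csv"),
                            show_col_types = FALSE)
  mvc <- readr::read_csv(file.path(dir, "mvc.csv"), show_col_types = FALSE)
  muscles <- config$muscles
  recs <- emg |>
    dplyr::group_by(.data$subject_id, .data$group, .data$timepoint) |>
    dplyr::group_map(function(df, key) {
      mat <- df |>
        dplyr::arrange(match(.data$muscle, muscles), .data$sample_index) |>
        dplyr::pull(.data$value_uV) |>
        matrix(nrow = length(unique(df$muscle)), byrow = TRUE,
               dimnames = list(intersect(muscles, unique(df$muscle)), NULL))
      ev <- events[events$subject_id == key$subject_id &
                     events$timepoint == key$timepoint,
                   c("event", "time_s")]
      tibble(subject_id = key$subject_id, group = key$group,
             timepoint = key$timepoint, emg = list(mat), events = list(ev))
    }) |>
    dplyr::bind_rows()
  mvc_tbl <- mvc |>
    dplyr::group_by(.data$subject_id, .data$muscle, .data$trial) |>
    dplyr::group_map(function(df, key) {
      tibble(subject_id = key$subject_id, muscle = key$muscle,
             trial = key$trial,
             signal = list(df$value_uV[order(df$sample_index)]))
    }) |>
    dplyr::bind_rows()
  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- list(base = structure(
      list(weights = matrix(unlist(tj$weights), length(tj$muscles),
                            dimnames = list(tj$muscles, NULL)),
           activations = matrix(unlist(tj$activations), tj$n_syn),
           centers = tj$centers, widths = tj$widths,
           muscles = tj$muscles, n_syn = tj$n_syn,
           phase_bounds = tj$phase_bounds, noise_sd = tj$noise_sd),
      class = "kick_truth"))
  }
  structure(list(recordings = recs, mvc = mvc_tbl, truth = truth,
                 config = config, seed = config$seed),
            class = "kick_study")
}
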