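# Layout/family compatibility: 2D spectrogram models consume image
# layouts; split and 1D convolution consume signal layouts.
compatible_layouts <- function(family) {
  switch(family,
         spectro2d = c("grouped", "mixed", "stacked", "eeg_stack",
                       "emg_stack", "eeg_multi", "emg_multi"),
         split_conv = , conv1d = c("signal_full", "signal_eeg", "signal_emg"),
         stop("unknown family: ", family))
}

#' Default pipeline configuration
#'
#' Returns the full run configuration as a named list: synthetic-session
#' settings, filter/window/STFT specifications, the (layout, family)
#' pairings to train, search-space and training overrides, the split
#' protocol and a global seed. Every field can be overridden from a YAML
#' file (see [load_run_config()]) or by `quick = TRUE`, which shortens the
#' slow repetitions and reduces the search budget for a fast, reduced run
#' of the same protocol.
#'
#' @param quick Use the reduced protocol (shorter slow repetitions, 5
#'   search trials x 1 repeat, 15-epoch limit, reduced search space).
#' @param seed Global seed; per-stage seeds derive from it.
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(quick = FALSE, seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    quick = isTRUE(quick),
    subjects = "S01",
    slow_duration = if (quick) 6 else 30,
    fast_duration = 2,
    weights = c(0, 3, 5),
    reps_per_trial = 3,
    sampling_rate = 4000,
    effects = unclass(effect_model()),
    pairings = list(list(layout = "grouped", family = "spectro2d"),
                    list(layout = "emg_multi", family = "spectro2d"),
                    list(layout = "eeg_multi", family = "spectro2d")),
    search_trials = if (quick) 5L else 50L,
    trainings_per_trial = if (quick) 1L else 2L,
    max_epochs = if (quick) 15L else 50L,
    batch_size = 32L,
    patience = 5L,
    tune = TRUE,
    fixed_hp = NULL
  ), class = "run_config")
}

#' Load and validate a run configuration from YAML
#'
#' Unknown keys are rejected; known keys override the defaults of
#' [default_run_config()].
#'
#' @param path YAML file path.
#' @param quick,seed Passed to [default_run_config()] before applying
#'   overrides.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path, quick = FALSE, seed = 1L) {
  overrides <- yaml::read_yaml(path)
  cfg <- default_run_config(quick = quick, seed = seed)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (p in cfg$pairings) {
    if (!p$family %in% cnn_families())
      stop("unknown model family: ", p$family)
    if (!p$layout %in% layout_names())
      stop("unknown layout: ", p$layout)
    if (!p$layout %in% compatible_layouts(p$family))
      stop(sprintf("incompatible pairing: layout '%s' cannot feed family '%s'",
                   p$layout, p$family))
  }
  if (length(cfg$subjects) < 1) stop("at least one subject is required")
  cfg
}

#' Run the full classification pipeline
#'
#' Executes generate -> filter -> segment -> window -> image -> split ->
#' tune/train -> evaluate for every subject and every (layout, family)
#' pairing in the configuration, then aggregates across subjects. All
#' artifacts (the serialized configuration, the search log, per-subject
#' results and the comparison report) are written into `out_dir`;
#' re-running with an identical configuration reproduces the same
#' predicted labels and accuracies.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [load_run_config()].
#' @param out_dir Run directory to create and populate.
#' @param verbose Print stage progress to stderr.
#' @return Invisibly, the report list also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("nf_run_"),
                         verbose = TRUE) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say <- function(...) if (verbose) message(sprintf(...))
  space <- if (config$quick) quick_search_space() else search_space()
  tspec <- train_spec(batch_size = config$batch_size,
                      max_epochs = config$max_epochs,
                      patience = config$patience,
                      search_trials = config$search_trials,
                      trainings_per_trial = config$trainings_per_trial,
                      seed = config$seed)
  all_logs <- NULL
  per_subject <- list()
  reports <- list()   # reports[[pairing_key]][[subject]]
  for (subject in config$subjects) {
    say("[%s] generating synthetic session", subject)
    spec <- session_spec(subject_id = subject,
                         sampling_rate = config$sampling_rate,
                         slow_duration = config$slow_duration,
                         fast_duration = config$fast_duration,
                         weights = config$weights,
                         reps_per_trial = config$reps_per_trial,
                         seed = config$seed)
    rec <- generate_recording(spec, do.call(effect_model, config$effects))
    say("[%s] filtering and segmenting", subject)
    rec <- segment_movement(filter_recording(rec))
    ws <- make_windows(rec)
    say("[%s] %d windows", subject, dim(ws$windows)[3])
    split <- split_windows(ws, split_spec(seed = config$seed))
    for (p in config$pairings) {
      key <- paste(p$layout, p$family, sep = "/")
      say("[%s] %s: building images", subject, key)
      dataset <- build_image_dataset(ws, p$layout)
      data <- model_data(dataset, split)
      if (isTRUE(config$tune) && is.null(config$fixed_hp)) {
        say("[%s] %s: random search (%d trials x %d fits)", subject, key,
            tspec$search_trials, tspec$trainings_per_trial)
        tuned <- tune_model(data, p$family, space, tspec, layout = p$layout)
        model <- tuned$best_model
        all_logs <- rbind(all_logs,
                          cbind(subject = subject, pairing = key, tuned$log))
      } else {
        hp <- config$fixed_hp
        model <- train_model(data, p$family, hp, tspec, layout = p$layout)
      }
      rep <- evaluate_model(model, data$test, subject_id = subject)
      say("[%s] %s: test accuracy %.2f%%", subject, key, rep$accuracy)
      reports[[key]] <- c(reports[[key]], list(rep))
      per_subject[[length(per_subject) + 1L]] <- data.frame(
        subject = subject, pairing = key, accuracy = rep$accuracy,
        macro_f = rep$macro_f, n_test = rep$n,
        slow_accuracy = if ("slow" %in% names(rep$speed_accuracy))
          rep$speed_accuracy[["slow"]] else NA_real_,
        fast_accuracy = if ("fast" %in% names(rep$speed_accuracy))
          rep$speed_accuracy[["fast"]] else NA_real_)
    }
  }
  aggregates <- lapply(reports, aggregate_reports)
  subject_tab <- do.call(rbind, per_subject)
  comparison <- NULL
  if (length(aggregates) >= 2 && length(config$subjects) >= 2) {
    acc <- sapply(names(aggregates), function(k)
      aggregates[[k]]$subject_accuracy)
    comparison <- compare_models(acc)
  }
  report <- list(
    pairings = lapply(names(aggregates), function(k) list(
      pairing = k,
      mean_accuracy = aggregates[[k]]$mean_accuracy,
      sd_accuracy = aggregates[[k]]$sd_accuracy,
      pooled_f = aggregates[[k]]$pooled_f,
      pooled_confusion = aggregates[[k]]$pooled_confusion)),
    comparison = if (is.null(comparison)) NULL else
      list(F = comparison$F, p = comparison$p,
           pairwise_p = comparison$pairwise_p),
    seed = config$seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       matrix = "rowmajor")
  utils::write.csv(subject_tab, file.path(out_dir, "per_subject.csv"),
                   row.names = FALSE)
  if (!is.null(all_logs))
    utils::write.csv(all_logs, file.path(out_dir, "search_log.csv"),
                     row.names = FALSE)
  say("run written to %s", out_dir)
  invisible(list(report = report, aggregates = aggregates,
                 per_subject = subject_tab, comparison = comparison,
                 out_dir = out_dir))
}
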