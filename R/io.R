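#' Write a session to plain-text files
#'
#' Serializes a session to a directory: `behavior.csv` (per-sample time,
#' position, velocity, lap index, pause flag), `dff.csv` (cells x frames),
#' and `truth.json` (behavior config, noise level, master seed, and the
#' ground-truth cell list).
#'
#' @param session a `"pf_session"`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- session$behavior
  write.csv(data.frame(time_s = b$time_s, position_cm = b$position_cm,
                       velocity_cm_s = b$velocity_cm_s,
                       lap_index = b$lap_index, is_pause = b$is_pause),
            file.path(dir, "behavior.csv"), row.names = FALSE)
  write.csv(as.data.frame(session$dff), file.path(dir, "dff.csv"),
            row.names = FALSE)
  meta <- list(track_length_cm = b$track_length_cm,
               frame_rate_hz = b$frame_rate_hz, n_laps = b$n_laps,
               noise_sigma = session$noise_sigma, seed = session$seed,
               cfg = if (!is.null(session$cfg)) unclass(session$cfg),
               truth = lapply(session$truth, unclass))
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing `behavior.csv`, `dff.csv`, `truth.json`.
#' @return A `"pf_session"`.
#' @export
read_session <- function(dir) {
  b <- read.csv(file.path(dir, "behavior.csv"))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  behavior <- structure(list(time_s = b$time_s, position_cm = b$position_cm,
                             velocity_cm_s = b$velocity_cm_s,
                             lap_index = b$lap_index, is_pause = b$is_pause,
                             track_length_cm = meta$track_length_cm,
                             frame_rate_hz = meta$frame_rate_hz,
                             n_laps = meta$n_laps),
                        class = "pf_behavior")
  dff <- as.matrix(read.csv(file.path(dir, "dff.csv")))
  dimnames(dff) <- NULL
  truth <- lapply(seq_len(nrow(meta$truth)), function(i) {
    tc <- as.list(meta$truth[i, ])
    tc <- lapply(tc, function(v) if (is.list(v)) unlist(v) else v)
    class(tc) <- "pf_truth_cell"
    tc
  })
  structure(list(behavior = behavior, dff = dff, truth = truth,
                 noise_sigma = meta$noise_sigma, seed = meta$seed,
                 cfg = meta$cfg),
            class = "pf_session")
}

#' Simulate a preset and write it to disk
#'
#' @param preset preset name (see [simulate_preset()]); `"paired_days"`
#'   writes `day1/` and `day2/` subdirectories.
#' @param out_dir output directory.
#' @param n_cells,n_laps,seed,... passed to [simulate_preset()].
#' @return The session (or day pair), invisibly.
#' @export
pf_simulate <- function(preset, out_dir, n_cells = 90, n_laps = 40,
                        seed = 1L, ...) {
  s <- simulate_preset(preset, n_cells = n_cells, n_laps = n_laps,
                       seed = seed, ...)
  if (preset == "paired_days") {
    write_session(s$day1, file.path(out_dir, "day1"))
    write_session(s$day2, file.path(out_dir, "day2"))
  } else {
    write_session(s, out_dir)
  }
  invisible(s)
}

#' Write and read an analysis configuration as YAML
#'
#' Round-trips a [pf_config()] losslessly through a YAML file, so runs can be
#' reproduced from a checked-in configuration.
#'
#' @param config a [pf_config()].
#' @param path YAML file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config()` returns the `"pf_config"`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$bin_width_cm <- NULL
  vals$fine_bin_width_cm <- NULL
  do.call(pf_config, vals)
}

#' Run the pipeline end to end and write its report tables
#'
#' Executes transient detection, place-field detection and all per-field
#' metrics on a session and writes `fields.csv` (per-field summary),
#' `metrics_long.csv` (per-field per-lap COM/peak/skew/width),
#' `lap_table.csv` (per-lap velocities), `population_curve.csv` (when
#' enough fields qualify), and `provenance.json` (seed, configuration,
#' package version). Outputs are pure functions of the inputs and seed, so
#' reruns are byte-identical.
#'
#' @param session a `"pf_session"` or a directory readable by
#'   [read_session()].
#' @param out_dir output directory.
#' @param config a [pf_config()].
#' @param seed analysis seed.
#' @param stages character subset of `c("fields", "dynamics", "decoding")`;
#'   decoding is off by default (it presumes enough cells and laps to train
#'   the position decoder) and writes `decoder_errors.csv` and
#'   `confusion.csv` when enabled.
#' @param n_decoder_cells,n_decoder_repeats decoder trial shape when the
#'   decoding stage is enabled.
#' @return The `"pf_analysis"`, invisibly.
#' @export
pf_run <- function(session, out_dir, config = pf_config(), seed = 1L,
                   stages = c("fields", "dynamics"),
                   n_decoder_cells = 50, n_decoder_repeats = 5) {
  if (is.character(session)) session <- read_session(session)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ana <- pf_analyze(session, config, seed,
                    keep_traces = "decoding" %in% stages)
  write.csv(ana$fields, file.path(out_dir, "fields.csv"), row.names = FALSE)
  write.csv(field_metrics(ana), file.path(out_dir, "metrics_long.csv"),
            row.names = FALSE)
  write.csv(lap_velocity(session$behavior),
            file.path(out_dir, "lap_table.csv"), row.names = FALSE)
  if ("dynamics" %in% stages && nrow(ana$fields) > 0) {
    curve <- tryCatch(analysis_shift_curve(ana), error = function(e) NULL)
    if (!is.null(curve)) {
      write.csv(curve$curve, file.path(out_dir, "population_curve.csv"),
                row.names = FALSE)
    }
  }
  if ("decoding" %in% stages) {
    nl <- session$behavior$n_laps
    if (nl >= 20) {
      train <- if (nl >= 40) 6:35 else 2:(nl - 3)
      val <- if (nl >= 40) 36:40 else (nl - 2):(nl - 1)
      ds <- build_decoder_dataset(ana$sig_traces, session$behavior, config)
      n_cells <- min(n_decoder_cells, ncol(ds$X))
      ex <- decoding_experiment(ds, n_repeats = n_decoder_repeats,
                                n_cells = n_cells,
                                seed = derive_seed(seed, 424243L),
                                train_laps = train, val_laps = val)
      write.csv(data.frame(repeat_idx = seq_along(ex$errors_cm),
                           error_cm = ex$errors_cm,
                           val_error_cm = ex$val_errors_cm),
                file.path(out_dir, "decoder_errors.csv"), row.names = FALSE)
      model <- train_nb_decoder(ds, train_laps = train, val_laps = val,
                                var_floor = config$decoder_var_floor)
      write.csv(decode_and_score(model, ds, laps = 1)$confusion,
                file.path(out_dir, "confusion.csv"), row.names = FALSE)
    } else {
      warning("decoding stage skipped: fewer than 20 laps")
    }
  }
  jsonlite::write_json(
    list(seed = seed, n_cells = ana$n_cells, n_fields = nrow(ana$fields),
         config = unclass(config),
         package_version = as.character(utils::packageVersion("pfdyn"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(ana)
}
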