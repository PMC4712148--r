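#' Simulation run configuration
#'
#' Bundles everything [run_simulate()] needs: the population, the stimulus
#' protocols (Table-scale grating repeats by default), the mapping-movie
#' spec, and the classification thresholds. The default movie is a single
#' 300 s block at 64 x 64 px — enough to collect the few thousand spikes the
#' STA stage needs — while the grating protocols keep their standard
#' condition tables and repeat counts.
#'
#' @param seed Global seed; fans out to per-stage seeds via [derive_seed()].
#' @param n_neurons Population size.
#' @param class_mix Passed to [sample_population()].
#' @param grating_repeats Optional named list of per-set repeat overrides,
#'   e.g. `list(spatial = 3)`.
#' @param flicker_repeats Total flicker epochs (default 800).
#' @param movie_spec A [noise_movie_spec()]; default 64 x 64, 30 Hz, 300 s,
#'   one session.
#' @param analysis A [default_config()] list of thresholds.
#' @param snr Passed to [sample_population()].
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_neurons = 12L,
                       class_mix = list(on = 0.5, linear = 0.95,
                                        transient = 0.95, ds = 0.05,
                                        os = 0.02),
                       grating_repeats = list(),
                       flicker_repeats = 800L,
                       movie_spec = NULL,
                       analysis = default_config(),
                       snr = "high") {
  movie_spec <- movie_spec %||% noise_movie_spec(
    movie_duration_s = 300, grey_duration_s = 10, n_sessions = 1L,
    seed = derive_seed(seed, 90L))
  structure(list(seed = as.integer(seed), n_neurons = as.integer(n_neurons),
                 class_mix = class_mix, grating_repeats = grating_repeats,
                 flicker_repeats = as.integer(flicker_repeats),
                 movie_spec = movie_spec, analysis = analysis, snr = snr),
            class = "sim_config")
}

#' Simulate a full experiment in memory
#'
#' Samples a ground-truth population, builds all protocols, generates the
#' mapping movie, and simulates every neuron's spike trains under every
#' stimulus. This is the in-memory engine behind [run_simulate()].
#'
#' @param config A [sim_config()].
#' @param stages Character vector of stages to simulate; any of
#'   `"gratings"`, `"flicker"`, `"movie"`.
#' @return A list: `truth`, `protocols` (named list), `movie`, `spikes`
#'   (one tibble, `protocol` column naming the stage).
#' @export
simulate_experiment <- function(config = sim_config(),
                                stages = c("gratings", "flicker", "movie")) {
  truth <- sample_population(config$n_neurons, derive_seed(config$seed, 1L),
                             class_mix = config$class_mix, snr = config$snr)
  protocols <- list()
  spikes <- list()
  sets <- c("spatial", "temporal", "contrast", "direction")
  if ("gratings" %in% stages) {
    for (k in seq_along(sets)) {
      s <- sets[k]
      protocols[[s]] <- grating_protocol(
        s, seed = derive_seed(config$seed, 10L + k),
        n_repeats = config$grating_repeats[[s]])
    }
  }
  if ("flicker" %in% stages) {
    protocols$flicker <- flicker_protocol(config$flicker_repeats)
  }
  movie <- NULL
  if ("movie" %in% stages) movie <- generate_noise_movie(config$movie_spec)

  if (config$n_neurons > 0) {
    for (i in seq_len(nrow(truth))) {
      nrn <- truth[i, ]
      base <- derive_seed(config$seed, 100L + 10L * i)
      if ("gratings" %in% stages) {
        for (k in seq_along(sets)) {
          s <- sets[k]
          sp <- simulate_trials(nrn, protocols[[s]], seed = base + k)
          if (nrow(sp) > 0) sp$protocol <- s
          spikes[[length(spikes) + 1L]] <- sp
        }
      }
      if ("flicker" %in% stages) {
        sp <- simulate_flicker_response(nrn, protocols$flicker,
                                        seed = base + 5L)
        if (nrow(sp) > 0) sp$protocol <- "flicker"
        spikes[[length(spikes) + 1L]] <- sp
      }
      if ("movie" %in% stages) {
        sp <- simulate_movie_response(nrn, movie, seed = base + 6L)
        if (nrow(sp) > 0) sp$protocol <- "movie"
        spikes[[length(spikes) + 1L]] <- sp
      }
    }
  } else {
    warn("empty population: no spikes simulated")
  }
  spikes <- dplyr::bind_rows(spikes)
  list(truth = truth, protocols = protocols, movie = movie, spikes = spikes)
}

write_protocols <- function(protocols, dir) {
  for (nm in names(protocols)) {
    readr::write_csv(protocols[[nm]],
                     file.path(dir, paste0("protocol_", nm, ".csv")))
  }
}

read_protocols <- function(dir) {
  files <- list.files(dir, pattern = "^protocol_.*\\.csv$", full.names = TRUE)
  prot <- list()
  for (f in files) {
    nm <- sub("^protocol_(.*)\\.csv$", "\\1", basename(f))
    p <- readr::read_csv(f, show_col_types = FALSE)
    needed <- c("condition_id", "trial_index", "duration_s")
    miss <- setdiff(needed, names(p))
    if (length(miss) > 0) {
      abort(sprintf("protocol file %s lacks columns: %s", basename(f),
                    paste(miss, collapse = ", ")))
    }
    attr(p, "set_name") <- nm
    if (nm %in% names(grating_sets)) {
      attr(p, "varying") <- grating_sets[[nm]]$varying
    }
    if (nm == "flicker") attr(p, "epoch_s") <- p$duration_s[1]
    prot[[nm]] <- p
  }
  prot
}

#' Run the simulation stage and write its artifacts
#'
#' Writes `ground_truth.json`, `protocol_<set>.csv`, `movie.rds`, and
#' `spikes.csv` under `out_dir`. Deterministic under a fixed config: the
#' same config writes byte-identical spike tables.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the in-memory experiment list.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste("cannot create", out_dir))
  exp <- simulate_experiment(config)
  jsonlite::write_json(exp$truth, file.path(out_dir, "ground_truth.json"),
                       digits = NA, auto_unbox = FALSE)
  write_protocols(exp$protocols, out_dir)
  if (!is.null(exp$movie)) saveRDS(exp$movie, file.path(out_dir, "movie.rds"))
  readr::write_csv(exp$spikes, file.path(out_dir, "spikes.csv"))
  saveRDS(config, file.path(out_dir, "sim_config.rds"))
  invisible(exp)
}

#' Run the characterization stage from simulation artifacts
#'
#' Reads `spikes.csv`, the protocol CSVs, and (if present) `movie.rds` from
#' `in_dir`, characterizes every unit, and writes `cell_reports.csv`. A
#' missing movie file skips the receptive-field stage with a warning; the
#' other stages proceed.
#'
#' @param in_dir Directory written by [run_simulate()].
#' @param out_dir Output directory (default `in_dir`).
#' @param config Analysis thresholds ([default_config()]).
#' @return The cell-report tibble, invisibly.
#' @export
run_characterize <- function(in_dir, out_dir = in_dir,
                             config = default_config()) {
  spike_file <- file.path(in_dir, "spikes.csv")
  if (!file.exists(spike_file)) abort(paste("missing", spike_file))
  spikes <- readr::read_csv(spike_file, show_col_types = FALSE)
  needed <- c("unit_id", "protocol", "condition_id", "trial_index",
              "spike_time_s")
  miss <- setdiff(needed, names(spikes))
  if (length(miss) > 0) {
    abort(sprintf("spikes.csv lacks columns: %s", paste(miss, collapse = ", ")))
  }
  protocols <- read_protocols(in_dir)
  known <- unlist(lapply(protocols, function(p) unique(p$condition_id)))
  unknown <- setdiff(unique(spikes$condition_id), c(known, "movie"))
  if (length(unknown) > 0) {
    abort(sprintf("spikes.csv references unknown condition_id: %s",
                  paste(unknown, collapse = ", ")))
  }
  movie_file <- file.path(in_dir, "movie.rds")
  movie <- if (file.exists(movie_file)) readRDS(movie_file) else NULL
  truth_file <- file.path(in_dir, "ground_truth.json")
  truth <- if (file.exists(truth_file)) {
    tibble::as_tibble(jsonlite::read_json(truth_file, simplifyVector = TRUE))
  } else NULL
  reports <- characterize_population(spikes, protocols, movie = movie,
                                     config = config, truth = truth)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(reports, file.path(out_dir, "cell_reports.csv"))
  invisible(reports)
}

#' Run the reporting stage
#'
#' Builds the population tables from a cell-report tibble (or the
#' `cell_reports.csv` in a directory) and writes
#' `population_summary.json`, `classification_table.csv`, and a Markdown
#' narrative `population_report.md`.
#'
#' @param reports A report tibble or a directory containing
#'   `cell_reports.csv`.
#' @param out_dir Output directory.
#' @return The population-table list, invisibly.
#' @export
run_report <- function(reports, out_dir) {
  if (is.character(reports)) {
    f <- file.path(reports, "cell_reports.csv")
    if (!file.exists(f)) abort(paste("missing", f))
    reports <- readr::read_csv(f, show_col_types = FALSE)
  }
  tab <- build_population_table(reports)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tab$classification,
                   file.path(out_dir, "classification_table.csv"))
  jsonlite::write_json(
    list(n_units = tab$n_units,
         classification = tab$classification,
         metrics = tab$metrics,
         agreement = tab$agreement,
         multiple_testing_correction = "none"),
    file.path(out_dir, "population_summary.json"),
    digits = NA, auto_unbox = TRUE, null = "null")

  lines <- c(
    "# Population report", "",
    sprintf("Units: %d", tab$n_units), "",
    "| axis | level | count | fraction |", "|---|---|---|---|",
    sprintf("| %s | %s | %d | %.3f |", tab$classification$axis,
            tab$classification$level, tab$classification$count,
            tab$classification$fraction),
    "", "| metric | n | form | centre | low | high |", "|---|---|---|---|---|---|",
    sprintf("| %s | %d | %s | %.3g | %.3g | %.3g |", tab$metrics$metric,
            tab$metrics$n, tab$metrics$form, tab$metrics$centre,
            tab$metrics$spread_low, tab$metrics$spread_high))
  if (!is.null(tab$agreement)) {
    lines <- c(lines, "", "| axis | agreement with ground truth |", "|---|---|",
               sprintf("| %s | %.3f |", tab$agreement$axis,
                       tab$agreement$agreement))
  }
  writeLines(lines, file.path(out_dir, "population_report.md"))
  invisible(tab)
}

#' Run the whole pipeline: simulate, characterize, report
#'
#' @param config A [sim_config()].
#' @param out_dir Artifact directory.
#' @return The population-table list, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), out_dir) {
  run_simulate(config, out_dir)
  reports <- run_characterize(out_dir, config = config$analysis)
  run_report(reports, out_dir)
}
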