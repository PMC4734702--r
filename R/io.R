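# Configuration files, delimited trace output, the one-command experiment
# runner, and deterministic miniature fixtures for the test suite.
# Floating-point columns are written at 9 significant digits so repeated
# runs of one config produce byte-identical files.

.fmt_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Write a trace (or any tibble) as CSV with stable float formatting
#'
#' @param x A tibble; doubles are formatted at 9 significant digits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- .fmt_num(df[[j]])
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace()]
#'
#' @param path CSV path.
#' @return A tibble (plain; provenance attributes are not round-tripped).
#' @export
read_trace <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# small deterministic string hash (djb2 over a 31-bit modulus); used to
# fingerprint fixture traces without binary artifacts
.checksum <- function(x) {
  s <- paste(.fmt_num(as.numeric(x)), collapse = ",")
  bytes <- utf8ToInt(s)
  h <- 5381
  m <- 2147483647
  for (b in bytes) h <- (h * 33 + b) %% m
  sprintf("%d", h)
}

#' Experiment configuration
#'
#' Assembles and validates the flat configuration that drives
#' [run_experiment()]: model variant, paradigm, reset speed, lesions,
#' motivation, seed, and parameter overrides keyed by model symbol.
#' Unknown override symbols are rejected (with the list of known symbols);
#' overrides outside a weight's robustness range warn.
#'
#' @param variant `"rate"` or `"spiking"`.
#' @param paradigm `"pavlovian"` or `"rubbernecking"`.
#' @param reset `"slow"` or `"fast"` plan-reset time constant.
#' @param N Sensory channels.
#' @param seed Integer seed.
#' @param lesion_ba,lesion_plan Interneuron lesion flags.
#' @param motivation Length-2 testing-phase-2 drive (Pavlovian only).
#' @param n_distractors Distractor count (Pavlovian only).
#' @param lag_steps,n_trials,conditioned Rubbernecking settings.
#' @param overrides Named list of parameter overrides by symbol.
#' @param record_stride Recording stride in steps.
#' @param output Output directory for [run_experiment()] (optional).
#' @return An `amygate_config` list.
#' @export
experiment_config <- function(variant = c("rate", "spiking"),
                              paradigm = c("pavlovian", "rubbernecking"),
                              reset = c("slow", "fast"),
                              N = 10, seed = 1L,
                              lesion_ba = FALSE, lesion_plan = FALSE,
                              motivation = c(0, 0), n_distractors = 6L,
                              lag_steps = 500L, n_trials = 20L,
                              conditioned = TRUE,
                              overrides = list(),
                              record_stride = 10L, output = NULL) {
  cfg <- list(
    variant = match.arg(variant), paradigm = match.arg(paradigm),
    reset = match.arg(reset), N = as.integer(N), seed = as.integer(seed),
    lesion_ba = isTRUE(lesion_ba), lesion_plan = isTRUE(lesion_plan),
    motivation = as.numeric(motivation),
    n_distractors = as.integer(n_distractors),
    lag_steps = as.integer(lag_steps), n_trials = as.integer(n_trials),
    conditioned = isTRUE(conditioned),
    overrides = overrides,
    record_stride = as.integer(record_stride), output = output
  )
  config_params(cfg) # validates overrides (errors/warnings surface here)
  structure(cfg, class = "amygate_config")
}

#' Build the parameter object described by a config
#'
#' @param config An `amygate_config` (or plain list with its fields).
#' @return An `amygate_params`.
#' @export
config_params <- function(config) {
  builder <- if (identical(config$variant, "spiking")) spiking_params else rate_params
  do.call(builder, c(
    list(N = config$N, reset = config$reset),
    config$overrides
  ))
}

#' Write / read experiment configurations as YAML
#'
#' Round-trip identity: a written config reads back equal to the original.
#'
#' @param config An `amygate_config`.
#' @param path YAML file path.
#' @return `write_experiment_config()`: `path`, invisibly;
#'   `read_experiment_config()`: an `amygate_config`.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw[setdiff(names(raw), character(0))])
}

#' Run a fully configured experiment and write its outputs
#'
#' Builds the schedule and parameters from the config, runs the selected
#' model variant, and writes into `out_dir`: `trace.csv` (the recorded
#' trace), `summary.csv` (plan/attention summary for Pavlovian runs;
#' lag/seed/detection-rate row for rubbernecking runs), `config.yaml`
#' (effective configuration plus provenance: all effective parameter
#' values, seed, package version), and `spikes.csv` for spiking runs.
#' Identical config and seed produce byte-identical summary and trace
#' files.
#'
#' @param config An `amygate_config`.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$output`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the result objects and file paths.
#' @export
run_experiment <- function(config, out_dir = config$output, quiet = FALSE) {
  stopifnot(!is.null(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config_params(config)
  lesion <- lesion_config(config$lesion_ba, config$lesion_plan)
  say <- function(...) if (!quiet) message(...)

  if (config$paradigm == "pavlovian") {
    say("building Pavlovian schedule (seed ", config$seed, ")")
    sched <- build_pavlovian_schedule(
      n_channels = config$N, seed = config$seed,
      n_distractors = config$n_distractors, motivation = config$motivation
    )
  } else {
    say("building rubbernecking schedule (lag ", config$lag_steps, ", seed ",
        config$seed, ")")
    sched <- build_rubbernecking_schedule(
      lag_steps = config$lag_steps, n_trials = config$n_trials,
      seed = config$seed, conditioned = config$conditioned,
      n_channels = config$N
    )
  }
  say("integrating ", sched$n_steps, " steps (", config$variant, " model)")
  tr <- simulate(sched, params,
    lesion = lesion,
    record_stride = config$record_stride
  )

  paths <- list(trace = file.path(out_dir, "trace.csv"))
  write_trace(tr, paths$trace)
  if (config$paradigm == "pavlovian") {
    pl <- plan_timeline(tr)
    at <- attention_summary(tr, plan = pl)
    summary <- dplyr::bind_cols(glance(pl), glance(at))
    result <- list(trace = tr, plan = pl, attention = at)
  } else {
    det <- score_detection(tr)
    summary <- tibble::tibble(
      lag_steps = config$lag_steps, n_trials = config$n_trials,
      seed = config$seed, conditioned = config$conditioned, rate = det$rate
    )
    result <- list(trace = tr, detection = det)
  }
  paths$summary <- file.path(out_dir, "summary.csv")
  write_trace(summary, paths$summary)
  if (config$variant == "spiking") {
    paths$spikes <- file.path(out_dir, "spikes.csv")
    write_trace(spike_raster(tr), paths$spikes)
  }
  paths$config <- file.path(out_dir, "config.yaml")
  prov <- c(
    unclass(config)[setdiff(names(config), "output")],
    list(
      effective_parameters = as.list(unclass(params)),
      package_version = as.character(packageVersion("amygate"))
    )
  )
  yaml::write_yaml(prov, paths$config)
  say("wrote ", length(paths), " files to ", out_dir)
  invisible(c(result, list(paths = paths, summary = summary)))
}

# fixture definitions ---------------------------------------------------

.fixture_names <- c("tiny-pavlovian", "single-neuron", "single-trial-detection")

.fixture_build <- function(name) {
  switch(name,
    "tiny-pavlovian" = {
      sched <- build_pavlovian_schedule(
        n_channels = 3, seed = 42L, n_distractors = 0,
        epoch_steps = 1000L, cs_duration = 200L, r_duration = 150L,
        r_delay = 50L, ep1_reps = 1L, ep2_reps = 2L, test_cycles = 1L
      )
      list(schedule = sched, params = rate_params(N = 3))
    },
    "single-neuron" = {
      # constant-drive shunting unit; equilibrium B*E/(A+E) = 5
      E <- 1; I <- 0; A <- 1; B <- 10; C <- 10; tau <- 0.05; h <- 1e-4
      x <- numeric(5000)
      for (s in 2:5000) x[s] <- shunting_step(x[s - 1], E, I, A, B, C, tau, h)
      list(
        trace = tibble::tibble(time = seq_len(5000) * h, x = x),
        fixed_point = shunting_fixed_point(E, I, A, B, C)
      )
    },
    "single-trial-detection" = {
      sched <- build_rubbernecking_schedule(
        lag_steps = 500L, n_trials = 1L, seed = 1L,
        cond_steps = 25000L, n_pairings = 1L
      )
      sched$trials$threshold <- 0.05
      list(schedule = sched, params = rate_params(reset = "fast"))
    },
    stop("unknown fixture name: ", name, "; known: ",
      paste(.fixture_names, collapse = ", "),
      call. = FALSE
    )
  )
}

.fixture_checksum <- function(name, fix = .fixture_build(name)) {
  if (!is.null(fix$schedule)) {
    tr <- simulate(fix$schedule, fix$params)
    .checksum(as.matrix(as.data.frame(tr)))
  } else {
    .checksum(as.matrix(as.data.frame(fix$trace)))
  }
}

#' Deterministic miniature fixtures
#'
#' Canned inputs for fast tests: `tiny-pavlovian` (3 channels, 4000 steps,
#' scaled-down pulse geometry), `single-neuron` (a constant-drive shunting
#' unit with known equilibrium), `single-trial-detection` (one
#' rubbernecking trial with threshold forced to 0.05). Each fixture has a
#' reference checksum of its simulated trace stored with the package;
#' `verify = TRUE` recomputes and compares, so any change to the dynamics
#' is caught. Checksums are regenerated only by the explicit
#' [write_fixture_checksums()].
#'
#' @param name One of `"tiny-pavlovian"`, `"single-neuron"`,
#'   `"single-trial-detection"`.
#' @param verify Recompute the trace checksum and compare with the stored
#'   reference (error on mismatch).
#' @return A list with the fixture's pieces (`schedule` and `params`, or
#'   `trace` and `fixed_point`) plus `name` and `checksum` (the stored
#'   reference, `NA` if none stored yet).
#' @export
generate_fixture <- function(name, verify = FALSE) {
  fix <- .fixture_build(name)
  path <- system.file("extdata", "fixture-checksums.json", package = "amygate")
  stored <- if (nzchar(path)) jsonlite::read_json(path) else list()
  fix$name <- name
  fix$checksum <- stored[[name]] %||% NA_character_
  if (isTRUE(verify)) {
    got <- .fixture_checksum(name, fix)
    if (is.na(fix$checksum)) {
      stop("no stored checksum for fixture ", name, call. = FALSE)
    }
    if (!identical(got, fix$checksum)) {
      stop(
        "fixture ", name, " checksum mismatch: stored ", fix$checksum,
        ", recomputed ", got,
        call. = FALSE
      )
    }
  }
  fix
}

#' Regenerate the stored fixture checksums
#'
#' Recomputes every fixture's trace checksum and writes the reference
#' file. Run deliberately after an intended change to the dynamics.
#'
#' @param path Output JSON path (defaults to the source tree's
#'   `inst/extdata/fixture-checksums.json` when writable).
#' @return The checksum list, invisibly.
#' @export
write_fixture_checksums <- function(path = file.path("inst", "extdata", "fixture-checksums.json")) {
  sums <- lapply(setNames(.fixture_names, .fixture_names), .fixture_checksum)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(sums, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(sums)
}
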