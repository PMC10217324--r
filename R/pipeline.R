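# End-to-end pipeline: simulate -> analyze -> fit -> report, with a single
# YAML-serializable configuration, reproducible seeds, and run directories
# that echo their configuration. The thin command-line wrapper in
# inst/cli/serialdep.R dispatches onto these functions.

#' Run configuration
#'
#' One document holding every stage's settings. Every random operation in a
#' run traces to the single top-level `seed`, and the config is echoed
#' verbatim into each output directory.
#'
#' @param sim A [sim_config()].
#' @param observer An [observer_params()].
#' @param min_trials_per_user Preprocessing threshold (see
#'   [preprocess_trials()]).
#' @param session_gap_minutes Session gap for [sessionize()].
#' @param lags Lags to analyze.
#' @param metrics Metrics to analyze.
#' @param binspec A [bin_spec()].
#' @param n_permutations Permutations per lag.
#' @param seed Top-level seed.
#' @param version Config schema version string.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), observer = observer_params(),
                       min_trials_per_user = 20L, session_gap_minutes = 30,
                       lags = 1:4, metrics = .metric_names,
                       binspec = malignancy_bins(),
                       n_permutations = 1000L, seed = 1L,
                       version = "1") {
  .check_metrics(metrics)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, observer = observer,
                 min_trials_per_user = as.integer(min_trials_per_user),
                 session_gap_minutes = session_gap_minutes,
                 lags = as.integer(lags), metrics = metrics, binspec = binspec,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), version = version),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML path.
#' @return `read_run_config()`: a `run_config`; `write_run_config()`:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config(
    sim = do.call(sim_config, y$sim %||% list()),
    observer = do.call(observer_params, y$observer %||% list()),
    min_trials_per_user = y$min_trials_per_user %||% 20L,
    session_gap_minutes = y$session_gap_minutes %||% 30,
    lags = y$lags %||% 1:4,
    metrics = y$metrics %||% .metric_names,
    binspec = if (is.null(y$binspec)) malignancy_bins() else {
      bin_spec(y$binspec$domain_low, y$binspec$domain_high, y$binspec$width,
               y$binspec$min_trials_per_bin %||% 0L)
    },
    n_permutations = y$n_permutations %||% 1000L,
    seed = y$seed %||% 1L,
    version = y$version %||% "1"
  )
  cfg
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  flat <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Simulate a dataset to disk
#'
#' Generates the stimulus pool and trial table under `config` and writes
#' `stimuli.csv`, `trials.csv`, a `manifest.json` (seed, parameters, row
#' counts) and a verbatim `config.yaml` into `outdir`. Identical configs
#' (including seed) produce byte-identical CSVs.
#'
#' @param config A [run_config()] or path to its YAML.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the written paths and the tables.
#' @export
run_simulate <- function(config = run_config(), outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stimuli <- generate_stimuli(config$sim)
  trials <- simulate_trials(stimuli, config$observer, config$sim)
  write_stimuli(stimuli, file.path(outdir, "stimuli.csv"))
  write_trials(trials, file.path(outdir, "trials.csv"))
  write_run_config(config, file.path(outdir, "config.yaml"))
  manifest <- list(seed = config$sim$seed,
                   n_stimuli = nrow(stimuli), n_trials = nrow(trials),
                   n_users = config$sim$n_users,
                   trials_per_user = config$sim$trials_per_user,
                   observer = unclass(config$observer))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(outdir = outdir, stimuli = stimuli, trials = trials,
                 manifest = manifest))
}

#' Analyze a trial dataset end-to-end
#'
#' Reads (or accepts) trial and stimulus tables, preprocesses them (writing
#' the exclusion report), sessionizes, runs [serial_dependence()] at every
#' configured lag, fits tuning curves, and writes tidy results:
#' `exclusion_report.json`, `net_change.csv` (metric, lag, bin_center, delta,
#' cost, n, upper95, p, p_adj), `tuning_fits.csv` and `summary.json`, plus
#' the echoed `config.yaml`. Stage timings and the exclusion report are
#' logged via [message()].
#'
#' @param trials Trial tibble or CSV path.
#' @param stimuli Stimulus tibble or CSV path.
#' @param config A [run_config()] or YAML path.
#' @param outdir Output directory.
#' @return Invisibly, a list with `net_change` (per-lag list), `fits`
#'   (amplitude table), and `report`.
#' @export
run_analyze <- function(trials, stimuli, config = run_config(), outdir) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.character(stimuli)) {
    if (!file.exists(stimuli)) {
      abort(paste0("stimulus file not found: ", stimuli), class = "serialdep_io_error")
    }
    stimuli <- read_stimuli(stimuli)
  }
  if (is.character(trials)) {
    if (!file.exists(trials)) {
      abort(paste0("trial file not found: ", trials), class = "serialdep_io_error")
    }
    trials <- read_trials(trials)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  pp <- preprocess_trials(trials, min_trials_per_user = config$min_trials_per_user)
  write_exclusion_report(pp$report, file.path(outdir, "exclusion_report.json"))
  message(sprintf("preprocess: %d -> %d records (%.1fs)", pp$report$n_input,
                  pp$report$n_output, as.numeric(Sys.time() - t0, units = "secs")))
  trials <- sessionize(pp$trials, gap_minutes = config$session_gap_minutes)

  t1 <- Sys.time()
  curves <- list()
  for (lg in config$lags) {
    curves[[as.character(lg)]] <- serial_dependence(
      trials, stimuli, lag = lg, binspec = config$binspec,
      metrics = config$metrics, n_permutations = config$n_permutations,
      seed = config$seed + lg
    )
  }
  message(sprintf("serial analysis, lags %s (%.1fs)",
                  paste(config$lags, collapse = ","),
                  as.numeric(Sys.time() - t1, units = "secs")))
  tidy_nc <- purrr::map_dfr(curves, tibble::as_tibble)
  readr::write_csv(tidy_nc, file.path(outdir, "net_change.csv"), progress = FALSE)

  t2 <- Sys.time()
  fit_metrics <- intersect(config$metrics, c("error_rate", "d_prime"))
  fits <- purrr::map_dfr(curves, function(sd_lag) {
    purrr::map_dfr(fit_metrics, function(m) glance(fit_tuning(sd_lag, metric = m)))
  })
  readr::write_csv(fits, file.path(outdir, "tuning_fits.csv"), progress = FALSE)
  message(sprintf("tuning fits (%.1fs)", as.numeric(Sys.time() - t2, units = "secs")))

  overall <- sdt_summary(trials)
  jsonlite::write_json(
    list(overall = as.list(overall), exclusion = unclass(pp$report),
         seed = config$seed, n_permutations = config$n_permutations),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_run_config(config, file.path(outdir, "config.yaml"))
  invisible(list(net_change = curves, fits = fits, report = pp$report))
}
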