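# Run configuration: a flat, documented key set that maps onto
# model_params(), season_calendar(), and build_scenario().

config_defaults <- function() {
  p <- model_params()
  cal <- season_calendar()
  list(
    scenario = "A",
    r3 = 0.35,
    winter_advantage = FALSE,
    eps_winter = 0.1,
    temp_shift_x = 0,
    horizon_years = NA,           # NA -> scenario default (100; 200 for E)
    m = p$m, K = p$K, k = p$k, f = p$f, c = p$c,
    e = p$e, h_max = p$h_max, s_max = p$s_max,
    eps_base = p$eps_base,
    sexual_windows = cal$sexual_windows,
    hatching_window = cal$hatching_window,
    winter_window = cal$winter_window,
    rtol = 1e-8, atol = 1e-12,
    sample_interval = 1,
    delta_detect = 0.01,
    final_decade_years = 10,
    intro_density = 0.001
  )
}

#' Load and validate a run configuration
#'
#' Merges, in order of increasing precedence: the package defaults (the
#' published parameter table and scenario A), an optional YAML file, and
#' inline overrides. Unknown keys and out-of-range values are rejected with
#' the offending key named.
#'
#' @param path Optional path to a YAML file of configuration keys.
#' @param overrides Named list of inline overrides (highest precedence).
#' @return A validated `run_config` (named list).
#' @examples
#' cfg <- load_config(overrides = list(scenario = "B", horizon_years = 5))
#' cfg$scenario
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  apply_layer <- function(cfg, layer, origin) {
    if (length(layer) == 0) return(cfg)
    if (is.null(names(layer)) || any(names(layer) == "")) {
      abort(sprintf("All %s entries must be named.", origin))
    }
    unknown <- setdiff(names(layer), names(cfg))
    if (length(unknown) > 0) {
      abort(sprintf("Unknown configuration key%s in %s: %s.",
                    if (length(unknown) > 1) "s" else "", origin,
                    paste(unknown, collapse = ", ")))
    }
    cfg[names(layer)] <- layer
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Config file '%s' not found.", path))
    file_cfg <- yaml::read_yaml(path)
    cfg <- apply_layer(cfg, file_cfg, sprintf("'%s'", path))
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  fail <- function(key, why) {
    abort(sprintf("Invalid configuration: `%s` %s.", key, why))
  }
  if (!cfg$scenario %in% c("A", "B", "C", "D", "E")) {
    fail("scenario", "must be one of A, B, C, D, E")
  }
  num1 <- function(key, lo = -Inf, hi = Inf) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < lo || v > hi) {
      fail(key, sprintf("must be a single number in [%s, %s]",
                        format(lo), format(hi)))
    }
  }
  num1("r3", lo = 1e-6); num1("m", lo = 0); num1("K", lo = 1e-6)
  num1("k", lo = 0); num1("f", lo = 0); num1("c", lo = 0, hi = 1)
  num1("s_max", lo = 0); num1("eps_base", lo = 0, hi = 1 - 1e-12)
  num1("eps_winter", lo = 0, hi = 1 - 1e-12)
  num1("temp_shift_x"); num1("rtol", lo = 1e-300); num1("atol", lo = 1e-300)
  num1("sample_interval", lo = 1e-6); num1("delta_detect", lo = 1e-300)
  num1("final_decade_years", lo = 1); num1("intro_density", lo = 0)
  if (!is.logical(cfg$winter_advantage) || length(cfg$winter_advantage) != 1L) {
    fail("winter_advantage", "must be TRUE or FALSE")
  }
  e <- unlist(cfg$e)
  if (length(e) != 6L || any(!is.finite(e)) || any(e < 0) || any(e > 1)) {
    fail("e", "must be 6 fractions in [0, 1]")
  }
  h <- unlist(cfg$h_max)
  if (length(h) != 6L || any(!is.finite(h)) || any(h < 0)) {
    fail("h_max", "must be 6 non-negative rates")
  }
  cfg$e <- e
  cfg$h_max <- h
  if (!(length(cfg$horizon_years) == 1L &&
        (is.na(cfg$horizon_years) ||
           (is.numeric(cfg$horizon_years) && cfg$horizon_years >= 1)))) {
    fail("horizon_years", "must be NA (scenario default) or >= 1")
  }
  structure(cfg, class = "run_config")
}

#' Build a scenario specification from a configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A `scenario_spec`.
#' @export
config_to_spec <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  params <- model_params(
    m = cfg$m, K = cfg$K, k = cfg$k, f = cfg$f, c = cfg$c,
    e = cfg$e, h_max = cfg$h_max, s_max = cfg$s_max,
    eps_base = cfg$eps_base, temp_shift_x = cfg$temp_shift_x
  )
  calendar <- season_calendar(
    sexual_windows = cfg$sexual_windows,
    hatching_window = unlist(cfg$hatching_window),
    winter_window = cfg$winter_window
  )
  horizon <- if (is.na(cfg$horizon_years)) NULL else cfg$horizon_years
  build_scenario(
    id = cfg$scenario, r3 = cfg$r3, params = params,
    horizon_years = horizon,
    winter_advantage = cfg$winter_advantage, eps_winter = cfg$eps_winter,
    calendar = calendar, intro_density = cfg$intro_density
  )
}

#' Run a configured simulation and write its artifacts
#'
#' Executes the full pipeline (scenario build, integration, summaries) and
#' writes four files into `out_dir`: `trajectory.csv` (long per-class
#' format), `summary.json` + `summary_annual.csv`, and `manifest.json` (the
#' effective configuration, an md5 of it, package/R versions, and wall-clock
#' time) - enough to re-create the run exactly.
#'
#' @param cfg A `run_config` from [load_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named vector of the file paths written.
#' @examples
#' cfg <- load_config(overrides = list(horizon_years = 2))
#' paths <- run_simulation(cfg, file.path(tempdir(), "runA"))
#' @export
run_simulation <- function(cfg, out_dir) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  t_start <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  spec <- config_to_spec(cfg)
  sim <- simulate_scenario(spec, rtol = cfg$rtol, atol = cfg$atol,
                           sample_interval = cfg$sample_interval)
  report <- summarize_simulation(sim, delta_detect = cfg$delta_detect,
                                 final_decade_years = cfg$final_decade_years)

  traj_path <- file.path(out_dir, "trajectory.csv")
  traj_long <- tidy(sim) |>
    tidyr::pivot_wider(names_from = "stage", values_from = "density") |>
    dplyr::rename(A = "asexual", S = "sexual", E = "ephippia")
  readr::write_csv(traj_long, traj_path)

  sum_paths <- write_summary(report, file.path(out_dir, "summary"))

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null", na = "null")
  cfg_tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, cfg_tmp)
  manifest <- list(
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    package_version = as.character(utils::packageVersion("daphniahybrid")),
    r_version = R.version.string,
    wall_clock_seconds = as.numeric(difftime(Sys.time(), t_start,
                                             units = "secs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(cfg_tmp)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")

  invisible(c(trajectory = traj_path, sum_paths, manifest = manifest_path))
}
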