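#' Annual per-class statistics of a trajectory
#'
#' Aggregates a simulated trajectory into calendar years (year y covers
#' `[365(y-1), 365y)` days). For each year and class the time-weighted
#' (trapezoidal) mean and the maximum of the active density A + S are
#' computed; the class proportion is its time-weighted mean share of the
#' total active density, so proportions sum to one in every year with a
#' positive community.
#'
#' @param x A `daphnia_sim` or its trajectory tibble (columns `time_days`,
#'   `A1..E6`).
#' @param year_length Days per year.
#' @return A tibble with columns `year`, `class_index`, `class_role`,
#'   `mean_active`, `max_active`, `proportion`.
#' @examples
#' sim <- simulate_scenario(build_scenario("A", horizon_years = 2))
#' annual_statistics(sim)
#' @export
annual_statistics <- function(x, year_length = 365) {
  traj <- if (inherits(x, "daphnia_sim")) x$trajectory else x
  if (!is.data.frame(traj) || nrow(traj) == 0) {
    abort("Empty trajectory.")
  }
  t <- traj$time_days
  act <- active_densities(traj)
  n_years <- floor((max(t) + 1e-9) / year_length)
  if (n_years < 1) abort("Trajectory must span at least one full year.")

  roles <- class_roles()
  rows <- vector("list", n_years)
  for (y in seq_len(n_years)) {
    a <- year_length * (y - 1)
    b <- year_length * y
    idx <- which(t >= a - 1e-9 & t <= b + 1e-9)
    tt <- t[idx]
    xx <- act[idx, , drop = FALSE]
    dt <- diff(tt)
    # trapezoidal time-weighted means over [a, b]
    means <- colSums(dt * (xx[-1, , drop = FALSE] +
                             xx[-length(tt), , drop = FALSE]) / 2) / (b - a)
    maxs <- apply(xx, 2, max)
    total <- sum(means)
    props <- if (total > 0) means / total else rep(NA_real_, 6)
    rows[[y]] <- tibble::tibble(
      year = y, class_index = 1:6, class_role = roles,
      mean_active = unname(means), max_active = unname(maxs),
      proportion = unname(props)
    )
  }
  dplyr::bind_rows(rows)
}

#' Establishment, dominance, and persistence metrics
#'
#' Operationalises the establishment language used for this model: a class
#' is *established* in a year when its annual mean active density reaches a
#' detection threshold (default 0.01 individuals per litre - a continuous
#' model never reaches exact zero); *dominant* when its annual proportion
#' exceeds one half; its *persistence* is the run of consecutive established
#' years starting at first establishment.
#'
#' The metrics are computed over whatever years are present in `stats`, so
#' filtering the annual table (e.g. to post-introduction years) re-anchors
#' them.
#'
#' @param stats Annual statistics tibble from [annual_statistics()].
#' @param delta_detect Detection threshold (individuals L^-1).
#' @param final_decade_years Number of trailing years over which the
#'   final-decade mean proportion and maximum density are taken.
#' @return A tibble with one row per class: `first_established`,
#'   `persistence_years`, `n_established_years`, `established_final_year`,
#'   `dominance_onset`, `final_decade_mean_proportion`,
#'   `final_decade_max_active`.
#' @examples
#' sim <- simulate_scenario(build_scenario("A", horizon_years = 2))
#' establishment_metrics(annual_statistics(sim))
#' @export
establishment_metrics <- function(stats, delta_detect = 0.01,
                                  final_decade_years = 10) {
  if (!is.data.frame(stats) || nrow(stats) == 0) abort("Empty annual table.")
  if (!is.finite(delta_detect) || delta_detect <= 0) {
    abort("`delta_detect` must be positive.")
  }
  years <- sort(unique(stats$year))
  last_year <- max(years)
  decade <- years[years > last_year - final_decade_years]

  stats |>
    dplyr::group_by(.data$class_index, .data$class_role) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::summarise(
      first_established = first_true_year(.data$year,
                                          .data$mean_active >= delta_detect),
      persistence_years = consecutive_run(.data$year,
                                          .data$mean_active >= delta_detect),
      n_established_years = sum(.data$mean_active >= delta_detect),
      established_final_year =
        .data$mean_active[which.max(.data$year)] >= delta_detect,
      dominance_onset = first_true_year(
        .data$year, !is.na(.data$proportion) & .data$proportion > 0.5),
      final_decade_mean_proportion =
        mean(.data$proportion[.data$year %in% decade]),
      final_decade_max_active =
        max(.data$max_active[.data$year %in% decade]),
      .groups = "drop"
    )
}

first_true_year <- function(year, flag) {
  hit <- which(flag)
  if (length(hit) == 0) NA_integer_ else as.integer(year[hit[1]])
}

consecutive_run <- function(year, flag) {
  hit <- which(flag)
  if (length(hit) == 0) return(0L)
  run <- 1L
  while (run < length(flag) - hit[1] + 1L && flag[hit[1] + run]) {
    run <- run + 1L
  }
  run
}

#' Growth-rate reduction boundary for F1 persistence
#'
#' Finds, by bisection on the F1 growth rate r3, the largest whole-year
#' reduction of r3 (as a percentage of the reference 0.35 day^-1) at which
#' F1 hybrids are still established in the final simulation year. The
#' predicate must differ between the bracket endpoints (establishment is
#' verified, not assumed, to change across the bracket).
#'
#' @param scenario_builder Function taking `r3` and returning a
#'   [build_scenario()] spec.
#' @param r3_low,r3_high Bracket for r3 (day^-1), `r3_low < r3_high`.
#' @param delta_detect Detection threshold for establishment
#'   (individuals L^-1).
#' @param bisection_tol Bracket width on r3 at which the search stops.
#' @param r3_reference Reference rate against which the reduction is quoted.
#' @param ... Passed to [simulate_scenario()] (e.g. `rtol`, `atol`).
#' @return An object of class `persistence_boundary`: list with `r3_star`
#'   (the smallest established r3 found), `reduction_pct`, and the tibble of
#'   `evaluations`.
#' @examples
#' \dontrun{
#' pb <- persistence_boundary(
#'   function(r3) build_scenario("A", r3 = r3, winter_advantage = TRUE),
#'   0.28, 0.35)
#' pb$reduction_pct
#' }
#' @export
persistence_boundary <- function(scenario_builder, r3_low, r3_high,
                                 delta_detect = 0.01,
                                 bisection_tol = 1e-4,
                                 r3_reference = 0.35,
                                 ...) {
  if (!is.function(scenario_builder)) {
    abort("`scenario_builder` must be a function of r3.")
  }
  if (!(r3_low < r3_high)) abort("Need r3_low < r3_high.")
  evals <- list()
  predicate <- function(r3) {
    sim <- simulate_scenario(scenario_builder(r3), ...)
    met <- establishment_metrics(annual_statistics(sim), delta_detect)
    est <- met$established_final_year[met$class_index == 3L]
    evals[[length(evals) + 1L]] <<- tibble::tibble(r3 = r3, established = est)
    est
  }
  p_lo <- predicate(r3_low)
  p_hi <- predicate(r3_high)
  if (p_lo == p_hi) {
    abort(sprintf(
      "F1 establishment does not change across the bracket: established(%g) = established(%g) = %s.",
      r3_low, r3_high, p_lo))
  }
  if (p_lo && !p_hi) {
    abort("Establishment decreases with r3 across this bracket; expected it to increase.")
  }
  lo <- r3_low
  hi <- r3_high
  while (hi - lo > bisection_tol) {
    mid <- (lo + hi) / 2
    if (predicate(mid)) hi <- mid else lo <- mid
  }
  structure(
    list(
      r3_star = hi,
      reduction_pct = 100 * (r3_reference - hi) / r3_reference,
      r3_reference = r3_reference,
      bisection_tol = bisection_tol,
      delta_detect = delta_detect,
      evaluations = dplyr::bind_rows(evals)
    ),
    class = "persistence_boundary"
  )
}

#' @export
print.persistence_boundary <- function(x, ...) {
  cat(sprintf(
    "<persistence_boundary> r3* = %.4f (largest tolerated reduction %.2f%% of %.2f)\n",
    x$r3_star, x$reduction_pct, x$r3_reference))
  cat(sprintf("  %d simulations, bracket tol %g, delta_detect %g per L\n",
              nrow(x$evaluations), x$bisection_tol, x$delta_detect))
  invisible(x)
}

#' Summarise a simulation into a report
#'
#' @param sim A `daphnia_sim`.
#' @param delta_detect Detection threshold (individuals L^-1).
#' @param final_decade_years Trailing years for final-decade summaries.
#' @return A `summary_report`: list with `annual` (per-year per-class
#'   tibble), `classes` (per-class metrics), and `meta`.
#' @examples
#' sim <- simulate_scenario(build_scenario("A", horizon_years = 2))
#' rep <- summarize_simulation(sim)
#' @export
summarize_simulation <- function(sim, delta_detect = 0.01,
                                 final_decade_years = 10) {
  if (!inherits(sim, "daphnia_sim")) abort("`sim` must be a daphnia_sim.")
  annual <- annual_statistics(sim, sim$spec$calendar$year_length)
  classes <- establishment_metrics(annual, delta_detect, final_decade_years)
  structure(
    list(
      annual = annual,
      classes = classes,
      meta = list(
        schema_version = "1.0",
        scenario = sim$spec$id,
        r3 = sim$spec$r3,
        winter_advantage = sim$spec$winter_advantage,
        eps_winter_F1 = sim$spec$params$eps_winter_F1,
        temp_shift_x = sim$spec$params$temp_shift_x,
        horizon_years = sim$spec$horizon_years,
        delta_detect = delta_detect,
        final_decade_years = final_decade_years,
        solver = sim$solver,
        version = sim$version
      )
    ),
    class = "summary_report"
  )
}

#' Write / read a summary report
#'
#' `write_summary()` writes `<path>.json` (metadata and per-class metrics)
#' and `<path>_annual.csv` (the per-year table); `read_summary()` restores a
#' report from those files, round-trip stable.
#'
#' @param report A `summary_report` from [summarize_simulation()].
#' @param path Output path prefix (without extension).
#' @return `write_summary()` invisibly returns the two file paths;
#'   `read_summary()` returns a `summary_report`.
#' @examples
#' sim <- simulate_scenario(build_scenario("A", horizon_years = 2))
#' p <- file.path(tempdir(), "runA")
#' write_summary(summarize_simulation(sim), p)
#' rep2 <- read_summary(p)
#' @export
write_summary <- function(report, path) {
  if (!inherits(report, "summary_report")) {
    abort("`report` must be a summary_report.")
  }
  if (nrow(report$annual) == 0) abort("Refusing to write an empty report.")
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, "_annual.csv")
  ok <- tryCatch({
    jsonlite::write_json(
      list(meta = report$meta, classes = report$classes),
      json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
    )
    readr::write_csv(report$annual, csv_path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("Failed to write summary at '%s': %s", path,
                  conditionMessage(ok)))
  }
  invisible(c(json = json_path, csv = csv_path))
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, "_annual.csv")
  if (!file.exists(json_path) || !file.exists(csv_path)) {
    abort(sprintf("No summary found at '%s'.", path))
  }
  raw <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  classes <- tibble::as_tibble(raw$classes)
  classes$first_established <- as.integer(classes$first_established)
  classes$dominance_onset <- as.integer(classes$dominance_onset)
  classes$persistence_years <- as.integer(classes$persistence_years)
  classes$n_established_years <- as.integer(classes$n_established_years)
  annual <- readr::read_csv(csv_path, show_col_types = FALSE,
                            progress = FALSE)
  structure(
    list(annual = annual, classes = classes, meta = raw$meta),
    class = "summary_report"
  )
}
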