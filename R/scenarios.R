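#' Growth-rate schedules
#'
#' The five competition scenarios differ only in how the parental growth
#' rates r_1 and r_2 vary in time. A schedule holds one rule per parental
#' species plus the constant F1 rate `r3` and F2 rate `r6`; backcross rates
#' are always the instantaneous mean of the respective parental rate and
#' `r3`.
#'
#' Rule kinds: `rule_constant(value)`, `rule_biennial(first, second,
#' hold_years)` (each value held for `hold_years` years, then swapped), and
#' `rule_within_year(first, second, switch_doy)` (the first value before
#' day-of-year `switch_doy`, the second after, every year).
#'
#' @param rule1,rule2 Rules for parental species 1 and 2.
#' @param r3 F1 hybrid growth rate (day^-1), constant.
#' @param r6 F2 hybrid growth rate (day^-1), constant.
#' @param year_length Days per year.
#' @return An object of class `growth_schedule`.
#' @examples
#' sch <- growth_schedule(rule_constant(0.35), rule_constant(0.30))
#' growth_rate_at(sch, 5, 0) # (0.30 + 0.35) / 2
#' @export
growth_schedule <- function(rule1, rule2, r3 = 0.35, r6 = 0.30,
                            year_length = 365) {
  for (v in c(r3, r6)) {
    if (!is.finite(v) || v < 0) abort("Growth rates must be non-negative.")
  }
  structure(
    list(rule1 = rule1, rule2 = rule2, r3 = r3, r6 = r6,
         year_length = year_length),
    class = "growth_schedule"
  )
}

#' @rdname growth_schedule
#' @param value,first,second Growth rates (day^-1).
#' @param hold_years Years each value is held before swapping.
#' @param switch_doy Day-of-year at which the within-year rule switches
#'   (half-open convention: `[0, switch_doy)` takes `first`).
#' @export
rule_constant <- function(value) {
  if (!is.finite(value) || value < 0) abort("Growth rates must be non-negative.")
  list(kind = "constant", value = value)
}

#' @rdname growth_schedule
#' @export
rule_biennial <- function(first, second, hold_years = 2) {
  if (any(!is.finite(c(first, second))) || any(c(first, second) < 0)) {
    abort("Growth rates must be non-negative.")
  }
  list(kind = "biennial", values = c(first, second), hold_years = hold_years)
}

#' @rdname growth_schedule
#' @export
rule_within_year <- function(first, second, switch_doy = 165) {
  if (any(!is.finite(c(first, second))) || any(c(first, second) < 0)) {
    abort("Growth rates must be non-negative.")
  }
  list(kind = "within_year", values = c(first, second), switch_doy = switch_doy)
}

eval_rule <- function(rule, t, year_length) {
  switch(rule$kind,
    constant = rep(rule$value, length(t)),
    biennial = {
      phase <- floor(t / (year_length * rule$hold_years)) %% 2
      rule$values[phase + 1]
    },
    within_year = {
      doy <- t %% year_length
      ifelse(doy < rule$switch_doy, rule$values[1], rule$values[2])
    },
    abort(sprintf("Unknown growth-rate rule kind '%s'.", rule$kind))
  )
}

#' Evaluate a growth-rate schedule
#'
#' @param schedule A [growth_schedule()].
#' @param j Class index 1-6 (scalar).
#' @param t Time in days (vectorised).
#' @return r_j(t) in day^-1.
#' @export
growth_rate_at <- function(schedule, j, t) {
  if (!j %in% 1:6) abort("`j` must be a class index 1-6.")
  yl <- schedule$year_length
  switch(as.character(j),
    "1" = eval_rule(schedule$rule1, t, yl),
    "2" = eval_rule(schedule$rule2, t, yl),
    "3" = rep(schedule$r3, length(t)),
    "4" = (eval_rule(schedule$rule1, t, yl) + schedule$r3) / 2,
    "5" = (eval_rule(schedule$rule2, t, yl) + schedule$r3) / 2,
    "6" = rep(schedule$r6, length(t))
  )
}

# All six rates at a single time point.
growth_rates <- function(schedule, t) {
  vapply(1:6, function(j) growth_rate_at(schedule, j, t), numeric(1))
}

#' Build a competition scenario
#'
#' Assembles a full scenario specification: growth-rate schedule, initial
#' densities, introduction events, horizon, and parameters. The five
#' scenarios are:
#' * `A` - both parental species grow at 0.35 day^-1;
#' * `B` - species 1 grows faster (r1 = 0.35, r2 = 0.30);
#' * `C` - the parental rates (0.30 vs 0.35) swap every two years;
#' * `D` - the parental rates swap within each year at day 166 (species 1
#'   starts low, species 2 starts high);
#' * `E` - species 1 alone (r1 = 0.30) for 100 years, then species 2 enters
#'   at 0.001 L^-1 with r2 = 0.35; the horizon doubles to 200 years.
#'
#' In every scenario r6 = 0.30 (hybrid breakdown), r3 is a free knob
#' (default 0.35), and the backcross rates are the running means of the
#' respective parental rate and r3. Scenarios A-D start from 0.001
#' individuals L^-1 of each parental species; all other classes start empty.
#'
#' @param id Scenario identifier, one of `"A"`..`"E"`.
#' @param r3 F1 growth rate (day^-1).
#' @param params [model_params()]. Its `eps_winter_F1` is overwritten
#'   according to `winter_advantage`.
#' @param horizon_years Simulation horizon; default 100 years (200 for
#'   scenario E).
#' @param winter_advantage If `TRUE`, the F1 class uses `eps_winter`
#'   during the winter window; if `FALSE` (default), F1 has no overwintering
#'   advantage.
#' @param eps_winter Winter amplitude for F1 when the advantage is on
#'   (default 0.1, the strongest level studied: about 80% higher growth at
#'   the winter minimum).
#' @param calendar [season_calendar()].
#' @param intro_density Colonisation/introduction density (individuals L^-1).
#' @return An object of class `scenario_spec`.
#' @examples
#' spec <- build_scenario("A", winter_advantage = TRUE)
#' growth_rate_at(spec$schedule, 4, 0)
#' @export
build_scenario <- function(id,
                           r3 = 0.35,
                           params = model_params(),
                           horizon_years = NULL,
                           winter_advantage = FALSE,
                           eps_winter = 0.1,
                           calendar = season_calendar(),
                           intro_density = 0.001) {
  if (!is.character(id) || length(id) != 1L || !id %in% c("A", "B", "C", "D", "E")) {
    abort("`id` must be one of \"A\", \"B\", \"C\", \"D\", \"E\".")
  }
  if (!is.finite(r3) || r3 <= 0) abort("`r3` must be positive.")
  yl <- calendar$year_length

  schedule <- switch(id,
    A = growth_schedule(rule_constant(0.35), rule_constant(0.35),
                        r3 = r3, year_length = yl),
    B = growth_schedule(rule_constant(0.35), rule_constant(0.30),
                        r3 = r3, year_length = yl),
    C = growth_schedule(rule_biennial(0.30, 0.35), rule_biennial(0.35, 0.30),
                        r3 = r3, year_length = yl),
    D = growth_schedule(rule_within_year(0.30, 0.35, switch_doy = 165),
                        rule_within_year(0.35, 0.30, switch_doy = 165),
                        r3 = r3, year_length = yl),
    E = growth_schedule(rule_constant(0.30), rule_constant(0.35),
                        r3 = r3, year_length = yl)
  )

  if (is.null(horizon_years)) horizon_years <- if (id == "E") 200L else 100L

  initial <- if (id == "E") {
    community_state(A = c(intro_density, 0, 0, 0, 0, 0))
  } else {
    community_state(A = c(intro_density, intro_density, 0, 0, 0, 0))
  }

  introductions <- if (id == "E") {
    tibble::tibble(
      time_days = 100 * yl, class_index = 2L, density = intro_density
    )
  } else {
    tibble::tibble(
      time_days = numeric(0), class_index = integer(0), density = numeric(0)
    )
  }
  if (nrow(introductions) > 0 &&
      any(introductions$time_days > horizon_years * yl)) {
    abort("Introduction events must lie within the horizon.")
  }

  params$eps_winter_F1 <- if (isTRUE(winter_advantage)) eps_winter else params$eps_base

  structure(
    list(
      id = id,
      schedule = schedule,
      params = params,
      calendar = calendar,
      initial_state = initial,
      introductions = introductions,
      horizon_years = horizon_years,
      horizon_days = horizon_years * yl,
      winter_advantage = isTRUE(winter_advantage),
      r3 = r3,
      r3_reduction_pct = 100 * (0.35 - r3) / 0.35
    ),
    class = "scenario_spec"
  )
}

#' Apply an annual temperature offset to a scenario
#'
#' Sets the temperature offset `x` on the scenario's parameters; the Q10
#' factor `q = 2^(x/10)` then scales every class's logistic growth term
#' during integration. `x = 0` leaves the dynamics unchanged.
#'
#' @param spec A [build_scenario()] specification.
#' @param x Temperature offset in degrees C (the study used -5, -3, 0, +3,
#'   +5).
#' @return The modified `scenario_spec`.
#' @examples
#' spec <- apply_temperature(build_scenario("A"), x = -5)
#' temperature_factor(spec$params$temp_shift_x)
#' @export
apply_temperature <- function(spec, x) {
  if (!inherits(spec, "scenario_spec")) abort("`spec` must be a scenario_spec.")
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort("`x` must be a single finite number.")
  }
  spec$params$temp_shift_x <- x
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec %s> r3 = %g (%.1f%% below 0.35), horizon = %d years\n",
    x$id, x$r3, x$r3_reduction_pct, x$horizon_years))
  cat(sprintf("  winter advantage: %s (eps_winter_F1 = %g), temp shift x = %g\n",
              if (x$winter_advantage) "on" else "off",
              x$params$eps_winter_F1, x$params$temp_shift_x))
  if (nrow(x$introductions) > 0) {
    cat(sprintf("  introductions: class %s at day %s (+%g per L)\n",
                paste(x$introductions$class_index, collapse = ","),
                paste(x$introductions$time_days, collapse = ","),
                x$introductions$density[1]))
  }
  invisible(x)
}
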