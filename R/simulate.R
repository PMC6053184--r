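#' Event times at which the forcing is discontinuous
#'
#' The switching, hatching, winter-amplitude, and scenario growth-rate
#' functions are piecewise constant; the integrator restarts at every edge so
#' that no discontinuity is crossed inside an adaptive step. Returned times
#' are all window edges of every simulated year, the year boundaries, any
#' within-year or biennial schedule switches, all introduction events, and
#' the two horizon endpoints.
#'
#' @param spec A [build_scenario()] specification.
#' @return Sorted, deduplicated numeric vector of times in days, spanning
#'   `[0, horizon_days]`.
#' @examples
#' bp <- breakpoints(build_scenario("A", horizon_years = 1))
#' @export
breakpoints <- function(spec) {
  if (!inherits(spec, "scenario_spec")) abort("`spec` must be a scenario_spec.")
  cal <- spec$calendar
  yl <- cal$year_length
  horizon <- spec$horizon_days

  edges_doy <- c(
    unlist(cal$sexual_windows),
    cal$hatching_window,
    unlist(cal$winter_window)
  )
  for (rule in list(spec$schedule$rule1, spec$schedule$rule2)) {
    if (rule$kind == "within_year") edges_doy <- c(edges_doy, rule$switch_doy)
  }
  edges_doy <- sort(unique(edges_doy %% yl))

  n_years <- ceiling(horizon / yl)
  year_starts <- yl * (0:(n_years - 1))
  times <- c(
    outer(edges_doy, year_starts, `+`),
    yl * (0:n_years),
    spec$introductions$time_days,
    0, horizon
  )
  for (rule in list(spec$schedule$rule1, spec$schedule$rule2)) {
    if (rule$kind == "biennial") {
      hold <- yl * rule$hold_years
      times <- c(times, seq(0, horizon, by = hold))
    }
  }
  times <- sort(unique(times))
  times[times >= 0 & times <= horizon]
}

#' Add individuals of one class to a community state
#'
#' An introduction is an impulse: the asexual density of class `j` increases
#' by `density`; the other 17 state variables are untouched.
#'
#' @param state Named numeric state vector of length 18.
#' @param j Class index 1-6.
#' @param density Non-negative density to add (individuals L^-1).
#' @return The modified state vector.
#' @examples
#' introduce_class(community_state(), 2, 0.001)
#' @export
introduce_class <- function(state, j, density) {
  assert_state(state)
  if (!j %in% 1:6) abort("`j` must be a class index 1-6.")
  if (!is.finite(density) || density < 0) {
    abort("`density` must be non-negative.")
  }
  state[j] <- state[j] + density
  state
}

#' Simulate a scenario
#'
#' Integrates the community ODE system over the scenario horizon. The
#' adaptive integrator (lsoda) is restarted at every [breakpoints()] time so
#' that the piecewise-constant forcing (sexual windows, hatching window,
#' winter amplitude, growth-rate switches) never changes inside a step;
#' introduction events are applied as impulses at the segment start. The
#' model is deterministic: identical inputs and settings reproduce the
#' trajectory bit for bit.
#'
#' Sampled states lying in `(-neg_tol, 0)` - harmless integrator undershoot
#' of an exponentially decaying variable - are clamped to 0 in the output
#' only (the integrator state itself is untouched); anything more negative
#' raises an error naming the segment.
#'
#' @param spec A [build_scenario()] specification.
#' @param rtol,atol Relative and absolute integration tolerances
#'   (per variable, individuals L^-1).
#' @param sample_interval Output sampling step in days (breakpoint times are
#'   always included as well).
#' @param engine `"compiled"` (default, C right-hand side) or `"R"`
#'   (reference [community_derivatives()]; much slower, used for
#'   cross-checks).
#' @param neg_tol Clamping threshold for negative output samples.
#' @return A `daphnia_sim` object: list with `trajectory` (tibble with
#'   `time_days` and the 18 state columns), `spec`, and `solver` settings.
#' @examples
#' sim <- simulate_scenario(build_scenario("A", horizon_years = 2))
#' sim
#' @export
simulate_scenario <- function(spec,
                              rtol = 1e-8,
                              atol = 1e-12,
                              sample_interval = 1,
                              engine = c("compiled", "R"),
                              neg_tol = 1e-9) {
  if (!inherits(spec, "scenario_spec")) abort("`spec` must be a scenario_spec.")
  engine <- match.arg(engine)
  if (rtol <= 0 || atol <= 0) abort("Tolerances must be positive.")
  params <- spec$params
  cal <- spec$calendar
  q <- temperature_factor(params$temp_shift_x)
  bp <- breakpoints(spec)
  grid <- seq(0, spec$horizon_days, by = sample_interval)

  y <- spec$initial_state
  intro <- spec$introductions
  out_list <- vector("list", length(bp) - 1L)

  rates_fn <- function(t) growth_rates(spec$schedule, t)
  r_func <- function(t, y, p) {
    list(community_derivatives(t, y, params, cal, rates_fn, q))
  }

  for (i in seq_len(length(bp) - 1L)) {
    t0 <- bp[i]
    t1 <- bp[i + 1L]
    if (nrow(intro) > 0) {
      hit <- which(abs(intro$time_days - t0) < 1e-9)
      for (ev in hit) {
        y <- introduce_class(y, intro$class_index[ev], intro$density[ev])
      }
    }
    tm <- (t0 + t1) / 2
    pts <- unique(c(t0, grid[grid > t0 & grid < t1], t1))

    if (engine == "compiled") {
      doy <- day_of_year(tm, cal$year_length)
      winter <- in_windows(doy, cal$winter_window)
      eps_f1 <- if (winter) params$eps_winter_F1 else params$eps_base
      s_now <- params$s_max * in_windows(doy, cal$sexual_windows)
      h_now <- params$h_max * in_windows(doy, list(cal$hatching_window))
      pv <- pack_parms(growth_rates(spec$schedule, tm), q, params$eps_base,
                       eps_f1, s_now, h_now, params)
      seg <- deSolve::lsoda(
        y = y, times = pts, func = "dlh_derivs", parms = pv,
        dllname = "daphniahybrid", initfunc = "dlh_initmod",
        rtol = rtol, atol = atol
      )
    } else {
      # tcrit stops internal steps at the segment end, so the window-gated
      # rates stay constant over every step the solver actually takes
      seg <- deSolve::lsoda(
        y = y, times = pts, func = r_func, parms = NULL,
        rtol = rtol, atol = atol, tcrit = t1
      )
    }
    seg <- unclass(seg)
    if (nrow(seg) < length(pts) || any(!is.finite(seg[, -1]))) {
      abort(sprintf(
        "Integration failed on [%g, %g] days (scenario %s).", t0, t1, spec$id))
    }
    y <- setNames(seg[nrow(seg), -1], state_names())
    mn <- min(seg[, -1])
    if (mn < -neg_tol) {
      abort(sprintf(
        "State went negative (%.3e) on [%g, %g] days (scenario %s).",
        mn, t0, t1, spec$id))
    }
    seg[, -1][seg[, -1] < 0] <- 0
    out_list[[i]] <- if (i == 1L) seg else seg[-1L, , drop = FALSE]
  }

  out <- do.call(rbind, out_list)
  colnames(out) <- c("time_days", state_names())
  trajectory <- tibble::as_tibble(as.data.frame(out))

  structure(
    list(
      trajectory = trajectory,
      spec = spec,
      solver = list(
        method = "lsoda (piecewise)", engine = engine,
        rtol = rtol, atol = atol,
        sample_interval = sample_interval, neg_tol = neg_tol
      ),
      version = as.character(utils::packageVersion("daphniahybrid"))
    ),
    class = "daphnia_sim"
  )
}

#' @export
print.daphnia_sim <- function(x, ...) {
  cat(sprintf(
    "<daphnia_sim> scenario %s, %d years, %d samples (%s engine)\n",
    x$spec$id, x$spec$horizon_years, nrow(x$trajectory), x$solver$engine))
  final <- x$trajectory[nrow(x$trajectory), ]
  act <- active_densities(x$trajectory)
  cat(sprintf("  final day %g: total active %.3f per L\n",
              final$time_days, sum(act[nrow(act), ])))
  invisible(x)
}

# A + S per class as an n x 6 matrix.
active_densities <- function(trajectory) {
  as.matrix(trajectory[paste0("A", 1:6)]) +
    as.matrix(trajectory[paste0("S", 1:6)])
}
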