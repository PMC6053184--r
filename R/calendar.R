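#' Seasonal calendar of within-year event windows
#'
#' Defines the within-year windows that drive the piecewise forcing: two
#' sexual-reproduction windows (two weeks each, May and September), the spring
#' hatching window for ephippia, and the winter window during which the F1
#' class may use its own seasonal amplitude. All windows are half-open
#' day-of-year intervals `[start, end)` on a 365-day year, so the printed day
#' d of the field calendar is the unit interval `[d-1, d)`.
#'
#' @param year_length Days per year (365; no leap years).
#' @param sexual_windows List of `c(start, end)` half-open day-of-year
#'   intervals during which asexual females switch to sexual reproduction.
#'   Default: days 151-165 and 273-287, i.e. `[150,165)` and `[272,287)`.
#' @param hatching_window `c(start, end)`: ephippia hatch during this window.
#'   Default days 119-120, i.e. `[118,120)`.
#' @param winter_window List of `c(start, end)` intervals making up winter
#'   (may wrap the year boundary as two pieces). Default: 120 days,
#'   `[304,365)` and `[0,59)` (Nov 1 - Feb 28).
#'
#' @return An object of class `season_calendar`.
#' @examples
#' cal <- season_calendar()
#' @export
season_calendar <- function(year_length = 365,
                            sexual_windows = list(c(150, 165), c(272, 287)),
                            hatching_window = c(118, 120),
                            winter_window = list(c(304, 365), c(0, 59))) {
  check_window <- function(w) {
    if (length(w) != 2L || !all(is.finite(w)) || w[1] < 0 ||
        w[2] > year_length || w[1] >= w[2]) {
      abort("Calendar windows must be c(start, end) with 0 <= start < end <= year_length.")
    }
    w
  }
  if (!is.list(sexual_windows)) sexual_windows <- list(sexual_windows)
  if (!is.list(winter_window)) winter_window <- list(winter_window)
  sexual_windows <- lapply(sexual_windows, check_window)
  winter_window <- lapply(winter_window, check_window)
  check_window(hatching_window)
  structure(
    list(
      year_length = year_length,
      sexual_windows = sexual_windows,
      hatching_window = hatching_window,
      winter_window = winter_window
    ),
    class = "season_calendar"
  )
}

#' Map simulation time to day-of-year
#'
#' @param t Simulation time in days (non-negative).
#' @param year_length Days per year.
#' @return `t mod year_length`, in `[0, year_length)`.
#' @examples
#' day_of_year(36650) # 150
#' @export
day_of_year <- function(t, year_length = 365) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  t %% year_length
}

in_windows <- function(doy, windows) {
  hit <- rep(FALSE, length(doy))
  for (w in windows) {
    hit <- hit | (doy >= w[1] & doy < w[2])
  }
  hit
}

#' @export
print.season_calendar <- function(x, ...) {
  fmt <- function(ws) paste(vapply(ws, function(w)
    sprintf("[%g,%g)", w[1], w[2]), ""), collapse = " u ")
  cat("<season_calendar> year =", x$year_length, "days\n")
  cat("  sexual:  ", fmt(x$sexual_windows), "\n")
  cat("  hatching:", fmt(list(x$hatching_window)), "\n")
  cat("  winter:  ", fmt(x$winter_window), "\n")
  invisible(x)
}
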