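#' Seasonal forcing function
#'
#' The annual cycle of light and temperature is represented by the periodic
#' multiplier
#' \deqn{\sigma(t) = \frac{1 - \varepsilon \cos(2\pi t/365)}{1+\varepsilon},}
#' which scales both the growth rates and the carrying capacity. It reaches
#' its maximum 1 at mid-year (t = 182.5 mod 365) and its minimum
#' \eqn{(1-\varepsilon)/(1+\varepsilon)} at the turn of the year.
#'
#' @param t Time in days (vectorised).
#' @param eps Amplitude \eqn{\varepsilon \in [0, 1)}.
#' @param year_length Days per year.
#' @return Numeric vector of sigma values in
#'   `[(1 - eps)/(1 + eps), 1]`.
#' @examples
#' seasonal_sigma(182.5, 0.7) # 1
#' seasonal_sigma(365, 0.7)   # 0.3 / 1.7
#' @export
seasonal_sigma <- function(t, eps, year_length = 365) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) ||
      eps < 0 || eps >= 1) {
    abort("`eps` must lie in [0, 1).")
  }
  (1 - eps * cos(2 * pi * t / year_length)) / (1 + eps)
}

#' Class-specific seasonal forcing
#'
#' All classes share the baseline seasonal function except the F1 hybrid
#' class (j = 3), which during the winter window uses `eps_winter_F1`. A
#' lowered winter amplitude raises the F1 growth multiplier while the
#' parental classes collapse seasonally, modelling better overwinter survival
#' of F1 as parthenogenetic females.
#'
#' @param t Time in days (vectorised).
#' @param j Class index 1-6 (scalar).
#' @param params [model_params()].
#' @param calendar [season_calendar()].
#' @return Numeric vector of sigma values.
#' @examples
#' p <- model_params(eps_winter_F1 = 0.1)
#' class_sigma(330, 3, p, season_calendar())
#' @export
class_sigma <- function(t, j, params, calendar = season_calendar()) {
  if (!j %in% 1:6) abort("`j` must be a class index 1-6.")
  sig <- seasonal_sigma(t, params$eps_base, calendar$year_length)
  if (j == 3L && params$eps_winter_F1 != params$eps_base) {
    doy <- day_of_year(t, calendar$year_length)
    winter <- in_windows(doy, calendar$winter_window)
    if (any(winter)) {
      sig[winter] <- seasonal_sigma(t[winter], params$eps_winter_F1,
                                    calendar$year_length)
    }
  }
  sig
}

#' Switching rate to sexual reproduction
#'
#' Asexual females switch to sexual reproduction at rate `s_max` during the
#' two sexual windows (the same for all classes), and not at all otherwise.
#'
#' @param t Time in days (vectorised).
#' @param calendar [season_calendar()].
#' @param s_max Switching rate during the windows (day^-1).
#' @return s(t), day^-1.
#' @examples
#' switching_rate(155, season_calendar()) # 0.5
#' @export
switching_rate <- function(t, calendar = season_calendar(), s_max = 0.5) {
  if (s_max < 0) abort("`s_max` must be non-negative.")
  doy <- day_of_year(t, calendar$year_length)
  s_max * in_windows(doy, calendar$sexual_windows)
}

#' Hatching rate from ephippia
#'
#' Ephippia hatch only during the short photoperiod-driven spring window, at
#' a class-specific rate; each ephippium releases two asexual females
#' (it contains two embryos).
#'
#' @param t Time in days (vectorised).
#' @param j Class index 1-6 (scalar).
#' @param calendar [season_calendar()].
#' @param h_max Length-6 vector of in-window hatching rates (day^-1).
#' @return h_j(t), day^-1.
#' @examples
#' hatching_rate(119.5, 1) # 0.1
#' hatching_rate(119.5, 3) # 0.05
#' @export
hatching_rate <- function(t, j, calendar = season_calendar(),
                          h_max = model_params()$h_max) {
  if (!j %in% 1:6) abort("`j` must be a class index 1-6.")
  if (any(h_max < 0)) abort("`h_max` must be non-negative.")
  doy <- day_of_year(t, calendar$year_length)
  h_max[j] * in_windows(doy, list(calendar$hatching_window))
}

#' Q10 temperature scaling factor
#'
#' An offset of the annual mean temperature by `x` degrees C multiplies all
#' logistic growth terms by the Q10-derived factor `q = 2^(x/10)` (a Q10 of 2
#' for Daphnia growth). Only the growth term is scaled; switching, mortality,
#' hatching, and ephippium production are unaffected.
#'
#' @param x Temperature offset in degrees C (vectorised).
#' @return q = 2^(x/10).
#' @examples
#' temperature_factor(c(-5, 0, 10))
#' @export
temperature_factor <- function(x) {
  if (any(!is.finite(x))) abort("`x` must be finite.")
  2^(x / 10)
}
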