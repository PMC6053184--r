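#' Right-hand side of the community ODE system
#'
#' Time derivatives of the 18 state variables. For each class j:
#' \deqn{\dot A_j = q\, r_j(t)\, \sigma_j(t)\, A_j
#'   \left(1 - \frac{\sum_i (A_i + S_i)}{\sigma(t) K}\right)
#'   - s(t) A_j + 2 h_j(t) E_j}
#' \deqn{\dot S_j = s(t) A_j - m S_j}
#' \deqn{\dot E_j = (1 - e_j)\, f\, k\, \phi_j(t) - h_j(t) E_j}
#' where \eqn{\sigma_j} is the class-specific seasonal multiplier
#' ([class_sigma()]; only F1 may differ in winter), the density bracket by
#' default uses the shared baseline \eqn{\sigma} (the carrying capacity is a
#' common resource), \eqn{s(t)} and \eqn{h_j(t)} are the window-gated
#' switching and hatching rates, \eqn{\phi} is the mating kernel
#' ([mating_output()]) evaluated at the current S1, S2, S3, and
#' \eqn{q = 2^{x/10}} is the Q10 temperature factor.
#'
#' This pure-R evaluation is the reference implementation; the integrator
#' normally uses an equivalent compiled version for speed.
#'
#' @param t Time in days (scalar).
#' @param state Named or unnamed numeric vector of length 18, ordered
#'   `A1..A6, S1..S6, E1..E6`.
#' @param params [model_params()].
#' @param calendar [season_calendar()].
#' @param rates Either a numeric vector of 6 growth rates r_j (day^-1) or a
#'   function `f(t)` returning one (e.g. a scenario schedule closure).
#' @param q Temperature factor; defaults to
#'   `temperature_factor(params$temp_shift_x)`.
#' @return Named numeric vector of length 18 of time derivatives.
#' @examples
#' st <- community_state(A = c(1, 1, 0, 0, 0, 0))
#' community_derivatives(0, st, model_params(), rates = rep(0.35, 6))
#' @export
community_derivatives <- function(t, state, params,
                                  calendar = season_calendar(),
                                  rates,
                                  q = temperature_factor(params$temp_shift_x)) {
  assert_state(state)
  r <- if (is.function(rates)) rates(t) else rates
  if (length(r) != 6L || any(!is.finite(r)) || any(r < 0)) {
    abort("Growth rates must be 6 non-negative numbers.")
  }
  A <- state[1:6]
  S <- state[7:12]
  E <- state[13:18]

  doy <- day_of_year(t, calendar$year_length)
  sig_base <- seasonal_sigma(t, params$eps_base, calendar$year_length)
  winter <- in_windows(doy, calendar$winter_window)
  sig <- rep(sig_base, 6)
  if (winter && params$eps_winter_F1 != params$eps_base) {
    sig[3] <- seasonal_sigma(t, params$eps_winter_F1, calendar$year_length)
  }
  sig_den <- if (params$sigma_bracket == "class") sig else rep(sig_base, 6)

  s_now <- params$s_max * in_windows(doy, calendar$sexual_windows)
  h_now <- params$h_max * in_windows(doy, list(calendar$hatching_window))

  total <- sum(A + S)
  phi <- mating_output(S[1], S[2], S[3], params$c)

  dA <- q * r * sig * A * (1 - total / (sig_den * params$K)) -
    s_now * A + 2 * h_now * E
  dS <- s_now * A - params$m * S
  dE <- (1 - params$e) * params$f * params$k * phi - h_now * E

  setNames(c(dA, dS, dE), state_names())
}

# Pack the per-segment constants for the compiled right-hand side.
# Layout (length 28): r[6], q, eps_base, eps_F1_effective, s_now, h_now[6],
# m, K, k, f, c, e[6], bracket_class_flag.
pack_parms <- function(r, q, eps_base, eps_f1_eff, s_now, h_now, params) {
  c(r, q, eps_base, eps_f1_eff, s_now, h_now,
    params$m, params$K, params$k, params$f, params$c, params$e,
    as.numeric(params$sigma_bracket == "class"))
}
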