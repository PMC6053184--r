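#' Model parameters
#'
#' Constructs the full parameter set of the community model. Defaults are the
#' published baseline for the *Daphnia longispina* species complex: hybrid
#' classes have a 50% lower hatching rate from ephippia and a higher fraction
#' of empty (egg-free) ephippia than the parental species, and three quarters
#' of sexual individuals mate within their own class.
#'
#' @param m Mortality rate of sexual females (day^-1).
#' @param K Carrying capacity shared by all classes, asexual plus sexual
#'   individuals (individuals L^-1).
#' @param k Ephippia produced per sexual encounter (dimensionless).
#' @param f Ephippia produced per day per encounter propensity (day^-1).
#' @param c Fraction of sexual individuals that mate strictly within their own
#'   class; the remaining `1 - c` mate at random across classes 1-3.
#' @param e Length-6 vector: fraction of empty ephippia per class, in `[0,1]`.
#' @param h_max Length-6 vector: hatching rate from ephippia during the spring
#'   hatching window (day^-1).
#' @param s_max Rate at which asexual females switch to sexual reproduction
#'   during the two sexual windows (day^-1).
#' @param eps_base Amplitude of the seasonal forcing function, in `[0,1)`.
#' @param eps_winter_F1 Seasonal amplitude used for the F1 class during the
#'   winter window; values below `eps_base` give F1 an overwintering
#'   advantage as parthenogenetic females. Defaults to `eps_base` (no
#'   advantage).
#' @param temp_shift_x Annual mean temperature offset x (degrees C); growth is
#'   scaled by the Q10 factor `2^(x/10)` (see [temperature_factor()]).
#' @param sigma_bracket Which seasonal amplitude scales the carrying capacity
#'   in the logistic density bracket: `"base"` (default; K is a shared
#'   resource, always scaled with `eps_base`) or `"class"` (each class uses
#'   its own sigma, for sensitivity checks).
#'
#' @return An object of class `daphnia_params` (a named list).
#' @examples
#' p <- model_params()
#' p$K
#' @export
model_params <- function(m = 0.15,
                         K = 150,
                         k = 1,
                         f = 0.14,
                         c = 0.75,
                         e = c(0.7, 0.7, 0.8, 0.75, 0.75, 0.85),
                         h_max = c(0.1, 0.1, 0.05, 0.05, 0.05, 0.05),
                         s_max = 0.5,
                         eps_base = 0.7,
                         eps_winter_F1 = eps_base,
                         temp_shift_x = 0,
                         sigma_bracket = c("base", "class")) {
  sigma_bracket <- match.arg(sigma_bracket)
  check_scalar <- function(x, name, lo = 0, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
      abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                    name, format(lo), format(hi)))
    }
  }
  check_scalar(m, "m"); check_scalar(K, "K"); check_scalar(k, "k")
  check_scalar(f, "f"); check_scalar(c, "c", 0, 1)
  check_scalar(s_max, "s_max")
  check_scalar(eps_base, "eps_base", 0, 1)
  check_scalar(eps_winter_F1, "eps_winter_F1", 0, 1)
  if (eps_base >= 1 || eps_winter_F1 >= 1) {
    abort("Seasonal amplitudes must lie in [0, 1).")
  }
  if (!is.numeric(x = temp_shift_x) || length(temp_shift_x) != 1L ||
      !is.finite(temp_shift_x)) {
    abort("`temp_shift_x` must be a single finite number.")
  }
  if (length(e) != 6L || any(!is.finite(e)) || any(e < 0) || any(e > 1)) {
    abort("`e` must be 6 empty-ephippium fractions in [0, 1].")
  }
  if (length(h_max) != 6L || any(!is.finite(h_max)) || any(h_max < 0)) {
    abort("`h_max` must be 6 non-negative hatching rates.")
  }
  structure(
    list(
      m = m, K = K, k = k, f = f, c = c,
      e = unname(e), h_max = unname(h_max), s_max = s_max,
      eps_base = eps_base, eps_winter_F1 = eps_winter_F1,
      temp_shift_x = temp_shift_x, sigma_bracket = sigma_bracket
    ),
    class = "daphnia_params"
  )
}

#' @export
print.daphnia_params <- function(x, ...) {
  cat("<daphnia_params>\n")
  cat(sprintf("  m = %g, K = %g, k = %g, f = %g, c = %g, s_max = %g\n",
              x$m, x$K, x$k, x$f, x$c, x$s_max))
  cat(sprintf("  e     = (%s)\n", paste(x$e, collapse = ", ")))
  cat(sprintf("  h_max = (%s)\n", paste(x$h_max, collapse = ", ")))
  cat(sprintf("  eps_base = %g, eps_winter_F1 = %g, temp_shift_x = %g\n",
              x$eps_base, x$eps_winter_F1, x$temp_shift_x))
  cat(sprintf("  sigma_bracket = %s\n", x$sigma_bracket))
  invisible(x)
}
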