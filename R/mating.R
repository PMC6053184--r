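#' Mating encounter kernel
#'
#' Ephippium-production propensities for the six classes from the current
#' densities of sexual individuals of the two parental species (S1, S2) and
#' F1 hybrids (S3); backcrosses and F2 hybrids carry no sexual function. A
#' fraction `c` of sexual individuals mates strictly within its own class and
#' the remaining `1 - c` mate at random, so with `T = S1 + S2 + S3`:
#' \deqn{\phi_j = S_j (S_j + c(T - S_j)) / (2T), \quad j = 1, 2}
#' \deqn{\phi_3 = (1-c) S_1 S_2 / T, \quad
#'       \phi_4 = (1-c) S_1 S_3 / T, \quad
#'       \phi_5 = (1-c) S_2 S_3 / T}
#' \deqn{\phi_6 = S_3 (S_3 + c(S_1 + S_2)) / (2T).}
#' Sexes are implicit (half of sexual individuals are female), so the outputs
#' always satisfy the conservation identity
#' \eqn{\sum_j \phi_j = T/2}. When `T = 0` all outputs are 0.
#'
#' @param S1,S2,S3 Non-negative densities of sexual individuals of parental
#'   species 1, parental species 2, and F1 hybrids.
#' @param c Within-class mating fraction in `[0, 1]`.
#' @return Numeric vector of length 6: encounter propensities per offspring
#'   class (parental 1, parental 2, F1, backcross-to-1, backcross-to-2, F2).
#' @examples
#' mating_output(1, 1, 0, c = 0) # (0.25, 0.25, 0.5, 0, 0, 0)
#' sum(mating_output(2, 3, 4, c = 0.75)) # (2+3+4)/2
#' @export
mating_output <- function(S1, S2, S3, c) {
  s <- c(S1, S2, S3)
  if (length(s) != 3L || any(!is.finite(s)) || any(s < 0)) {
    abort("`S1`, `S2`, `S3` must be single finite non-negative numbers.")
  }
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0 || c > 1) {
    abort("`c` must lie in [0, 1].")
  }
  total <- S1 + S2 + S3
  if (total == 0) {
    return(numeric(6))
  }
  c(
    S1 * (S1 + c * (total - S1)) / (2 * total),
    S2 * (S2 + c * (total - S2)) / (2 * total),
    (1 - c) * S1 * S2 / total,
    (1 - c) * S1 * S3 / total,
    (1 - c) * S2 * S3 / total,
    S3 * (S3 + c * (S1 + S2)) / (2 * total)
  )
}
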