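#' The six genotype classes of the community
#'
#' The community is partitioned into six classes: the two parental species,
#' first-generation (F1) hybrids, the backcross of F1 to each parental
#' species, and second-generation (F2) hybrids. Class indices 1-6 are used
#' throughout the package in this fixed order.
#'
#' @return A tibble with columns `class_index` (integer, 1-6) and
#'   `class_role` (character).
#' @examples
#' hybrid_classes()
#' @export
hybrid_classes <- function() {
  tibble::tibble(
    class_index = 1:6,
    class_role = c(
      "parental-1", "parental-2", "F1-hybrid",
      "backcross-to-1", "backcross-to-2", "F2-hybrid"
    )
  )
}

class_roles <- function() hybrid_classes()$class_role

#' Names of the 18 state variables
#'
#' Per class j = 1..6 the model tracks asexual females `Aj`, sexual females
#' `Sj`, and ephippia (dormant eggs) `Ej`, all in individuals (or ephippia)
#' per litre.
#'
#' @return Character vector of length 18: `A1..A6`, `S1..S6`, `E1..E6`.
#' @export
state_names <- function() {
  c(paste0("A", 1:6), paste0("S", 1:6), paste0("E", 1:6))
}

#' Construct a community state vector
#'
#' @param A,S,E Numeric vectors of length 6: densities of asexual females,
#'   sexual females, and ephippia per class (per litre). All entries must be
#'   finite and non-negative.
#' @return A named numeric vector of length 18 (see [state_names()]).
#' @examples
#' community_state(A = c(0.001, 0.001, 0, 0, 0, 0))
#' @export
community_state <- function(A = rep(0, 6), S = rep(0, 6), E = rep(0, 6)) {
  state <- c(A, S, E)
  if (length(state) != 18L) {
    abort("`A`, `S` and `E` must each have length 6.")
  }
  if (!all(is.finite(state))) {
    abort("Community state must be finite.")
  }
  if (any(state < 0)) {
    abort("Community state densities must be non-negative.")
  }
  setNames(state, state_names())
}

assert_state <- function(state) {
  if (length(state) != 18L || !all(is.finite(state))) {
    abort("`state` must be a finite numeric vector of length 18.")
  }
  invisible(state)
}
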