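#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated trajectory
#'
#' Long-format view of a simulation: one row per sample time, class, and
#' life-history stage.
#'
#' @param x A `daphnia_sim`.
#' @param ... Unused.
#' @return A tibble with columns `time_days`, `class_index`, `class_role`,
#'   `stage` (`"asexual"`, `"sexual"`, `"ephippia"`), `density`.
#' @examples
#' sim <- simulate_scenario(build_scenario("A", horizon_years = 1))
#' tidy(sim)
#' @method tidy daphnia_sim
#' @export
tidy.daphnia_sim <- function(x, ...) {
  x$trajectory |>
    tidyr::pivot_longer(
      cols = -"time_days",
      names_to = c("stage", "class_index"),
      names_pattern = "([ASE])([1-6])",
      values_to = "density"
    ) |>
    dplyr::mutate(
      class_index = as.integer(.data$class_index),
      stage = dplyr::recode(.data$stage,
        A = "asexual", S = "sexual", E = "ephippia")
    ) |>
    dplyr::left_join(hybrid_classes(), by = "class_index") |>
    dplyr::select("time_days", "class_index", "class_role", "stage",
                  "density")
}

#' One-row summary of a simulation
#'
#' @param x A `daphnia_sim`.
#' @param delta_detect Detection threshold (individuals L^-1).
#' @param ... Unused.
#' @return A one-row tibble: scenario settings plus final-decade mean
#'   proportions of the two parental species and F1 hybrids and whether F1
#'   is established in the final year.
#' @examples
#' sim <- simulate_scenario(build_scenario("A", horizon_years = 2))
#' glance(sim)
#' @method glance daphnia_sim
#' @export
glance.daphnia_sim <- function(x, delta_detect = 0.01, ...) {
  met <- establishment_metrics(annual_statistics(x), delta_detect)
  prop <- function(j) met$final_decade_mean_proportion[met$class_index == j]
  tibble::tibble(
    scenario = x$spec$id,
    horizon_years = x$spec$horizon_years,
    r3 = x$spec$r3,
    winter_advantage = x$spec$winter_advantage,
    eps_winter_F1 = x$spec$params$eps_winter_F1,
    temp_shift_x = x$spec$params$temp_shift_x,
    p_parental1 = prop(1),
    p_parental2 = prop(2),
    p_f1 = prop(3),
    f1_established_final_year = met$established_final_year[met$class_index == 3]
  )
}

#' @rdname persistence_boundary
#' @param x A `persistence_boundary`.
#' @param ... Unused.
#' @method tidy persistence_boundary
#' @export
tidy.persistence_boundary <- function(x, ...) {
  x$evaluations
}
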