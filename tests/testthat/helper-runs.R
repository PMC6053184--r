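# Long simulations reused across test files, computed once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache, inherits = FALSE)
}

sim_century <- function(id, winter_advantage = FALSE, eps_winter = 0.1,
                        r3 = 0.35, ...) {
  key <- paste("sim", id, winter_advantage, eps_winter, r3, sep = "_")
  cached(key, simulate_scenario(
    build_scenario(id, r3 = r3, winter_advantage = winter_advantage,
                   eps_winter = eps_winter), ...))
}

f1_stats <- function(sim) {
  st <- annual_statistics(sim)
  st[st$class_index == 3L, ]
}

final_decade_f1_prop <- function(sim) {
  met <- establishment_metrics(annual_statistics(sim))
  met$final_decade_mean_proportion[met$class_index == 3L]
}

f1_established_final_year <- function(id, r3, ...) {
  sim <- sim_century(id, winter_advantage = TRUE, r3 = r3, ...)
  met <- establishment_metrics(annual_statistics(sim))
  met$established_final_year[met$class_index == 3L]
}

# Locate the F1 establishment boundary on r3 for a winter-advantage
# scenario. Starts from the given bracket; if F1 is established at both
# ends, extends the lower end through `lo_candidates` until the predicate
# flips. Returns NULL when no boundary exists down to the last candidate.
find_f1_boundary <- function(id, lo_candidates, hi = 0.35) {
  lo <- NULL
  for (cand in lo_candidates) {
    if (!f1_established_final_year(id, cand)) {
      lo <- cand
      break
    }
  }
  if (is.null(lo)) return(NULL)
  persistence_boundary(
    function(r3) build_scenario(id, r3 = r3, winter_advantage = TRUE),
    lo, hi)
}
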