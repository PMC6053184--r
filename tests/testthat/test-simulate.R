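test_that("breakpoints enumerate all forcing edges", {
  bp <- breakpoints(build_scenario("A", horizon_years = 1))
  for (edge in c(0, 59, 118, 120, 150, 165, 272, 287, 304, 365)) {
    expect_true(edge %in% bp)
  }
  expect_true(all(diff(bp) > 0))
  expect_true(all(bp >= 0 & bp <= 365))
  # scenario E includes the introduction time
  expect_true(36500 %in% breakpoints(build_scenario("E")))
  # biennial schedule boundaries are year boundaries already present
  bpC <- breakpoints(build_scenario("C", horizon_years = 5))
  expect_true(all(c(730, 1460) %in% bpC))
})

test_that("introduce_class is an impulse on one asexual class only", {
  st <- community_state(A = c(1, 0, 0, 0, 0, 0), S = rep(0.5, 6))
  st2 <- introduce_class(st, 2, 0.001)
  expect_equal(st2[["A2"]], 0.001)
  expect_equal(st2[-2], st[-2])
  expect_equal(introduce_class(st, 4, 0), st)
  expect_error(introduce_class(st, 7, 1), "1-6")
  expect_error(introduce_class(st, 1, -1), "non-negative")
})

test_that("with constant conditions the trajectory matches the closed-form logistic", {
  # forcing off: no switching, no hatching, flat seasonality; the two
  # parental populations jointly follow N' = r N (1 - N/K) and split it
  # evenly by symmetry
  p <- model_params(s_max = 0, h_max = rep(0, 6), eps_base = 0)
  spec <- build_scenario("A", params = p, horizon_years = 2)
  sim <- simulate_scenario(spec)
  tr <- sim$trajectory
  r <- 0.35; K <- 150; N0 <- 0.002
  N <- K * N0 * exp(r * tr$time_days) / (K + N0 * (exp(r * tr$time_days) - 1))
  expect_equal(tr$A1, N / 2, tolerance = 1e-6)
  expect_equal(tr$A2, N / 2, tolerance = 1e-6)
  expect_equal(max(abs(tr$S1)), 0)
  expect_equal(max(abs(tr$E3)), 0)
})

test_that("compiled and R right-hand sides integrate to the same trajectory", {
  spec <- build_scenario("A", winter_advantage = TRUE, horizon_years = 2)
  sim_c <- simulate_scenario(spec, engine = "compiled")
  sim_r <- simulate_scenario(spec, engine = "R")
  a <- as.matrix(sim_c$trajectory[-1])
  b <- as.matrix(sim_r$trajectory[-1])
  expect_equal(sim_c$trajectory$time_days, sim_r$trajectory$time_days)
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-9)), 1e-6)
})

test_that("a twenty-year run matches an independently computed reference state", {
  # state at day 7300 computed with an independent LSODA implementation
  # (scipy) of the same equations, frozen here; agreement at 1e-6 relative
  scipy_state <- c(
    1.2235798048e+01, 1.2235798048e+01, 1.9006281452e+00, 2.6477897738e-01,
    2.6477897738e-01, 3.3576742399e-02, 5.6926608070e-05, 5.6926608070e-05,
    8.8426037341e-06, 1.2318746200e-06, 1.2318746200e-06, 3.7699612899e-07,
    7.5289489215e+01, 7.5289489215e+01, 2.3117823477e+01, 3.5591802897e+00,
    3.5591802897e+00, 6.9873480172e+00
  )
  sim <- cached("A_20y", simulate_scenario(build_scenario("A", horizon_years = 20)))
  ours <- as.numeric(sim$trajectory[sim$trajectory$time_days == 7300, -1])
  expect_lt(max(abs(ours - scipy_state) / pmax(abs(scipy_state), 1e-9)), 1e-6)
})

test_that("interchanging the parental species leaves the dynamics invariant", {
  sim <- cached("A_5y", simulate_scenario(build_scenario("A", horizon_years = 5)))
  tr <- sim$trajectory
  expect_equal(tr$A1, tr$A2, tolerance = 1e-9)
  expect_equal(tr$S1, tr$S2, tolerance = 1e-9)
  expect_equal(tr$E1, tr$E2, tolerance = 1e-9)
  expect_equal(tr$E4, tr$E5, tolerance = 1e-9)
})

test_that("sampled states are non-negative and dense", {
  sim <- cached("A_5y", simulate_scenario(build_scenario("A", horizon_years = 5)))
  tr <- sim$trajectory
  expect_true(all(as.matrix(tr[-1]) >= 0))
  expect_true(all(diff(tr$time_days) > 0))
  expect_lte(max(diff(tr$time_days)), 1)
  expect_equal(range(tr$time_days), c(0, 5 * 365))
})

test_that("halving the tolerances leaves decade-scale totals unchanged", {
  spec <- build_scenario("A", horizon_years = 30)
  sim1 <- simulate_scenario(spec)
  sim2 <- simulate_scenario(spec, rtol = 5e-9, atol = 5e-13)
  m1 <- establishment_metrics(annual_statistics(sim1))
  m2 <- establishment_metrics(annual_statistics(sim2))
  rel <- abs(m1$final_decade_mean_proportion - m2$final_decade_mean_proportion) /
    pmax(m2$final_decade_mean_proportion, 1e-9)
  expect_lt(max(rel), 1e-3)
})

test_that("invalid solver settings are rejected", {
  spec <- build_scenario("A", horizon_years = 1)
  expect_error(simulate_scenario(spec, rtol = 0), "positive")
  expect_error(simulate_scenario("A"), "scenario_spec")
})
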