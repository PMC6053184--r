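test_that("scenario A is fully symmetric with r6 lowered", {
  spec <- build_scenario("A")
  for (j in 1:5) expect_equal(growth_rate_at(spec$schedule, j, 1000), 0.35)
  expect_equal(growth_rate_at(spec$schedule, 6, 1000), 0.30)
  expect_equal(unname(spec$initial_state[1:2]), c(0.001, 0.001))
  expect_equal(unname(spec$initial_state[3:18]), rep(0, 16))
  expect_equal(spec$horizon_years, 100)
  expect_equal(nrow(spec$introductions), 0)
})

test_that("backcross rates are running means of parent and F1 rates", {
  specB <- build_scenario("B")
  expect_equal(growth_rate_at(specB$schedule, 4, 500), 0.35)
  expect_equal(growth_rate_at(specB$schedule, 5, 500), 0.325)
  # averaging identity holds through the time-dependent scenarios too
  tt <- seq(0, 4 * 365, by = 13.7)
  for (id in c("C", "D")) {
    sch <- build_scenario(id, r3 = 0.32)$schedule
    expect_equal(growth_rate_at(sch, 4, tt),
                 (growth_rate_at(sch, 1, tt) + 0.32) / 2)
    expect_equal(growth_rate_at(sch, 5, tt),
                 (growth_rate_at(sch, 2, tt) + 0.32) / 2)
  }
})

test_that("scenario C swaps parental rates every two years (period 4)", {
  sch <- build_scenario("C")$schedule
  expect_equal(growth_rate_at(sch, 1, 365), 0.30)      # year 1: first phase
  expect_equal(growth_rate_at(sch, 1, 3 * 365), 0.35)  # year 3: swapped
  expect_equal(growth_rate_at(sch, 2, 365), 0.35)
  expect_equal(growth_rate_at(sch, 2, 3 * 365), 0.30)
  tt <- seq(0, 8 * 365, by = 31)
  expect_equal(growth_rate_at(sch, 1, tt + 4 * 365),
               growth_rate_at(sch, 1, tt))
})

test_that("scenario D swaps parental rates within the year at day 166", {
  sch <- build_scenario("D")$schedule
  expect_equal(growth_rate_at(sch, 1, 100), 0.30)
  expect_equal(growth_rate_at(sch, 1, 200), 0.35)
  expect_equal(growth_rate_at(sch, 2, 100), 0.35)
  expect_equal(growth_rate_at(sch, 2, 200), 0.30)
  tt <- seq(0, 2 * 365, by = 0.5)
  expect_equal(growth_rate_at(sch, 1, tt + 365), growth_rate_at(sch, 1, tt))
})

test_that("scenario E starts with species 1 alone and introduces species 2", {
  spec <- build_scenario("E")
  expect_equal(spec$horizon_years, 200)
  expect_equal(unname(spec$initial_state[1]), 0.001)
  expect_equal(unname(spec$initial_state[2:18]), rep(0, 17))
  expect_equal(spec$introductions$time_days, 36500)
  expect_equal(spec$introductions$class_index, 2L)
  expect_equal(spec$introductions$density, 0.001)
  expect_equal(growth_rate_at(spec$schedule, 1, 0), 0.30)
  expect_equal(growth_rate_at(spec$schedule, 2, 0), 0.35)
})

test_that("winter advantage toggles the F1 winter amplitude", {
  expect_equal(build_scenario("A")$params$eps_winter_F1, 0.7)
  expect_equal(build_scenario("A", winter_advantage = TRUE)$params$eps_winter_F1,
               0.1)
  expect_equal(
    build_scenario("A", winter_advantage = TRUE,
                   eps_winter = 0.325)$params$eps_winter_F1,
    0.325)
})

test_that("temperature application and bad inputs", {
  spec <- apply_temperature(build_scenario("A"), 5)
  expect_equal(spec$params$temp_shift_x, 5)
  expect_equal(temperature_factor(spec$params$temp_shift_x), sqrt(2))
  expect_error(build_scenario("F"), "one of")
  expect_error(build_scenario("A", r3 = -0.1), "positive")
  expect_error(apply_temperature(build_scenario("A"), Inf), "finite")
})

test_that("r3 reductions are labelled as percentages of 0.35", {
  expect_equal(build_scenario("A", r3 = 0.31)$r3_reduction_pct,
               100 * (0.35 - 0.31) / 0.35)
})
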