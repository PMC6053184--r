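test_that("day_of_year wraps on a 365-day year and rejects negative time", {
  expect_equal(day_of_year(0), 0)
  expect_equal(day_of_year(365), 0)
  expect_equal(day_of_year(36650), 150)
  expect_equal(day_of_year(400.25), 35.25)
  expect_error(day_of_year(-1), "non-negative")
})

test_that("seasonal forcing matches its closed form and stays in bounds", {
  expect_equal(seasonal_sigma(182.5, 0.7), 1.0)
  expect_equal(seasonal_sigma(365, 0.7), 0.3 / 1.7)
  expect_equal(seasonal_sigma(365, 0.25), 0.6)
  expect_error(seasonal_sigma(10, 1.0), "\\[0, 1\\)")
  expect_error(seasonal_sigma(10, -0.1), "\\[0, 1\\)")
  # bounds and periodicity over a dense grid, several amplitudes
  tt <- seq(0, 365, by = 0.25)
  for (eps in c(0, 0.1, 0.475, 0.7, 0.99)) {
    s <- seasonal_sigma(tt, eps)
    expect_true(all(s >= (1 - eps) / (1 + eps) - 1e-12))
    expect_true(all(s <= 1 + 1e-12))
    expect_equal(seasonal_sigma(tt + 365, eps), s)
  }
})

test_that("only the F1 class gets the winter amplitude override", {
  cal <- season_calendar()
  p <- model_params(eps_winter_F1 = 0.1)
  # deep winter, day 330
  expect_equal(class_sigma(330, 1, p, cal), seasonal_sigma(330, 0.7))
  expect_equal(class_sigma(330, 3, p, cal), seasonal_sigma(330, 0.1))
  # the wrap-around piece of winter (February)
  expect_equal(class_sigma(365 + 30, 3, p, cal), seasonal_sigma(395, 0.1))
  # mid-year is outside winter: seasonal maximum for everyone
  expect_equal(class_sigma(182.5, 3, p, cal), 1.0)
  # without the advantage the override is inert
  p0 <- model_params()
  expect_equal(class_sigma(330, 3, p0, cal), seasonal_sigma(330, 0.7))
})

test_that("switching is gated to the two sexual windows", {
  cal <- season_calendar()
  expect_equal(switching_rate(155, cal, 0.5), 0.5)
  expect_equal(switching_rate(280, cal, 0.5), 0.5)
  expect_equal(switching_rate(100, cal, 0.5), 0)
  # half-open edges: [150, 165) and [272, 287)
  expect_equal(switching_rate(150, cal, 0.5), 0.5)
  expect_equal(switching_rate(165, cal, 0.5), 0)
  # periodic in whole years
  expect_equal(switching_rate(10 * 365 + 155, cal, 0.5), 0.5)
})

test_that("hatching is gated to the spring window with class-specific rates", {
  expect_equal(hatching_rate(119.5, 1), 0.1)
  expect_equal(hatching_rate(119.5, 3), 0.05)
  expect_equal(hatching_rate(200, 2), 0)
  expect_equal(hatching_rate(118, 1), 0.1)
  expect_equal(hatching_rate(120, 1), 0)
})

test_that("Q10 temperature factor follows 2^(x/10)", {
  expect_equal(temperature_factor(0), 1)
  expect_equal(temperature_factor(10), 2)
  expect_equal(temperature_factor(-5), 2^(-0.5))
  expect_equal(temperature_factor(-3), 2^(-0.3))
  expect_error(temperature_factor(NA_real_), "finite")
})
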