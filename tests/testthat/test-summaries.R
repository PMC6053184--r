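constant_trajectory <- function(days, A = rep(0, 6), S = rep(0, 6),
                                E = rep(0, 6)) {
  tt <- 0:days
  out <- cbind(tt, matrix(rep(c(A, S, E), each = length(tt)), nrow = length(tt)))
  colnames(out) <- c("time_days", state_names())
  tibble::as_tibble(as.data.frame(out))
}

test_that("annual means of constant trajectories are exact", {
  tr <- constant_trajectory(365, A = c(10, 0, 0, 0, 0, 0))
  st <- annual_statistics(tr)
  expect_equal(nrow(st), 6)
  expect_equal(st$mean_active[st$class_index == 1], 10)
  expect_equal(st$max_active[st$class_index == 1], 10)
  expect_equal(st$proportion[st$class_index == 1], 1)
  tr2 <- constant_trajectory(730, A = c(30, 10, 0, 0, 0, 0))
  st2 <- annual_statistics(tr2)
  expect_equal(st2$proportion[st2$class_index == 1], c(0.75, 0.75))
  expect_equal(st2$proportion[st2$class_index == 2], c(0.25, 0.25))
  expect_error(annual_statistics(tibble::tibble()), "Empty")
  expect_error(annual_statistics(constant_trajectory(100)), "full year")
})

test_that("proportions sum to one in every year of a real simulation", {
  sim <- cached("A_5y", simulate_scenario(build_scenario("A", horizon_years = 5)))
  st <- annual_statistics(sim)
  sums <- tapply(st$proportion, st$year, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(st$mean_active <= st$max_active + 1e-12))
})

test_that("establishment, dominance and persistence metrics behave on crafted input", {
  yrs <- 1:10
  mk <- function(mean1, mean3) {
    dplyr::bind_rows(lapply(yrs, function(y) tibble::tibble(
      year = y, class_index = c(1L, 3L),
      class_role = c("parental-1", "F1-hybrid"),
      mean_active = c(mean1[y], mean3[y]),
      max_active = c(mean1[y], mean3[y]) * 2,
      proportion = c(mean1[y], mean3[y]) / (mean1[y] + mean3[y])
    )))
  }
  # F1 appears in year 3, vanishes after year 6, never dominates
  m3 <- c(0, 0, 1, 2, 1, 0.5, 0.001, 0.001, 0.001, 0.001)
  m1 <- rep(10, 10)
  met <- establishment_metrics(mk(m1, m3), delta_detect = 0.01)
  f1 <- met[met$class_index == 3L, ]
  expect_equal(f1$first_established, 3L)
  expect_equal(f1$persistence_years, 4L)
  expect_equal(f1$n_established_years, 4L)
  expect_false(f1$established_final_year)
  expect_true(is.na(f1$dominance_onset))
  p1 <- met[met$class_index == 1L, ]
  expect_equal(p1$persistence_years, 10L)
  expect_equal(p1$dominance_onset, 1L)
  # never-established class
  met0 <- establishment_metrics(mk(m1, rep(0, 10)), delta_detect = 0.01)
  expect_equal(met0$persistence_years[met0$class_index == 3L], 0L)
  expect_true(is.na(met0$first_established[met0$class_index == 3L]))
  expect_error(establishment_metrics(mk(m1, m3), delta_detect = 0), "positive")
})

test_that("final-decade summaries use only the trailing years", {
  yrs <- 1:20
  tab <- dplyr::bind_rows(lapply(yrs, function(y) tibble::tibble(
    year = y, class_index = 1L, class_role = "parental-1",
    mean_active = ifelse(y <= 10, 100, 50),
    max_active = ifelse(y <= 10, 100, 50),
    proportion = ifelse(y <= 10, 0.9, 0.4)
  )))
  met <- establishment_metrics(tab, final_decade_years = 10)
  expect_equal(met$final_decade_mean_proportion, 0.4)
  expect_equal(met$final_decade_max_active, 50)
})

test_that("the bisection refuses a bracket with no establishment change", {
  # over a 4-year horizon F1 hybrids are established (they are freshly
  # produced by random mating) at both bracket ends
  expect_error(
    persistence_boundary(
      function(r3) build_scenario("A", r3 = r3, horizon_years = 4),
      0.34, 0.35),
    "does not change")
})

test_that("summary reports round-trip through JSON + CSV", {
  sim <- cached("A_5y", simulate_scenario(build_scenario("A", horizon_years = 5)))
  rep1 <- summarize_simulation(sim)
  path <- file.path(withr::local_tempdir(), "runA")
  write_summary(rep1, path)
  rep2 <- read_summary(path)
  expect_equal(as.data.frame(rep2$annual), as.data.frame(rep1$annual),
               tolerance = 1e-12)
  expect_equal(as.data.frame(rep2$classes), as.data.frame(rep1$classes),
               tolerance = 1e-12)
  expect_equal(rep2$meta$scenario, "A")
  expect_error(read_summary(file.path(tempdir(), "nope")), "No summary")
})

test_that("glance and tidy expose the standard views", {
  sim <- cached("A_5y", simulate_scenario(build_scenario("A", horizon_years = 5)))
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_equal(g$scenario, "A")
  expect_true(g$p_f1 >= 0 && g$p_f1 <= 1)
  td <- tidy(sim)
  expect_equal(nrow(td), nrow(sim$trajectory) * 18)
  expect_setequal(unique(td$stage), c("asexual", "sexual", "ephippia"))
  expect_setequal(unique(td$class_role), hybrid_classes()$class_role)
})
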