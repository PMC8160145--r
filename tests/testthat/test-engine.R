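# Stock-flow engine: initial state, capacities, waits, shock, stepping,
# conservation and outcome accounting.

test_that("init_state splits the population by initial prevalence", {
  cfg <- region_config("r", initial_population = 1e6,
                       initial_distress_prevalence = 0.135)
  s <- init_state(cfg)
  stocks <- s[1:11]
  expect_equal(sum(stocks), 1e6)
  expect_equal(sum(stocks[-1]), 135000)   # everyone outside 'well' is distressed
  expect_true(all(stocks >= 0))
  expect_true(all(s[12:15] == 0))

  s0 <- init_state(region_config("r", initial_population = 5e5,
                                 initial_distress_prevalence = 0))
  expect_equal(unname(s0[["well"]]), 5e5)
  expect_true(all(s0[2:11] == 0))

  s1 <- init_state(region_config("r", initial_population = 5e5,
                                 initial_distress_prevalence = 1))
  expect_equal(unname(s1[["well"]]), 0)
  expect_equal(sum(s1[1:11]), 5e5)

  expect_error(region_config("r", initial_population = 0), "positive")
})

test_that("capacity_at follows the lever formulae", {
  cfg <- region_config("r", service_capacities = c(gp = 100, specialist = 10,
                                                   inpatient = 5, cmhc = 80),
                       capacity_growth = c(gp = 0.05, specialist = 0,
                                           inpatient = 0, cmhc = 0))
  expect_equal(capacity_at("gp", 1, cfg), 105)
  expect_equal(capacity_at("gp", 1, cfg, list(multiplier = 2)), 110)
  # CMHC default increment 0: constant over time
  expect_equal(capacity_at("cmhc", 7, cfg), 80)
  # additive CMHC increment in contacts per 10k population per week
  inc <- capacity_at("cmhc", 2, cfg, list(cmhc_increment = 0.1, start = 0))
  expect_equal(inc, 80 + 0.1 * cfg$initial_population / 1e4 * 2)
  expect_error(capacity_at("dentist", 1, cfg), "unknown service")
})

test_that("wait_time implements capped Little's law and flags saturation", {
  expect_equal(as.numeric(wait_time(30, 10)), 3)
  expect_equal(as.numeric(wait_time(0, 10)), 0)
  expect_equal(as.numeric(wait_time(1000, 10, cap = 52)), 52)
  w <- wait_time(5, 0)
  expect_equal(as.numeric(w), 52)
  expect_true(attr(w, "saturated"))
})

test_that("shock multiplier is a rectangular pulse on distress onset", {
  sh <- list(start = 9.164, duration = 2, onset_multiplier = 1.2)
  expect_equal(shock_multiplier(5, sh), 1)
  expect_equal(shock_multiplier(10, sh), 1.2)
  expect_equal(shock_multiplier(9.164 + 2, sh), 1)
  # scaling the duration moves only the pulse end, not its height
  sh2 <- sh; sh2$duration <- 3
  expect_equal(shock_multiplier(10, sh2), shock_multiplier(10, sh))
  expect_equal(shock_multiplier(11.5, sh2), 1.2)
  expect_equal(shock_multiplier(11.5, sh), 1)
})

test_that("zero dynamics leave the state unchanged", {
  cfg <- no_demography(tiny_config())
  traj <- simulate_region(cfg, zero_params(), t_end = 1, dt = dt_test)
  first <- unlist(traj[1, 2:16])
  last <- unlist(traj[nrow(traj), 2:16])
  expect_identical(first, last)
})

test_that("a single onset flow follows the Euler update to first order", {
  cfg <- no_demography(tiny_config())
  p <- zero_params()
  p$distress_onset_rate <- 0.2
  traj <- simulate_region(cfg, p, t_end = 5 * dt_test, dt = dt_test)
  well0 <- traj$well[1]
  expect_equal(traj$well[2], well0 * (1 - 0.2 * dt_test), tolerance = 1e-12)
  expect_equal(traj$distressed[2] - traj$distressed[1],
               well0 * 0.2 * dt_test, tolerance = 1e-9)
})

test_that("persons are conserved up to demographic flow and suicide deaths", {
  cfg <- no_demography(tiny_config())
  traj <- simulate_region(cfg, t_end = 6, dt = dt_test)
  total <- rowSums(traj[, 2:12]) + traj$suicide_deaths
  expect_equal(max(abs(total - total[1])) / total[1], 0, tolerance = 1e-10)
})

test_that("stocks stay non-negative and runs are deterministic", {
  cfg <- tiny_config()
  t1 <- simulate_region(cfg, t_end = 15, dt = dt_test)
  t2 <- simulate_region(cfg, t_end = 15, dt = dt_test)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(as.matrix(t1[, 2:12]) >= 0))
})

test_that("completed services never exceed capacity", {
  cfg <- tiny_config()
  # stress the queues with a surge in help seeking
  p <- model_params(help_seeking_rate = 2.5)
  traj <- simulate_region(cfg, p, t_end = 8, dt = dt_test)
  expect_true(all(traj$gp_intake <= traj$capacity_gp + 1e-9))
  expect_true(all(traj$specialist_intake <= traj$capacity_specialist + 1e-9))
  expect_true(all(traj$inpatient_intake <= traj$capacity_inpatient + 1e-9))
  expect_true(all(traj$cmhc_intake <= traj$capacity_cmhc_free + 1e-9))
})

test_that("a stronger distress shock cannot decrease cumulative suicides", {
  cfg <- tiny_config()
  out <- vapply(c(1, 1.1, 1.3), function(m) {
    traj <- simulate_region(cfg, model_params(shock_onset_multiplier = m),
                            t_end = 20, dt = dt_test)
    cumulative_outcomes(traj, c(9, 20))$suicides
  }, numeric(1))
  expect_true(all(diff(out) >= 0))
})

test_that("cumulative outcome windows are additive and span-consistent", {
  cfg <- tiny_config()
  traj <- simulate_region(cfg, t_end = 6, dt = dt_test)
  zero <- cumulative_outcomes(traj, c(3, 3))
  expect_equal(zero$suicides, 0)
  expect_equal(zero$ed_presentations, 0)
  full <- cumulative_outcomes(traj, c(0, 6))
  expect_equal(full$suicides, tail(traj$suicide_deaths, 1))
  expect_equal(full$disengagements, tail(traj$disengagement_events, 1))
  a <- cumulative_outcomes(traj, c(0, 2.5))
  b <- cumulative_outcomes(traj, c(2.5, 6))
  expect_equal(a$suicides + b$suicides, full$suicides, tolerance = 1e-10)
  expect_equal(a$ed_presentations + b$ed_presentations,
               full$ed_presentations, tolerance = 1e-10)
  expect_error(cumulative_outcomes(traj, c(5, 7)), "outside")
})

test_that("halving the step changes decade outcomes by well under 1%", {
  cfg <- tiny_config()
  o1 <- cumulative_outcomes(simulate_region(cfg, t_end = 12, dt = dt_test),
                            c(2, 12))
  o2 <- cumulative_outcomes(simulate_region(cfg, t_end = 12, dt = dt_test / 2),
                            c(2, 12))
  for (col in c("suicides", "ed_presentations", "disengagements"))
    expect_lt(abs(o1[[col]] - o2[[col]]) / o2[[col]], 0.01)
})

test_that("district outcomes aggregate by component-wise summation", {
  x <- published_district_baseline()
  phn <- aggregate_regions(x)
  expect_equal(phn$suicides, 1778)
  expect_equal(phn$ed_presentations, 155901)
  expect_equal(phn$region_id, "PHN")
  one <- aggregate_regions(x[1, ])
  expect_equal(one$suicides, x$suicides[1])
  bad <- x; bad$window_end[2] <- 21
  expect_error(aggregate_regions(bad), "window")
})
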