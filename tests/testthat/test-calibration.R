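# MAPE loss, calibration objective and the Powell optimiser.

test_that("mape matches hand-computed values", {
  expect_equal(mape(c(100, 200), c(110, 180)), 10)
  expect_equal(mape(c(3, 7, 11), c(3, 7, 11)), 0)
  expect_equal(mape(50, 75), 50)
  expect_error(mape(c(1, 0), c(1, 1)), "zero observed")
  expect_error(mape(1:3, 1:2), "equal")
})

test_that("mape is non-negative and scale-invariant", {
  set.seed(11)
  for (i in 1:20) {
    obs <- runif(6, 1, 100)
    sim <- obs * runif(6, 0.5, 1.5)
    m <- mape(obs, sim)
    expect_gte(m, 0)
    k <- runif(1, 0.1, 10)
    expect_equal(mape(k * obs, k * sim), m, tolerance = 1e-12)
  }
})

test_that("objective is zero at the generating parameters and positive away", {
  fx <- recovery_fixture(seed = 3)
  cfg <- fx$configs[[1]]
  x_true <- unlist(unclass(fx$truth_params)[fx$free])
  f0 <- calibration_objective(x_true, fx$free, fx$targets_noiseless, cfg,
                              fx$truth_params)
  expect_lt(as.numeric(f0), 1e-8)
  x_off <- x_true * c(1.1, 1, 1, 1, 1, 1)
  expect_gt(as.numeric(calibration_objective(x_off, fx$free,
                                             fx$targets_noiseless, cfg,
                                             fx$truth_params)), 0.1)
  # sum over series does not depend on row order of the targets
  shuf <- fx$targets_noiseless[sample(nrow(fx$targets_noiseless)), ]
  shuf <- calibration_targets(dplyr::arrange(shuf, series, time))
  f1 <- calibration_objective(x_off, fx$free, shuf, cfg, fx$truth_params)
  f2 <- calibration_objective(x_off, fx$free, fx$targets_noiseless, cfg,
                              fx$truth_params)
  expect_equal(as.numeric(f1), as.numeric(f2))
})

test_that("powell_fit solves a quadratic bowl to coordinate tolerance", {
  centre <- c(1.5, -0.5, 2)
  fit <- powell_fit(function(x) sum((x - centre)^2), c(0, 0, 0),
                    lower = c(-5, -5, -5), upper = c(5, 5, 5))
  expect_true(fit$converged)
  expect_equal(fit$par, centre, tolerance = 1e-3)
  expect_lt(fit$value, 1e-6)
})

test_that("powell_fit at the optimum returns almost immediately", {
  fit <- powell_fit(function(x) sum((x - 1)^2), c(1, 1),
                    lower = c(0, 0), upper = c(2, 2))
  expect_lte(fit$iterations, 2)
  expect_equal(fit$par, c(1, 1), tolerance = 1e-6)
})

test_that("accepted Powell iterates never increase the objective", {
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  fit <- powell_fit(rosen, c(-1.2, 1), lower = c(-2, -2), upper = c(2, 2),
                    max_iter = 50)
  expect_true(all(diff(fit$trace) <= 1e-12))
  expect_lt(fit$value, rosen(c(-1.2, 1)))
})

test_that("bounds are honoured when the optimum lies outside the box", {
  fit <- powell_fit(function(x) sum((x - 10)^2), c(0.5), lower = 0, upper = 1)
  expect_lte(fit$par, 1 + 1e-9)
  expect_equal(as.numeric(fit$par), 1, tolerance = 1e-3)
  expect_true(length(fit$bounds_active) >= 1)
  expect_error(powell_fit(function(x) sum(x), c(2), lower = 0, upper = 1),
               "bounds")
})

test_that("a two-parameter refit recovers synthetic truth quickly", {
  fx <- recovery_fixture(seed = 5)
  cfg <- fx$configs[[2]]   # smaller district: faster
  free <- c("help_seeking_rate", "attempt_hazard_untreated")
  truth <- fx$truth_params
  targets <- generate_history(cfg, truth, noise_cv = 0)
  # start from the truth everywhere except the two freed parameters
  start <- truth
  for (nm in free) start[[nm]] <- fx$base_params[[nm]]
  fit <- calibrate_model(targets, cfg, start, free = free,
                         bounds = fx$bounds[free], restarts = 0,
                         max_iter = 60)
  for (nm in free)
    expect_lt(abs(fit$estimates[[nm]] - truth[[nm]]) / truth[[nm]], 0.05)
  expect_lt(fit$objective, 0.5)
  td <- tidy(fit)
  expect_setequal(td$term, free)
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  gl <- glance(fit)
  expect_equal(gl$n_series, 6)
  expect_equal(gl$n_free, 2)
})
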