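# Latin hypercube design, propagation and interval summaries.

test_that("each dimension is stratified with one draw per stratum", {
  dims <- tibble::tibble(path = "p1", low = 0, high = 1)
  d <- lhs_design(dims, n = 4, seed = 9)
  q <- floor(d$samples[, 1] * 4)
  expect_setequal(q, 0:3)

  dims9 <- default_sensitivity_dims()
  expect_equal(nrow(dims9), 9)    # 8 program effects + shock duration
  expect_equal(dims9$low[1:8], rep(0.8, 8))
  expect_equal(dims9$high[9] / dims9$default[9], 1.5)
  d100 <- lhs_design(dims9, n = 100, seed = 10)
  for (j in seq_len(ncol(d100$samples))) {
    u <- (d100$samples[, j] - dims9$low[j]) / (dims9$high[j] - dims9$low[j])
    expect_setequal(floor(u * 100), 0:99)
  }
  expect_error(lhs_design(tibble::tibble(path = "x", low = 1, high = 1), 4),
               "degenerate")
})

test_that("designs are reproducible under a seed", {
  dims <- default_sensitivity_dims()
  expect_identical(lhs_design(dims, 20, seed = 4)$samples,
                   lhs_design(dims, 20, seed = 4)$samples)
  expect_false(identical(lhs_design(dims, 20, seed = 4)$samples,
                         lhs_design(dims, 20, seed = 5)$samples))
})

test_that("quantile summaries follow the linear-interpolation rule", {
  draws <- tibble::tibble(draw = 1:100, scenario_id = "s", region_id = "PHN",
                          outcome = "suicides", count = 1,
                          pct_reduction = as.numeric(1:100))
  s <- summarise_draws(draws)
  expect_equal(s$mean, 50.5)
  expect_equal(s$q2.5, 3.475)
  expect_equal(s$q97.5, 97.525)
  const <- dplyr::mutate(draws, pct_reduction = 7)
  sc <- summarise_draws(const)
  expect_equal(sc$q2.5, 7)
  expect_equal(sc$q97.5, 7)
  expect_equal(sc$mean, 7)
})

test_that("degenerate designs reproduce the point-estimate pipeline", {
  cfgs <- profile_configs()["central_coast"]
  sets <- enumerate_sets(intervention_catalogue(), 4)[5, ]
  dims <- default_sensitivity_dims()
  d <- lhs_design(dims, n = 3, seed = 2)
  d$samples[] <- rep(dims$default, each = 3)   # collapse every range
  draws <- run_sensitivity(d, sets, cfgs, window = c(10, 14), dt = dt_test)
  expect_true(all(is.finite(draws$pct_reduction)))
  point <- evaluate_scenarios(cfgs, sets = sets, window = c(10, 14),
                              dt = dt_test)
  s <- summarise_draws(draws)
  for (i in seq_len(nrow(s))) {
    expected <- point[[paste0("pct_", sub("^pct_", "", s$outcome[i]))]][
      point$scenario_id == s$scenario_id[i]]
    expect_equal(s$mean[i], expected, tolerance = 1e-12)
    expect_equal(s$q2.5[i], s$q97.5[i], tolerance = 1e-12)
  }
})

test_that("sensitivity draws are finite and seed-reproducible end-to-end", {
  cfgs <- profile_configs()["central_coast"]
  sets <- enumerate_sets(intervention_catalogue(), 4)[c(10, 250), ]
  design <- lhs_design(default_sensitivity_dims(), n = 4, seed = 31)
  a <- run_sensitivity(design, sets, cfgs, window = c(10, 13), dt = dt_test)
  b <- run_sensitivity(design, sets, cfgs, window = c(10, 13), dt = dt_test)
  expect_identical(a, b)
  expect_true(all(is.finite(a$pct_reduction)))
  expect_equal(nrow(a), 4 * 3 * 3 * 1)  # draws x scenarios(+baseline) x outcomes
})
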