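# Intervention catalogue and its mapping onto model parameters.

test_that("catalogue has 12 entries: 8 programs and 4 capacity levers", {
  cat_tab <- intervention_catalogue()
  expect_equal(nrow(cat_tab), 12)
  expect_equal(sum(cat_tab$kind == "program"), 8)
  expect_setequal(cat_tab$id[cat_tab$kind == "capacity_lever"],
                  c("cap_gp", "cap_specialist", "cap_inpatient", "cap_cmhc"))
  aft <- cat_tab$capacity_cost[[which(cat_tab$id == "post_attempt_aftercare")]]
  expect_equal(aft$service, "cmhc")
  expect_gt(aft$services_per_person_week, 0)
  # every target path resolves in the parameter set
  p <- model_params()
  for (tg in cat_tab$targets) expect_true(all(tg$path %in% names(p)))
})

test_that("empty set is the identity and application is order-independent", {
  p <- model_params()
  expect_identical(apply_interventions(p, character(0))$params, p)
  ids <- c("safety_planning", "post_attempt_aftercare", "social_connectedness",
           "cap_cmhc")
  a <- apply_interventions(p, ids)
  b <- apply_interventions(p, rev(ids))
  expect_identical(a$params, b$params)
  expect_identical(a$modifiers, b$modifiers)
  expect_error(apply_interventions(p, "mindfulness_app"), "unknown")
})

test_that("effects combine multiplicatively on shared parameters", {
  p <- model_params()
  both <- apply_interventions(p, c("safety_planning", "post_attempt_aftercare"))
  expect_equal(both$params$attempt_hazard_post,
               p$attempt_hazard_post * 0.8 * 0.8)
  lever <- apply_interventions(p, "cap_gp")
  expect_equal(lever$modifiers$capm_gp, 2)
  expect_equal(lever$params$distress_onset_rate, p$distress_onset_rate)
})

test_that("community support factor is linear in coverage within [0.5, 1.5]", {
  expect_equal(community_support_factor(0), 1)
  expect_equal(community_support_factor(1), 1.5)
  expect_equal(community_support_factor(0.5), 1.25)
})

test_that("clamping keeps every parameter inside its declared bounds", {
  p <- model_params()
  all12 <- intervention_catalogue()$id
  suppressWarnings(out <- apply_interventions(p, all12))
  validate_params(out$params)   # errors if any bound is violated
  expect_lte(out$params$frac_gp_recover + out$params$frac_gp_specialist +
               out$params$frac_gp_cmhc + out$params$frac_gp_online, 1 + 1e-9)
})

test_that("simulating an empty set is bit-identical to no intervention machinery", {
  cfg <- tiny_config()
  plain <- simulate_region(cfg, t_end = 12, dt = dt_test)
  empty <- simulate_region(cfg, interventions = character(0), t_end = 12,
                           dt = dt_test)
  expect_identical(as.data.frame(plain), as.data.frame(empty))
})

test_that("aftercare consumes CMHC capacity whenever anyone is enrolled", {
  cfg <- tiny_config()
  base <- simulate_region(cfg, t_end = 14, dt = dt_test)
  aft <- simulate_region(cfg, interventions = "post_attempt_aftercare",
                         t_end = 14, dt = dt_test)
  post <- aft$time > 10 & aft$post_attempt > 0
  # free CMHC throughput is strictly below baseline while enrolment > 0
  expect_true(all(aft$capacity_cmhc_free[post] <
                    base$capacity_cmhc_free[post]))
  expect_true(all(aft$capacity_cmhc_free >= 0))
  # and identical before the rollout date
  pre <- aft$time < 10
  expect_identical(aft$capacity_cmhc_free[pre], base$capacity_cmhc_free[pre])
})

test_that("scaling an effect towards neutral weakens its impact", {
  p <- model_params()
  full <- apply_interventions(p, "safety_planning")
  half <- apply_interventions(p, "safety_planning",
                              effect_scale = c(safety_planning = 0.5))
  expect_equal(half$params$attempt_hazard_post, p$attempt_hazard_post * 0.9)
  expect_gt(half$params$attempt_hazard_post, full$params$attempt_hazard_post)
  # capacity levers are policy settings: never scaled
  lever <- apply_interventions(p, "cap_cmhc", effect_scale = c(cap_cmhc = 0.5))
  expect_equal(lever$modifiers$cmhc_increment_per10k, 0.15)
})
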