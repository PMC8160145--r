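# Combination enumeration, reductions, dominance and Pareto filtering.

test_that("enumerate_sets counts subsets exactly", {
  cat_tab <- intervention_catalogue()
  s4 <- enumerate_sets(cat_tab, 4)
  expect_equal(nrow(s4), choose(12, 4))
  expect_equal(anyDuplicated(s4$scenario_id), 0)
  expect_true(all(vapply(s4$interventions, length, integer(1)) == 4))
  expect_equal(nrow(enumerate_sets(cat_tab, 5)), choose(12, 5))
  s0 <- enumerate_sets(cat_tab, 0)
  expect_equal(s0$scenario_id, "baseline")
  expect_error(enumerate_sets(cat_tab, 13), "between")
  # deterministic lexicographic order
  expect_identical(s4$scenario_id, sort(s4$scenario_id))
})

test_that("percent_reduction matches the published one-decimal values", {
  expect_equal(round(percent_reduction(1778, 1532), 1), 13.8)
  expect_equal(round(percent_reduction(155901, 138444), 1), 11.2)
  expect_equal(percent_reduction(250, 250), 0)
  expect_error(percent_reduction(0, 10), "positive")
})

test_that("dominance is weak on all outcomes and strict on at least one", {
  expect_true(dominates(c(10, 10, 10), c(11, 10, 12)))
  expect_false(dominates(c(10, 10, 10), c(9, 20, 20)))
  expect_false(dominates(c(10, 10, 10), c(10, 10, 10)))
  expect_error(dominates(1:2, 1:3), "length")
})

test_that("pareto_front matches constructed cases and keeps ties", {
  m <- rbind(c(10, 10, 10), c(12, 9, 11), c(13, 13, 13))
  res <- pareto_front(outcome_table_from_matrix(m))
  expect_setequal(res$non_dominated, c("s001", "s002"))
  expect_equal(res$dominated$scenario_id, "s003")
  expect_equal(res$dominated$dominated_by, "s001")
  # identical triplets are all retained
  res2 <- pareto_front(outcome_table_from_matrix(rbind(c(1, 2, 3), c(1, 2, 3))))
  expect_equal(length(res2$non_dominated), 2)
  one <- pareto_front(outcome_table_from_matrix(m[1, , drop = FALSE]))
  expect_equal(one$non_dominated, "s001")
  expect_error(pareto_front(outcome_table_from_matrix(m)[0, ]), "no scenario")
})

test_that("pareto_front equals the brute-force oracle on random instances", {
  set.seed(202)
  for (rep in 1:300) {
    n <- sample(2:40, 1)
    m <- matrix(sample(1:8, n * 3, replace = TRUE), ncol = 3)  # many ties
    tab <- outcome_table_from_matrix(m)
    res <- pareto_front(tab)
    expect_setequal(res$non_dominated, tab$scenario_id[pareto_oracle(m)])
    # every dominated entry names a valid witness
    if (nrow(res$dominated)) {
      for (i in seq_len(nrow(res$dominated))) {
        a <- unlist(tab[tab$scenario_id == res$dominated$dominated_by[i], 3:5])
        b <- unlist(tab[tab$scenario_id == res$dominated$scenario_id[i], 3:5])
        expect_true(dominates(a, b))
      }
    }
  }
})

test_that("front is invariant to row order and affine outcome rescaling", {
  set.seed(7)
  m <- matrix(runif(60, 10, 100), ncol = 3)
  tab <- outcome_table_from_matrix(m)
  ref <- pareto_front(tab)$non_dominated
  expect_setequal(pareto_front(tab[sample(nrow(tab)), ])$non_dominated, ref)
  tab2 <- tab
  tab2$ed_presentations <- 3.7 * tab2$ed_presentations + 12
  expect_setequal(pareto_front(tab2)$non_dominated, ref)
})

test_that("per-outcome optima lie on the front and ties break lexicographically", {
  set.seed(8)
  m <- matrix(sample(5:30, 75, replace = TRUE), ncol = 3)
  tab <- outcome_table_from_matrix(m)
  nd <- pareto_front(tab)$non_dominated
  for (o in c("suicides", "ed_presentations", "disengagements"))
    expect_true(best_per_outcome(tab, outcome = o) %in% nd)
  tie <- outcome_table_from_matrix(rbind(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(best_per_outcome(tie, outcome = "suicides"), "s001")
  expect_error(best_per_outcome(tab, outcome = "admissions"), "unknown")
})

test_that("scenario evaluation produces a consistent outcome table", {
  cfgs <- profile_configs()
  sets <- enumerate_sets(intervention_catalogue(), 4)[c(2, 30, 400), ]
  tab <- evaluate_scenarios(cfgs, sets = sets, window = c(10, 20),
                            dt = dt_test)
  expect_s3_class(tab, "mhsd_outcomes")
  # one baseline per region, zero reductions there
  base <- tab[tab$scenario_id == "baseline", ]
  expect_equal(nrow(base), 3)   # two districts + PHN
  expect_true(all(base$pct_suicides == 0))
  # PHN rows are the component-wise sums of the district rows
  for (sc in unique(tab$scenario_id)) {
    rows <- tab[tab$scenario_id == sc, ]
    phn <- rows[rows$region_id == "PHN", ]
    expect_equal(phn$suicides, sum(rows$suicides[rows$region_id != "PHN"]),
                 tolerance = 1e-10)
  }
  # reductions are recomputable from the counts
  phn <- tab[tab$region_id == "PHN", ]
  b <- phn$suicides[phn$scenario_id == "baseline"]
  expect_equal(phn$pct_suicides, 100 * (b - phn$suicides) / b,
               tolerance = 1e-12)
})
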