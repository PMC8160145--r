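# Shared fixtures: a small fast region, a coarse test step, and the
# published regional scenario outcome table (HNECC PHN projections,
# 2021-2031) used for arithmetic and set-logic checks.

dt_test <- 1 / 104   # half-week step keeps unit tests fast

tiny_config <- function(pop = 2e5, ...) {
  region_config("tiny", initial_population = pop,
                service_capacities = c(gp = 1772, specialist = 354,
                                       inpatient = 20, cmhc = 189) * pop / 1e6,
                ...)
}

# Parameters with every flow switched off (for identity/flat checks);
# bypass validation guards that require a positive shock.
zero_params <- function() {
  p <- model_params(validate = FALSE)
  for (nm in names(p)) p[[nm]] <- 0
  p$shock_onset_multiplier <- 1
  p$shock_duration <- 1
  p$capm_gp <- 1; p$capm_specialist <- 1; p$capm_inpatient <- 1
  p$wait_cap_weeks <- 52
  structure(p, class = "mhsd_params")
}

no_demography <- function(config) {
  config$births_rate <- 0
  config$net_migration <- 0
  config$background_mortality <- 0
  config
}

# Published scenario outcomes for the study region: baseline plus the 17
# non-dominated four-intervention combinations, with counts (suicides, ED
# presentations, disengagements over 2021-2031) and reported percent
# reductions to one decimal place.
published_outcomes <- function() {
  tibble::tribble(
    ~label, ~suicides, ~pct_s, ~ed, ~pct_e, ~diseng, ~pct_d,
    "0", 1778, NA,   155901, NA,   544972, NA,
    "a", 1532, 13.8, 143266, 8.1,  501191, 8.0,
    "b", 1534, 13.7, 138444, 11.2, 506134, 7.1,
    "c", 1543, 13.2, 141327, 9.3,  505835, 7.2,
    "d", 1544, 13.2, 143114, 8.2,  496362, 8.9,
    "e", 1566, 11.9, 138145, 11.4, 501555, 8.0,
    "f", 1576, 11.4, 141079, 9.5,  501267, 8.0,
    "g", 1578, 11.2, 142842, 8.4,  491787, 9.8,
    "h", 1578, 11.2, 138001, 11.5, 496730, 8.9,
    "i", 1588, 10.7, 140963, 9.6,  496443, 8.9,
    "j", 1619, 8.9,  137991, 11.5, 494169, 9.3,
    "k", 1629, 8.4,  140891, 9.6,  493829, 9.4,
    "l", 1630, 8.3,  142641, 8.5,  484337, 11.1,
    "m", 1632, 8.2,  137852, 11.6, 489305, 10.2,
    "n", 1642, 7.6,  140782, 9.7,  488964, 10.3,
    "o", 1667, 6.2,  137573, 11.8, 484531, 11.1,
    "p", 1678, 5.6,  140555, 9.8,  484195, 11.2,
    "q", 1689, 5.0,  143738, 7.8,  483846, 11.2
  )
}

# Published district-level baseline splits (Central Coast, Hunter New
# England) for the aggregation checks.
published_district_baseline <- function() {
  tibble::tibble(
    scenario_id = "baseline",
    region_id = c("central_coast", "hunter_new_england"),
    window_start = 10, window_end = 20,
    suicides = c(471, 1307),
    ed_presentations = c(42423, 113478),
    disengagements = c(164293, 380678)
  )
}

# Brute-force all-pairs Pareto oracle (independent of pareto_front()).
pareto_oracle <- function(m) {
  n <- nrow(m)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

outcome_table_from_matrix <- function(m, region = "PHN") {
  tibble::tibble(
    scenario_id = sprintf("s%03d", seq_len(nrow(m))),
    region_id = region,
    suicides = m[, 1], ed_presentations = m[, 2], disengagements = m[, 3]
  )
}
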