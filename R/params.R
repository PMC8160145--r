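# Model parameters and region configuration.
#
# All rates are per person per year unless noted; capacities are services per
# week; time is measured in model years since 1 January 2011, with one model
# year = 52 weeks so that the 1/16-week integration grid divides it exactly.

# Order must match the parameter enum in src/engine.cpp.
.PARAM_NAMES <- c(
  "distress_onset_rate", "recovery_untreated", "help_seeking_rate",
  "gp_completion_rate", "frac_gp_recover", "frac_gp_specialist",
  "frac_gp_cmhc", "frac_gp_online",
  "specialist_completion_rate", "frac_specialist_success",
  "cmhc_completion_rate", "frac_cmhc_success",
  "online_completion_rate", "frac_online_success",
  "inpatient_discharge_rate",
  "base_disengagement_rate", "disengagement_wait_sensitivity",
  "re_engagement_rate",
  "attempt_hazard_untreated", "attempt_hazard_in_care", "attempt_hazard_post",
  "attempt_case_fatality", "attempt_hospitalised_frac",
  "ed_crisis_rate",
  "post_attempt_exit_rate", "frac_post_attempt_cmhc",
  "shock_start", "shock_duration", "shock_onset_multiplier",
  "births_rate", "net_migration", "background_mortality",
  "wait_cap_weeks",
  "safe_space_divert", "acute_care_divert", "aftercare_cmhc_cost",
  "connectedness_coverage", "education_help_seeking_effect",
  "capm_gp", "capm_specialist", "capm_inpatient", "cmhc_increment_per10k"
)

.FRACTION_PARAMS <- c(
  "frac_gp_recover", "frac_gp_specialist", "frac_gp_cmhc", "frac_gp_online",
  "frac_specialist_success", "frac_cmhc_success", "frac_online_success",
  "frac_post_attempt_cmhc", "attempt_case_fatality",
  "attempt_hospitalised_frac", "safe_space_divert", "acute_care_divert",
  "connectedness_coverage"
)

.SERVICES <- c("gp", "specialist", "inpatient", "cmhc")

#' Model parameters for the regional mental-health system dynamics model
#'
#' Returns the full parameter set of the stock-flow model as a named list,
#' with any subset overridden through `...`. Every free parameter of the
#' model is exposed here: distress onset and recovery, help seeking, service
#' completion rates and pathway referral fractions, disengagement and
#' re-engagement, state-specific suicide-attempt hazards with case-fatality
#' and hospitalised fractions, crisis emergency-department presentation
#' rates, the pandemic distress-onset shock, demography, and the neutral
#' values of the intervention effect channels (zero unless a program is
#' active).
#'
#' Rates are per person-year; `shock_start` is in model years since 1 January
#' 2011 (the default corresponds to 1 March 2020); capacities live in
#' [region_config()].
#'
#' @param ... named overrides of individual parameters.
#' @param validate check invariants (non-negative rates, fractions in
#'   `[0, 1]`, referral fractions summing to at most 1, in-care attempt
#'   hazard not exceeding the untreated hazard).
#' @return An object of class `mhsd_params`: a named list with one element
#'   per model parameter.
#' @examples
#' p <- model_params(attempt_case_fatality = 0.10)
#' p$attempt_case_fatality
#' @export
model_params <- function(..., validate = TRUE) {
  p <- list(
    distress_onset_rate = 0.140,
    recovery_untreated = 0.50,
    help_seeking_rate = 1.30,
    gp_completion_rate = 4.0,
    frac_gp_recover = 0.50,
    frac_gp_specialist = 0.20,
    frac_gp_cmhc = 0.10,
    frac_gp_online = 0.10,
    specialist_completion_rate = 3.0,
    frac_specialist_success = 0.75,
    cmhc_completion_rate = 3.0,
    frac_cmhc_success = 0.70,
    online_completion_rate = 8.0,
    frac_online_success = 0.50,
    inpatient_discharge_rate = 26.0,
    base_disengagement_rate = 0.85,
    disengagement_wait_sensitivity = 0.05,
    re_engagement_rate = 0.60,
    attempt_hazard_untreated = 0.0095,
    attempt_hazard_in_care = 0.006,
    attempt_hazard_post = 0.25,
    attempt_case_fatality = 0.11,
    attempt_hospitalised_frac = 0.85,
    ed_crisis_rate = 0.11,
    post_attempt_exit_rate = 4.0,
    frac_post_attempt_cmhc = 0.40,
    shock_start = 9.164,
    shock_duration = 2.0,
    shock_onset_multiplier = 1.10,
    births_rate = NA_real_,       # filled from region_config at simulation time
    net_migration = NA_real_,
    background_mortality = NA_real_,
    wait_cap_weeks = 52.0,
    safe_space_divert = 0.0,
    acute_care_divert = 0.0,
    aftercare_cmhc_cost = 0.0,
    connectedness_coverage = 0.0,
    education_help_seeking_effect = 0.0,
    capm_gp = 1.0,
    capm_specialist = 1.0,
    capm_inpatient = 1.0,
    cmhc_increment_per10k = 0.0
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "mhsd_params")
  if (validate) validate_params(p)
  p
}

#' @rdname model_params
#' @param params an `mhsd_params` object.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "mhsd_params"))
  num <- vapply(params, function(v) is.numeric(v) && length(v) == 1, logical(1))
  if (!all(num)) stop("all parameters must be length-1 numerics")
  vals <- unlist(params)
  rates <- vals[!is.na(vals)]
  if (any(rates[setdiff(names(rates), "net_migration")] < 0))
    stop("negative rate parameter: ",
         paste(names(which(rates < 0)), collapse = ", "))
  fr <- vals[.FRACTION_PARAMS]
  fr <- fr[!is.na(fr)]
  if (any(fr < 0 | fr > 1))
    stop("fraction outside [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  gp_sum <- params$frac_gp_recover + params$frac_gp_specialist +
    params$frac_gp_cmhc + params$frac_gp_online
  if (gp_sum > 1 + 1e-9)
    stop("GP episode-end fractions sum to ", round(gp_sum, 4), " > 1")
  if (params$attempt_hazard_in_care > params$attempt_hazard_untreated + 1e-12)
    stop("in-care attempt hazard must not exceed the untreated hazard")
  if (params$shock_onset_multiplier < 1) stop("shock multiplier must be >= 1")
  if (params$shock_duration <= 0) stop("shock duration must be positive")
  invisible(params)
}

#' Region configuration
#'
#' Describes one health district: its population, demography, initial
#' distress prevalence, baseline weekly service capacities and their annual
#' growth, and the district's share of the regional burden (used by the
#' synthetic-data generator to split PHN-level totals).
#'
#' @param region_id label for the region.
#' @param initial_population resident population at the start of 2011.
#' @param initial_distress_prevalence fraction of the population in the
#'   moderate-to-very-high psychological distress band (K10 >= 16) at start.
#' @param service_capacities named vector of baseline throughput
#'   (services/week) for `gp`, `specialist`, `inpatient`, `cmhc`.
#' @param capacity_growth named vector of annual capacity growth fractions
#'   for the same services.
#' @param births_rate,net_migration persons per year entering the modelled
#'   (adult) population.
#' @param background_mortality non-suicide mortality, fraction per year.
#' @param burden_share the region's share of regional totals.
#' @return An object of class `mhsd_config` (named list).
#' @examples
#' cfg <- region_config("demo", initial_population = 1e6)
#' cfg$service_capacities[["gp"]]
#' @export
region_config <- function(region_id = "region",
                          initial_population = 1e6,
                          initial_distress_prevalence = 0.135,
                          service_capacities = c(gp = 1772, specialist = 354,
                                                 inpatient = 20, cmhc = 189),
                          capacity_growth = c(gp = 0.03, specialist = 0.04,
                                              inpatient = 0.01, cmhc = 0.0),
                          births_rate = 0.0123 * initial_population,
                          net_migration = 0.004 * initial_population,
                          background_mortality = 0.0085,
                          burden_share = 1.0) {
  if (!is.numeric(initial_population) || initial_population <= 0)
    stop("initial_population must be positive")
  if (initial_distress_prevalence < 0 || initial_distress_prevalence > 1)
    stop("initial_distress_prevalence must be in [0, 1]")
  service_capacities <- service_capacities[.SERVICES]
  capacity_growth <- capacity_growth[.SERVICES]
  if (anyNA(service_capacities) || anyNA(capacity_growth))
    stop("service_capacities and capacity_growth must name all of: ",
         paste(.SERVICES, collapse = ", "))
  if (any(service_capacities < 0)) stop("capacities must be non-negative")
  structure(list(
    region_id = region_id,
    initial_population = initial_population,
    initial_distress_prevalence = initial_distress_prevalence,
    service_capacities = service_capacities,
    capacity_growth = capacity_growth,
    births_rate = births_rate,
    net_migration = net_migration,
    background_mortality = background_mortality,
    burden_share = burden_share
  ), class = "mhsd_config")
}

# Flatten params + config demography into the engine's numeric layout.
.param_vector <- function(params, config) {
  p <- params
  if (is.na(p$births_rate)) p$births_rate <- config$births_rate
  if (is.na(p$net_migration)) p$net_migration <- config$net_migration
  if (is.na(p$background_mortality)) p$background_mortality <- config$background_mortality
  v <- unlist(p[.PARAM_NAMES], use.names = FALSE)
  if (anyNA(v)) stop("unresolved NA parameter in engine vector")
  names(v) <- .PARAM_NAMES
  v
}

#' @export
print.mhsd_params <- function(x, ...) {
  cat("<mhsd_params> ", length(x), " parameters\n", sep = "")
  print(tibble::enframe(unlist(x), name = "parameter", value = "value"), n = 15)
  invisible(x)
}

#' @export
print.mhsd_config <- function(x, ...) {
  cat("<mhsd_config> ", x$region_id,
      ": population ", format(x$initial_population, big.mark = ","),
      ", distress prevalence ", x$initial_distress_prevalence, "\n", sep = "")
  invisible(x)
}
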