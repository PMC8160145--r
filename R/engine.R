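# Deterministic stock-flow simulator: R surface over the compiled
# explicit-Euler core (src/engine.cpp).

.STOCKS <- c("well", "distressed", "awaiting_gp", "in_gp_care",
             "awaiting_specialist", "in_specialist_care", "in_cmhc_care",
             "inpatient", "online_services", "disengaged", "post_attempt")
.CUMS <- c("suicide_deaths", "self_harm_hospitalisations",
           "ed_presentations", "disengagement_events")
.TRAJ_COLS <- c("time", .STOCKS, .CUMS,
                "gp_intake", "specialist_intake", "cmhc_intake",
                "inpatient_intake",
                "capacity_gp", "capacity_specialist", "capacity_inpatient",
                "capacity_cmhc_free", "wait_gp", "wait_specialist",
                "background_deaths")

#' Default integration step: one sixteenth of a week, in model years
#'
#' The model year is 52 weeks, so `dt = 0.4375/364` years reproduces the
#' 0.4375-day output grid (832 steps per year).
#' @export
mhsd_dt <- function() 0.4375 / 364

#' Initial state of a region
#'
#' Splits the population between the well and distressed states according to
#' the configured initial prevalence, and seeds the service-pathway stocks at
#' the steady-state occupancy implied by the baseline flows. The closed form
#' assumes unconstrained capacity: a unit help-seeking flow `F = h s x` out
#' of the untreated distressed stock `x` implies queue and care occupancies
#' proportional to `F` (one-week queues, `F / completion_rate` in-care
#' loads), a disengaged stock balancing base-rate disengagement against
#' recovery and re-engagement, and post-attempt/inpatient stocks balancing
#' attempt inflows against their exit rates; `x` is then solved so all
#' distress-band stocks sum to the configured prevalence.
#'
#' @param config an [region_config()] object.
#' @param params an [model_params()] object.
#' @return Named numeric vector of the 11 person stocks followed by the 4
#'   cumulative outcome counters (all counters zero).
#' @examples
#' s <- init_state(region_config("demo", initial_population = 1e6))
#' sum(s[1:11])  # equals the initial population
#' @export
init_state <- function(config, params = model_params()) {
  stopifnot(inherits(config, "mhsd_config"))
  validate_params(params)
  pop <- config$initial_population
  prev <- config$initial_distress_prevalence
  d_tot <- pop * prev

  hs <- params$help_seeking_rate
  fs <- params$frac_gp_specialist
  fc <- params$frac_gp_cmhc
  fo <- params$frac_gp_online
  sdiv <- function(a, b) if (b > 0) a / b else 0   # zero-rate => no occupancy
  # occupancy coefficients per unit of untreated distressed stock
  # (queues carry ~1 week of inflow; in-care loads are flow / completion)
  co <- c(
    awaiting_gp = hs / 52,
    in_gp_care = sdiv(hs, params$gp_completion_rate),
    awaiting_specialist = fs * hs / 52,
    in_specialist_care = sdiv(fs * hs, params$specialist_completion_rate),
    in_cmhc_care = sdiv(fc * hs, params$cmhc_completion_rate),
    online_services = sdiv(fo * hs, params$online_completion_rate)
  )
  co["disengaged"] <- sdiv(params$base_disengagement_rate * sum(co),
                           params$re_engagement_rate +
                             params$recovery_untreated)
  hu <- params$attempt_hazard_untreated
  cf <- params$attempt_case_fatality
  hf <- params$attempt_hospitalised_frac
  co["post_attempt"] <- sdiv(hu * (1 - cf) * (1 - hf),
                             params$post_attempt_exit_rate)
  co["inpatient"] <- sdiv(hu * (1 - cf) * hf, params$inpatient_discharge_rate)

  x <- d_tot / (1 + sum(co))      # untreated distressed stock
  s <- c(
    well = pop - d_tot,
    distressed = x,
    awaiting_gp = co[["awaiting_gp"]] * x,
    in_gp_care = co[["in_gp_care"]] * x,
    awaiting_specialist = co[["awaiting_specialist"]] * x,
    in_specialist_care = co[["in_specialist_care"]] * x,
    in_cmhc_care = co[["in_cmhc_care"]] * x,
    inpatient = co[["inpatient"]] * x,
    online_services = co[["online_services"]] * x,
    disengaged = co[["disengaged"]] * x,
    post_attempt = co[["post_attempt"]] * x
  )
  c(s, setNames(rep(0, length(.CUMS)), .CUMS))
}

#' Service capacity at a point in time
#'
#' Baseline capacity compounds at the configured annual growth fraction. A
#' multiplicative capacity lever (GP, specialist, inpatient) multiplies the
#' growth rate from its start date: after the lever starts, capacity grows
#' as `(1 + m * g)` per year. The CMHC lever instead adds an annual
#' increment in contacts per 10,000 population per week (default 0, no
#' growth).
#'
#' @param service_id one of `"gp"`, `"specialist"`, `"inpatient"`, `"cmhc"`.
#' @param t model time in years since the start of 2011.
#' @param config an [region_config()].
#' @param modifiers optional list with elements `start` (lever start time,
#'   default 0), `multiplier` (growth multiplier `m`, default 1) and
#'   `cmhc_increment` (contacts per 10,000 population per week added per
#'   year, default 0).
#' @return Capacity in services per week.
#' @examples
#' cfg <- region_config("demo", service_capacities = c(gp = 100, specialist = 10,
#'                      inpatient = 5, cmhc = 10),
#'                      capacity_growth = c(gp = 0.05, specialist = 0,
#'                      inpatient = 0, cmhc = 0))
#' capacity_at("gp", 1, cfg)                               # 105
#' capacity_at("gp", 1, cfg, list(multiplier = 2))         # 110
#' @export
capacity_at <- function(service_id, t, config, modifiers = NULL) {
  if (!service_id %in% .SERVICES)
    stop("unknown service_id: ", service_id)
  if (any(t < 0)) stop("t must be non-negative")
  base <- config$service_capacities[[service_id]]
  g <- config$capacity_growth[[service_id]]
  start <- modifiers$start %||% 0
  m <- modifiers$multiplier %||% 1
  inc <- modifiers$cmhc_increment %||% 0
  pre <- pmin(t, start)
  post <- pmax(t - start, 0)
  if (service_id == "cmhc") {
    base * (1 + g)^t + inc * config$initial_population / 1e4 * post
  } else {
    base * (1 + g)^pre * (1 + m * g)^post
  }
}

#' Queue waiting time by Little's law
#'
#' Expected wait is queue length divided by weekly throughput, capped at
#' `cap` weeks. A saturated queue (positive queue, zero throughput) returns
#' the cap and is flagged in the `"saturated"` attribute.
#'
#' @param queue persons waiting.
#' @param throughput persons served per week.
#' @param cap maximum reported wait in weeks.
#' @return Wait time in weeks (vectorised), with a logical `"saturated"`
#'   attribute.
#' @examples
#' wait_time(30, 10)   # 3 weeks
#' @export
wait_time <- function(queue, throughput, cap = 52) {
  stopifnot(all(queue >= 0), all(throughput >= 0))
  sat <- throughput == 0 & queue > 0
  w <- ifelse(queue == 0, 0,
              ifelse(sat, cap, pmin(queue / throughput, cap)))
  attr(w, "saturated") <- sat
  w
}

#' Pandemic distress-onset shock multiplier
#'
#' Rectangular pulse: the distress-onset rate is multiplied by
#' `onset_multiplier` for `start <= t < start + duration` and unchanged
#' elsewhere.
#'
#' @param t model time (years since 2011), vectorised.
#' @param shock list with `start`, `duration`, `onset_multiplier`.
#' @return Dimensionless multiplier.
#' @export
shock_multiplier <- function(t, shock = list(start = 9.164, duration = 2,
                                             onset_multiplier = 1.10)) {
  ifelse(t >= shock$start & t < shock$start + shock$duration,
         shock$onset_multiplier, 1)
}

#' Simulate one region
#'
#' Runs the deterministic explicit-Euler stock-flow model for one region
#' from 1 January 2011. With `interventions` supplied (a character vector of
#' catalogue ids), the intervention-modified parameters and capacity levers
#' take effect at `intervention_start`; an empty set reproduces the
#' business-as-usual run exactly.
#'
#' @param config an [region_config()].
#' @param params an [model_params()].
#' @param interventions character vector of intervention ids (see
#'   [intervention_catalogue()]), or `NULL` for business as usual.
#' @param t_end end of the run in model years since 2011 (default 28).
#' @param dt integration step in model years; default one sixteenth of a
#'   week ([mhsd_dt()]).
#' @param intervention_start model time at which interventions switch on
#'   (default 10, i.e. 1 January 2021).
#' @param init optional initial state (from [init_state()] or a previous
#'   trajectory row); defaults to `init_state(config, params)`.
#' @param t0 model time of `init` (default 0).
#' @param catalogue intervention catalogue (defaults to the built-in one).
#' @param effect_scale optional per-program effect scaling forwarded to
#'   [apply_interventions()].
#' @return An object of class `mhsd_trajectory`: a tibble with one row per
#'   grid point (columns: time, the 11 stocks, the 4 cumulative outcome
#'   counters, service intake flows, capacities and queue waits), carrying
#'   the config, params and step size as attributes.
#' @examples
#' traj <- simulate_region(region_config("demo", initial_population = 2e5),
#'                         t_end = 2, dt = 1 / 52)
#' tail(traj$suicide_deaths, 1)
#' @export
simulate_region <- function(config, params = model_params(),
                            interventions = NULL,
                            t_end = 28, dt = mhsd_dt(),
                            intervention_start = 10,
                            init = NULL, t0 = 0, catalogue = NULL,
                            effect_scale = NULL) {
  stopifnot(inherits(config, "mhsd_config"))
  validate_params(params)
  if (t_end <= t0) stop("t_end must exceed t0")
  p_base <- .param_vector(params, config)
  if (is.null(interventions) || length(interventions) == 0) {
    p_post <- p_base
    t_switch <- Inf
  } else {
    if (is.null(catalogue)) catalogue <- intervention_catalogue()
    mod <- apply_interventions(params, interventions, catalogue = catalogue,
                               effect_scale = effect_scale)
    p_post <- .param_vector(mod$params, config)
    t_switch <- intervention_start
  }
  if (is.null(init)) init <- init_state(config, params)
  m <- sd_core(unname(init), unname(p_base), unname(p_post), t_switch,
               unname(config$service_capacities[.SERVICES]),
               unname(config$capacity_growth[.SERVICES]),
               config$initial_population, t0, t_end, dt)
  colnames(m) <- .TRAJ_COLS
  traj <- tibble::as_tibble(as.data.frame(m))
  structure(traj,
            class = c("mhsd_trajectory", class(traj)),
            region_id = config$region_id, config = config, params = params,
            dt = dt, interventions = interventions %||% character(0))
}

#' Long-format export of a trajectory
#'
#' @param traj an `mhsd_trajectory`.
#' @return Tidy tibble with columns `region_id`, `time`, `variable`, `value`.
#' @export
tidy_trajectory <- function(traj) {
  stopifnot(inherits(traj, "mhsd_trajectory"))
  out <- tidyr::pivot_longer(tibble::as_tibble(traj), -"time",
                             names_to = "variable", values_to = "value")
  dplyr::mutate(out, region_id = attr(traj, "region_id"), .before = 1)
}

#' Annualised outcome flows along a trajectory
#'
#' Converts the cumulative outcome counters into events-per-year series
#' using a centred one-year rolling window of the event flow (so a value at
#' time `t` is the number of events in `[t - 1/2, t + 1/2]`).
#'
#' @param traj an `mhsd_trajectory`.
#' @return Tibble with `time` and annualised `suicides_per_yr`,
#'   `ed_presentations_per_yr`, `disengagements_per_yr`, plus the distress
#'   prevalence series.
#' @export
annualise_trajectory <- function(traj) {
  stopifnot(inherits(traj, "mhsd_trajectory"))
  dt <- attr(traj, "dt")
  half <- round(0.5 / dt)
  n <- nrow(traj)
  roll <- function(cum) {
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cum[hi] - cum[lo]) / ((hi - lo) * dt)
  }
  pop <- rowSums(traj[, .STOCKS])
  tibble::tibble(
    time = traj$time,
    suicides_per_yr = roll(traj$suicide_deaths),
    ed_presentations_per_yr = roll(traj$ed_presentations),
    disengagements_per_yr = roll(traj$disengagement_events),
    self_harm_hospitalisations_per_yr = roll(traj$self_harm_hospitalisations),
    distress_prevalence = 1 - traj$well / pop,
    population = pop
  )
}

#' @export
print.mhsd_trajectory <- function(x, ...) {
  cat("<mhsd_trajectory> region ", attr(x, "region_id"),
      ": ", nrow(x), " grid points, t in [",
      round(min(x$time), 3), ", ", round(max(x$time), 3), "]\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
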