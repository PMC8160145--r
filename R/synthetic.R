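# Synthetic regional data generator: district profiles with the published
# headline statistics of the study region, and noisy "historical" series so
# calibration, scenario search and sensitivity analysis are testable without
# access to the confidential regional datasets.

.PHN_POPULATION <- 1269782
.PHN_CAPACITIES <- c(gp = 2250, specialist = 450, inpatient = 26, cmhc = 240)
.PHN_CAP_GROWTH <- c(gp = 0.03, specialist = 0.04, inpatient = 0.01, cmhc = 0)

#' Default synthetic district profiles
#'
#' Two districts mirroring the study region's structure: a larger district
#' carrying about 73.5% of the regional burden and a smaller one carrying
#' about 26.5% (the split implied by baseline suicide counts of 1307 and
#' 471), scaled to a total population of 1,269,782, with distress
#' prevalence 13.5 per 100 adults and a suicide rate of 13.7 per 100,000
#' per year.
#'
#' @param noise_cv coefficient of variation of the multiplicative
#'   observation noise applied by [generate_history()].
#' @return Tibble with `name`, `population`, `distress_rate_per_100`,
#'   `suicide_rate_per_100k`, `burden_share`, `noise_cv`.
#' @examples
#' sum(default_profiles()$population)  # 1269782
#' @export
default_profiles <- function(noise_cv = 0.05) {
  share <- c(1307, 471) / 1778
  pop <- round(share * .PHN_POPULATION)
  pop[1] <- .PHN_POPULATION - pop[2]   # shares must sum exactly to the total
  tibble::tibble(
    name = c("hunter_new_england", "central_coast"),
    population = pop,
    distress_rate_per_100 = 13.5,
    suicide_rate_per_100k = 13.7,
    burden_share = share,
    noise_cv = noise_cv
  )
}

#' Region configurations from synthetic profiles
#'
#' Extensive quantities (population, capacities, demographic flows) scale
#' linearly with the burden share; rates are common across districts.
#'
#' @param profiles tibble from [default_profiles()].
#' @return Named list of [region_config()] objects.
#' @export
profile_configs <- function(profiles = default_profiles()) {
  cfgs <- lapply(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, ]
    region_config(
      region_id = pr$name,
      initial_population = pr$population,
      initial_distress_prevalence = pr$distress_rate_per_100 / 100,
      service_capacities = .PHN_CAPACITIES * pr$burden_share,
      capacity_growth = .PHN_CAP_GROWTH,
      burden_share = pr$burden_share
    )
  })
  setNames(cfgs, profiles$name)
}

#' Generate noisy historical calibration series
#'
#' Simulates the truth parameters over the historical period, samples the
#' six calibration series at annual timestamps (model years 1..7, i.e.
#' start of 2012 through start of 2018, matching the annual cadence of the
#' public data collections the series correspond to), and applies
#' multiplicative lognormal observation noise with the requested
#' coefficient of variation (mean 1, so noise is unbiased).
#'
#' @param config a [region_config()].
#' @param params the data-generating (truth) parameters.
#' @param noise_cv coefficient of variation (`0` returns the model series
#'   exactly).
#' @param seed integer seed for the noise.
#' @param times annual timestamps.
#' @param dt integration step used for the truth run.
#' @return An [calibration_targets()] object.
#' @export
generate_history <- function(config, params = model_params(),
                             noise_cv = 0.05, seed = 1,
                             times = 1:7, dt = 1 / 104) {
  stopifnot(noise_cv >= 0)
  traj <- simulate_region(config, params, t_end = max(times) + 2 * dt,
                          dt = dt)
  series <- model_series(traj, setNames(rep(list(times),
                                            length(.TARGET_SERIES)),
                                        .TARGET_SERIES))
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log1p(noise_cv^2))
    series$value <- series$value *
      rlnorm(nrow(series), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  calibration_targets(series)
}

#' Parameter-recovery fixture
#'
#' Packages a complete generate-and-refit bundle: seeded truth parameters
#' (the six default free parameters jittered around the package defaults),
#' the two synthetic district configurations, noiseless and noisy target
#' sets for the larger district, and the free-parameter list with bounds.
#' Regenerating with the same seed is bit-identical.
#'
#' @param seed integer seed.
#' @param noise_cv coefficient of variation of the noisy target set.
#' @return List with `truth_params`, `base_params`, `configs`, `free`,
#'   `bounds`, `targets_noiseless`, `targets_noisy`, `seed`.
#' @export
recovery_fixture <- function(seed = 1, noise_cv = 0.05) {
  free <- c("distress_onset_rate", "help_seeking_rate",
            "frac_gp_specialist", "attempt_hazard_untreated",
            "attempt_hospitalised_frac", "inpatient_discharge_rate")
  base <- model_params()
  set.seed(seed)
  jitter <- runif(length(free), 0.88, 1.12)
  truth <- base
  for (i in seq_along(free)) truth[[free[i]]] <- base[[free[i]]] * jitter[i]
  truth <- structure(truth, class = "mhsd_params")
  validate_params(truth)
  configs <- profile_configs()
  bounds <- lapply(setNames(free, free), function(nm)
    c(0.5, 1.5) * base[[nm]])
  list(
    truth_params = truth,
    base_params = base,
    configs = configs,
    free = free,
    bounds = bounds,
    targets_noiseless = generate_history(configs[[1]], truth, noise_cv = 0),
    targets_noisy = generate_history(configs[[1]], truth,
                                     noise_cv = noise_cv, seed = seed),
    seed = seed
  )
}
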