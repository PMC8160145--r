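# Latin hypercube propagation of uncertainty in intervention effect sizes
# and pandemic-shock duration through the scenario pipeline.

#' Default sensitivity dimensions
#'
#' One dimension per program effect (a dimensionless scale factor on the
#' program's deviation from no-effect, default 1, varied +/-20%) plus the
#' pandemic distress-shock duration (varied +/-50% of its default).
#' Capacity levers are policy settings, not uncertain effects, and are not
#' varied.
#'
#' @param params baseline [model_params()] (supplies the default shock
#'   duration).
#' @param catalogue intervention catalogue.
#' @return Tibble `path`, `low`, `high`, `default`.
#' @export
default_sensitivity_dims <- function(params = model_params(),
                                     catalogue = intervention_catalogue()) {
  progs <- catalogue$id[catalogue$kind == "program"]
  dims <- tibble::tibble(
    path = paste0("effect:", progs),
    low = 0.8, high = 1.2, default = 1
  )
  dplyr::bind_rows(dims, tibble::tibble(
    path = "shock_duration",
    low = 0.5 * params$shock_duration,
    high = 1.5 * params$shock_duration,
    default = params$shock_duration
  ))
}

#' Latin hypercube design
#'
#' Stratified uniform sampling: for each dimension the `n` draws occupy the
#' `n` equal-probability strata exactly once, scaled to `[low, high]`.
#' Reproducible under `seed`.
#'
#' @param dims tibble with `path`, `low`, `high` (see
#'   [default_sensitivity_dims()]).
#' @param n number of samples.
#' @param seed integer seed.
#' @return Object of class `mhsd_lhs`: list with `samples` (an `n` by
#'   `nrow(dims)` matrix, columns named by `path`), `dims`, `n`, `seed`.
#' @export
lhs_design <- function(dims, n = 100, seed = 1) {
  stopifnot(n >= 1, nrow(dims) >= 1)
  if (any(dims$high <= dims$low)) stop("degenerate range in dims")
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(dims))
  samples <- sweep(sweep(u, 2, dims$high - dims$low, `*`), 2, dims$low, `+`)
  colnames(samples) <- dims$path
  structure(list(samples = samples, dims = dims, n = n, seed = seed),
            class = "mhsd_lhs")
}

#' Propagate a design through the scenario pipeline
#'
#' For each Latin-hypercube draw the program effect scales and shock
#' duration are set, the baseline and each scenario are re-simulated, and
#' percent reductions are recorded per scenario, region and outcome. A
#' failed draw is recorded (NA values) rather than aborting the analysis.
#'
#' @param design an [lhs_design()].
#' @param sets scenario table ([enumerate_sets()] rows) to evaluate.
#' @param configs list of region configurations.
#' @param params baseline parameters.
#' @param window evaluation window in model years.
#' @param dt integration step (a coarser step than the reporting grid keeps
#'   100-draw analyses fast).
#' @param catalogue intervention catalogue.
#' @return Tibble of draws: `draw`, `scenario_id`, `region_id`, `outcome`,
#'   `count`, `pct_reduction`.
#' @export
run_sensitivity <- function(design, sets, configs, params = model_params(),
                            window = c(10, 20), dt = 1 / 104,
                            catalogue = intervention_catalogue()) {
  stopifnot(inherits(design, "mhsd_lhs"))
  eff_cols <- grep("^effect:", colnames(design$samples), value = TRUE)
  out <- vector("list", design$n)
  for (i in seq_len(design$n)) {
    x <- design$samples[i, ]
    scale <- setNames(x[eff_cols], sub("^effect:", "", eff_cols))
    p <- params
    if ("shock_duration" %in% names(x))
      p$shock_duration <- unname(x[["shock_duration"]])
    res <- tryCatch({
      tab <- evaluate_scenarios(configs, p, sets = sets, window = window,
                                dt = dt, catalogue = catalogue,
                                effect_scale = scale)
      long <- tidyr::pivot_longer(
        tibble::as_tibble(tab)[, c("scenario_id", "region_id", .OUTCOMES,
                                   paste0("pct_", .OUTCOMES))],
        cols = -c("scenario_id", "region_id"),
        names_to = "name", values_to = "value")
      counts <- dplyr::filter(long, !startsWith(.data$name, "pct_"))
      pcts <- dplyr::filter(long, startsWith(.data$name, "pct_"))
      dplyr::mutate(
        tibble::tibble(
          draw = i,
          scenario_id = counts$scenario_id,
          region_id = counts$region_id,
          outcome = counts$name,
          count = counts$value,
          pct_reduction = pcts$value[match(
            paste(counts$scenario_id, counts$region_id, paste0("pct_", counts$name)),
            paste(pcts$scenario_id, pcts$region_id, pcts$name))]
        ))
    }, error = function(e) {
      warning("draw ", i, " failed: ", conditionMessage(e))
      tibble::tibble(draw = i, scenario_id = NA_character_,
                     region_id = NA_character_, outcome = NA_character_,
                     count = NA_real_, pct_reduction = NA_real_)
    })
    out[[i]] <- res
  }
  purrr::list_rbind(out)
}

#' Interval summaries of sensitivity draws
#'
#' Mean and empirical 50% and 95% intervals of the percent reductions, per
#' scenario, region and outcome. Quantiles use the linear-interpolation
#' rule between order statistics ([stats::quantile()] type 7).
#'
#' @param draws output of [run_sensitivity()].
#' @return Tibble with `scenario_id`, `region_id`, `outcome`, `n_draws`,
#'   `mean`, `q2.5`, `q25`, `q75`, `q97.5`.
#' @export
summarise_draws <- function(draws) {
  ok <- draws[!is.na(draws$scenario_id) & draws$scenario_id != "baseline", ]
  if (nrow(ok) == 0) stop("no successful draws to summarise")
  dplyr::summarise(
    dplyr::group_by(ok, .data$scenario_id, .data$region_id, .data$outcome),
    n_draws = sum(!is.na(.data$pct_reduction)),
    mean = mean(.data$pct_reduction, na.rm = TRUE),
    q2.5 = quantile(.data$pct_reduction, 0.025, na.rm = TRUE, names = FALSE),
    q25 = quantile(.data$pct_reduction, 0.25, na.rm = TRUE, names = FALSE),
    q75 = quantile(.data$pct_reduction, 0.75, na.rm = TRUE, names = FALSE),
    q97.5 = quantile(.data$pct_reduction, 0.975, na.rm = TRUE, names = FALSE),
    .groups = "drop"
  )
}
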