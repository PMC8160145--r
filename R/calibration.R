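# Calibration of free model parameters to historical series by Powell's
# derivative-free conjugate-direction method, minimising the sum of the
# per-series mean absolute percent errors (MAPE).

.TARGET_SERIES <- c("distress_prevalence", "self_harm_hospitalisation_rate",
                    "suicide_rate", "gp_mh_consultations_per_yr",
                    "allied_services_per_yr", "psych_bed_occupancy")

#' Mean absolute percent error
#'
#' `100/n * sum(|obs - sim| / |obs|)`. Observed values must be non-zero.
#'
#' @param observed,simulated equal-length numeric vectors.
#' @return MAPE in percent.
#' @examples
#' mape(c(100, 200), c(110, 180))  # 10
#' @export
mape <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 1)
    stop("observed and simulated must have equal positive length")
  zero <- which(observed == 0)
  if (length(zero))
    stop("zero observed value at position ", zero[1],
         "; MAPE is undefined there")
  100 * mean(abs(observed - simulated) / abs(observed))
}

#' Historical calibration targets
#'
#' Validates and classes a long table of historical series: psychological
#' distress prevalence (fraction), self-harm hospitalisation and suicide
#' rates (per 100,000 per year), GP mental-health consultations and
#' psychiatrist/allied services delivered per year, and psychiatric bed
#' occupancy (persons).
#'
#' @param data tibble/data.frame with columns `series`, `time` (model years
#'   since 2011) and `value` (> 0).
#' @return The validated tibble, classed `mhsd_targets`.
#' @export
calibration_targets <- function(data) {
  req <- c("series", "time", "value")
  if (!all(req %in% names(data))) stop("targets need columns series, time, value")
  data <- tibble::as_tibble(data[req])
  if (any(data$value <= 0))
    stop("all observed target values must be positive (MAPE denominators)")
  ord <- dplyr::group_by(data, .data$series)
  chk <- dplyr::summarise(ord, ok = !is.unsorted(.data$time, strictly = TRUE))
  if (!all(chk$ok)) stop("timestamps must be strictly increasing per series")
  structure(data, class = c("mhsd_targets", class(data)))
}

#' Model counterparts of the calibration series
#'
#' Extracts, from a simulated trajectory, the six observable series used for
#' calibration, evaluated at the requested timestamps. Rates and annual
#' service volumes are trailing 12-month totals, so timestamps must be at
#' least one model year after the start of the run; stock-type series are
#' linearly interpolated to the timestamps.
#'
#' @param traj an `mhsd_trajectory` spanning the requested times.
#' @param times named list mapping series name to its numeric timestamps.
#' @return Tibble `series`, `time`, `value`.
#' @export
model_series <- function(traj, times) {
  stopifnot(inherits(traj, "mhsd_trajectory"))
  dt <- attr(traj, "dt")
  pop <- rowSums(traj[, .STOCKS])
  cum_gp <- cumsum(traj$gp_intake) * dt
  cum_spec <- cumsum(traj$specialist_intake) * dt
  trail <- function(cum, t) {
    approx(traj$time, cum, xout = t, rule = 2)$y -
      approx(traj$time, cum, xout = t - 1, rule = 2)$y
  }
  interp <- function(v, t) approx(traj$time, v, xout = t, rule = 2)$y
  eval_one <- function(series, t) {
    switch(series,
      distress_prevalence = interp(1 - traj$well / pop, t),
      self_harm_hospitalisation_rate =
        trail(traj$self_harm_hospitalisations, t) / interp(pop, t) * 1e5,
      suicide_rate = trail(traj$suicide_deaths, t) / interp(pop, t) * 1e5,
      gp_mh_consultations_per_yr = trail(cum_gp, t),
      allied_services_per_yr = trail(cum_spec, t),
      psych_bed_occupancy = interp(traj$inpatient, t),
      stop("unknown series: ", series)
    )
  }
  purrr::list_rbind(purrr::imap(times, function(t, nm)
    tibble::tibble(series = nm, time = t, value = eval_one(nm, t))))
}

#' Summed-MAPE calibration objective
#'
#' Decodes a free-parameter vector into the model parameter set, simulates
#' the historical period, samples the model counterparts of each target
#' series at the observed timestamps, and returns the sum over series of
#' the mean absolute percent error. Simulation failures return a large
#' finite penalty so derivative-free search can continue.
#'
#' @param x numeric vector, one value per entry of `free`.
#' @param free character vector of parameter names being fitted.
#' @param targets an [calibration_targets()] table.
#' @param config region configuration used for the historical runs.
#' @param params baseline parameters for everything not in `free`.
#' @param dt integration step (coarser than the reporting grid is fine for
#'   optimisation; the default keeps the historical fit fast).
#' @param penalty objective value returned on simulation failure.
#' @return Objective in percent (sum of per-series MAPEs), with the
#'   per-series breakdown in the `"per_series"` attribute.
#' @export
calibration_objective <- function(x, free, targets, config,
                                  params = model_params(), dt = 1 / 104,
                                  penalty = 1e6) {
  stopifnot(length(x) == length(free))
  p <- unclass(params)
  p[free] <- as.list(x)
  p <- structure(p, class = "mhsd_params")
  res <- tryCatch({
    validate_params(p)
    t_end <- max(targets$time) + 2 * dt
    traj <- simulate_region(config, p, t_end = t_end, dt = dt)
    times <- split(targets$time, targets$series)
    sim <- model_series(traj, times)
    obs <- dplyr::arrange(tibble::as_tibble(targets), .data$series, .data$time)
    sim <- dplyr::arrange(sim, .data$series, .data$time)
    per <- vapply(split(seq_len(nrow(obs)), obs$series), function(i)
      mape(obs$value[i], sim$value[i]), numeric(1))
    structure(sum(per), per_series = per)
  }, error = function(e) structure(penalty, per_series = NULL))
  res
}

#' Powell's conjugate-direction minimisation with box constraints
#'
#' Derivative-free minimisation in the style of Powell's method: repeated
#' exact line minimisations (Brent's method via [stats::optimize()]) along a
#' set of directions, with the classic direction-replacement rule. Bounds
#' are handled by working in box-normalised coordinates and clipping line
#' searches to the feasible segment, so every evaluated point is inside the
#' box. Accepted iterates are monotonically non-increasing in the objective.
#'
#' @param fn objective function of a numeric vector.
#' @param x0 start point (within bounds).
#' @param lower,upper bounds vectors.
#' @param xtol convergence tolerance on the (normalised) coordinates.
#' @param ftol relative convergence tolerance on the objective.
#' @param max_iter maximum outer iterations.
#' @return List with `par`, `value`, `iterations`, `fn_evals`, `converged`,
#'   `bounds_active` (names/indices of coordinates within `xtol` of a
#'   bound) and `trace` (accepted objective values).
#' @examples
#' fit <- powell_fit(function(x) sum((x - 2)^2), c(0, 0),
#'                   lower = c(-5, -5), upper = c(5, 5))
#' fit$par
#' @export
powell_fit <- function(fn, x0, lower, upper, xtol = 1e-4, ftol = 1e-6,
                       max_iter = 200) {
  d <- length(x0)
  stopifnot(length(lower) == d, length(upper) == d, all(upper > lower))
  if (any(x0 < lower - 1e-12) || any(x0 > upper + 1e-12))
    stop("x0 outside bounds")
  span <- upper - lower
  decode <- function(z) lower + pmin(1, pmax(0, z)) * span
  n_eval <- 0L
  fz <- function(z) { n_eval <<- n_eval + 1L; fn(decode(z)) }

  z <- (x0 - lower) / span
  f <- as.numeric(fz(z))
  if (!is.finite(f)) stop("objective not finite at x0")
  trace <- f

  line_min <- function(z, f, dir) {
    nz <- dir != 0
    if (!any(nz)) return(list(z = z, f = f))
    lo <- (0 - z[nz]) / dir[nz]
    hi <- (1 - z[nz]) / dir[nz]
    a <- max(pmin(lo, hi)); b <- min(pmax(lo, hi))
    if (!is.finite(a) || !is.finite(b) || b - a < 1e-12)
      return(list(z = z, f = f))
    opt <- optimize(function(al) as.numeric(fz(z + al * dir)),
                    interval = c(a, b), tol = xtol / 4)
    if (is.finite(opt$objective) && opt$objective < f) {
      list(z = pmin(1, pmax(0, z + opt$minimum * dir)), f = opt$objective)
    } else list(z = z, f = f)
  }

  dirs <- diag(d)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    z0 <- z; f0 <- f
    biggest <- 0; ibig <- 1L
    for (i in seq_len(d)) {
      res <- line_min(z, f, dirs[, i])
      if (f - res$f > biggest) { biggest <- f - res$f; ibig <- i }
      z <- res$z; f <- res$f
    }
    trace <- c(trace, f)
    if (2 * (f0 - f) <= ftol * (abs(f0) + abs(f)) + 1e-12 ||
        sqrt(sum((z - z0)^2)) < xtol) {
      converged <- TRUE
      break
    }
    # Powell's direction-replacement test (extrapolated point)
    ze <- pmin(1, pmax(0, 2 * z - z0))
    fe <- as.numeric(fz(ze))
    if (fe < f0) {
      tmp <- 2 * (f0 - 2 * f + fe) * (f0 - f - biggest)^2 -
        biggest * (f0 - fe)^2
      if (tmp < 0) {
        newdir <- z - z0
        if (sqrt(sum(newdir^2)) > 1e-12) {
          res <- line_min(z, f, newdir / sqrt(sum(newdir^2)))
          z <- res$z; f <- res$f
          dirs[, ibig] <- dirs[, d]
          dirs[, d] <- newdir / sqrt(sum(newdir^2))
        }
      }
    }
  }
  par <- decode(z)
  active <- which(z < xtol | z > 1 - xtol)
  list(par = par, value = f, iterations = iter, fn_evals = n_eval,
       converged = converged, bounds_active = active, trace = trace)
}

#' Calibrate the model to historical series
#'
#' Fits the chosen free parameters by minimising the summed per-series MAPE
#' with [powell_fit()], from the baseline values plus a configurable number
#' of seeded jittered restarts (best result kept).
#'
#' @inheritParams calibration_objective
#' @param free character vector of parameter names to fit; the default
#'   frees the six least-evidenced, identifiable rates.
#' @param bounds named list mapping each free parameter to `c(lower,
#'   upper)`; default is `[0.5, 1.5]` times the baseline value.
#' @param restarts number of additional jittered starts.
#' @param seed integer seed controlling the restart jitter.
#' @param xtol,ftol,max_iter forwarded to [powell_fit()].
#' @return An object of class `mhsd_calibration`: fitted `params`, the
#'   objective value and per-series MAPEs, iteration counts, convergence
#'   flag and active bounds. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
calibrate_model <- function(targets, config, params = model_params(),
                            free = c("distress_onset_rate",
                                     "help_seeking_rate",
                                     "frac_gp_specialist",
                                     "attempt_hazard_untreated",
                                     "attempt_hospitalised_frac",
                                     "inpatient_discharge_rate"),
                            bounds = NULL, dt = 1 / 104,
                            restarts = 3, seed = 1,
                            xtol = 1e-4, ftol = 1e-6, max_iter = 200) {
  stopifnot(inherits(targets, "mhsd_targets"))
  x_base <- unlist(unclass(params)[free])
  if (anyNA(x_base)) stop("free parameters must have baseline values")
  if (is.null(bounds))
    bounds <- lapply(setNames(free, free), function(nm)
      c(0.5, 1.5) * x_base[[nm]])
  lower <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))

  obj <- function(x) calibration_objective(x, free, targets, config, params,
                                           dt = dt)
  starts <- list(pmin(pmax(x_base, lower), upper))
  if (restarts > 0) {
    set.seed(seed)
    for (r in seq_len(restarts))
      starts[[r + 1]] <- lower + runif(length(free)) * (upper - lower)
  }
  fits <- lapply(starts, function(x0)
    powell_fit(obj, x0, lower, upper, xtol = xtol, ftol = ftol,
               max_iter = max_iter))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  fitted <- unclass(params)
  fitted[free] <- as.list(best$par)
  fitted <- structure(fitted, class = "mhsd_params")
  final <- calibration_objective(best$par, free, targets, config, params,
                                 dt = dt)
  structure(list(
    params = fitted, free = free,
    estimates = setNames(best$par, free),
    lower = lower, upper = upper, start = x_base,
    objective = as.numeric(final),
    per_series = attr(final, "per_series"),
    iterations = best$iterations, fn_evals = best$fn_evals,
    converged = best$converged,
    bounds_active = free[best$bounds_active],
    restart_values = vapply(fits, `[[`, numeric(1), "value")
  ), class = "mhsd_calibration")
}

#' @export
print.mhsd_calibration <- function(x, ...) {
  cat("<mhsd_calibration> summed MAPE ", round(x$objective, 4), "% over ",
      length(x$per_series), " series; ", x$iterations, " iterations (",
      if (x$converged) "converged" else "max_iter", ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname calibrate_model
#' @param x an `mhsd_calibration` object.
#' @param ... unused.
#' @export
tidy.mhsd_calibration <- function(x, ...) {
  tibble::tibble(
    term = x$free,
    estimate = unname(x$estimates),
    start = unname(x$start),
    lower = unname(x$lower),
    upper = unname(x$upper),
    at_bound = x$free %in% x$bounds_active
  )
}

#' @rdname calibrate_model
#' @export
glance.mhsd_calibration <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_series = length(x$per_series),
    n_free = length(x$free),
    iterations = x$iterations,
    fn_evals = x$fn_evals,
    converged = x$converged
  )
}
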