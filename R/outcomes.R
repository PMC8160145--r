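# Cumulative scenario outcomes over an evaluation window, and aggregation
# of constituent districts to the whole region.

#' Cumulative outcomes over a window
#'
#' Differences the cumulative counters of a trajectory between the window
#' end and start (linear interpolation between grid points), giving the
#' numbers of suicides, mental health-related ED presentations and service
#' disengagements accrued in the window.
#'
#' @param traj an `mhsd_trajectory`.
#' @param window numeric length-2, `[start, end]` in model years since 2011
#'   (e.g. `c(10, 20)` for 2021--2031).
#' @param scenario_id label recorded in the result.
#' @return One-row tibble: `scenario_id`, `region_id`, `window_start`,
#'   `window_end`, `suicides`, `ed_presentations`, `disengagements`.
#' @examples
#' traj <- simulate_region(region_config("demo", initial_population = 2e5),
#'                         t_end = 3, dt = 1 / 52)
#' cumulative_outcomes(traj, c(1, 3))
#' @export
cumulative_outcomes <- function(traj, window, scenario_id = "baseline") {
  stopifnot(inherits(traj, "mhsd_trajectory"), length(window) == 2)
  if (window[2] < window[1]) stop("window end precedes start")
  tmin <- min(traj$time); tmax <- max(traj$time)
  if (window[1] < tmin - 1e-9 || window[2] > tmax + 1e-9)
    stop("window [", window[1], ", ", window[2],
         "] outside trajectory span [", round(tmin, 3), ", ",
         round(tmax, 3), "]")
  at <- function(col, t) approx(traj$time, traj[[col]], xout = t,
                                rule = 2)$y
  d <- function(col) at(col, window[2]) - at(col, window[1])
  tibble::tibble(
    scenario_id = scenario_id,
    region_id = attr(traj, "region_id"),
    window_start = window[1], window_end = window[2],
    suicides = d("suicide_deaths"),
    ed_presentations = d("ed_presentations"),
    disengagements = d("disengagement_events")
  )
}

#' Aggregate district outcomes to the regional (PHN) level
#'
#' Component-wise sum of outcome counts across regions, per scenario. All
#' rows of a scenario must share the same window.
#'
#' @param outcomes tibble of outcome rows as produced by
#'   [cumulative_outcomes()] (possibly many scenarios and regions).
#' @param region_id label for the aggregate (default `"PHN"`).
#' @return Tibble with one row per scenario.
#' @examples
#' x <- tibble::tibble(scenario_id = "baseline", region_id = c("A", "B"),
#'                     window_start = 10, window_end = 20,
#'                     suicides = c(471, 1307),
#'                     ed_presentations = c(42423, 113478),
#'                     disengagements = c(164293, 380678))
#' aggregate_regions(x)$suicides  # 1778
#' @export
aggregate_regions <- function(outcomes, region_id = "PHN") {
  req <- c("scenario_id", "region_id", "window_start", "window_end",
           "suicides", "ed_presentations", "disengagements")
  if (!all(req %in% names(outcomes))) stop("malformed outcome table")
  chk <- dplyr::summarise(dplyr::group_by(outcomes, .data$scenario_id),
                          nw = dplyr::n_distinct(.data$window_start,
                                                 .data$window_end))
  if (any(chk$nw != 1)) stop("mismatched windows within a scenario")
  out <- dplyr::summarise(
    dplyr::group_by(outcomes, .data$scenario_id),
    window_start = .data$window_start[1],
    window_end = .data$window_end[1],
    suicides = sum(.data$suicides),
    ed_presentations = sum(.data$ed_presentations),
    disengagements = sum(.data$disengagements),
    .groups = "drop"
  )
  dplyr::mutate(out, region_id = region_id, .after = "scenario_id")
}
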