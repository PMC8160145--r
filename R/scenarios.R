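# Exhaustive k-of-12 scenario evaluation, percent reductions against
# business as usual, and Pareto (non-dominated) filtering across the three
# minimised outcomes.

.OUTCOMES <- c("suicides", "ed_presentations", "disengagements")

#' Enumerate intervention sets
#'
#' All unordered size-`k` subsets of the catalogue ids, in deterministic
#' lexicographic order. `k = 0` yields the single empty (business-as-usual)
#' set.
#'
#' @param catalogue catalogue tibble or character vector of ids.
#' @param k subset size.
#' @return Tibble with `scenario_id` (ids joined by `+`; `"baseline"` for
#'   the empty set) and `interventions` (list column of character vectors).
#' @examples
#' nrow(enumerate_sets(intervention_catalogue(), 4))  # 495
#' @export
enumerate_sets <- function(catalogue, k) {
  ids <- if (is.character(catalogue)) catalogue else catalogue$id
  ids <- sort(unique(ids))
  if (k < 0 || k > length(ids)) stop("k must be between 0 and ", length(ids))
  if (k == 0)
    return(tibble::tibble(scenario_id = "baseline",
                          interventions = list(character(0))))
  sets <- combn(ids, k, simplify = FALSE)
  tibble::tibble(
    scenario_id = vapply(sets, paste, character(1), collapse = "+"),
    interventions = sets
  )
}

#' Percent reduction against baseline
#'
#' `100 * (baseline - scenario) / baseline`; positive when the scenario
#' prevents events.
#'
#' @param baseline_count,scenario_count outcome counts.
#' @return Percent reduction.
#' @examples
#' round(percent_reduction(1778, 1532), 1)  # 13.8
#' @export
percent_reduction <- function(baseline_count, scenario_count) {
  if (any(baseline_count <= 0)) stop("baseline count must be positive")
  100 * (baseline_count - scenario_count) / baseline_count
}

#' Pareto dominance between two outcome triplets
#'
#' Under minimisation, `a` dominates `b` iff `a` is no worse on every
#' outcome and strictly better on at least one. Identical triplets do not
#' dominate each other.
#'
#' @param a,b numeric vectors of outcome counts (same outcomes, same
#'   region/window).
#' @return Logical.
#' @examples
#' dominates(c(10, 10, 10), c(11, 10, 12))  # TRUE
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("outcome vectors differ in length")
  all(a <= b) && any(a < b)
}

#' Pareto front of an outcome table
#'
#' Identifies the non-dominated scenarios of one region: those not weakly
#' beaten on all three outcomes (strictly on at least one) by any other
#' scenario. Ties (identical triplets) are all retained. The baseline row,
#' if present, is excluded from the candidate set.
#'
#' @param table outcome table (one row per scenario for the chosen region)
#'   with columns `scenario_id`, `region_id` and the three outcome counts.
#' @param region region to filter on (`NULL` uses all rows as-is).
#' @param objectives outcome column names (minimised).
#' @return An object of class `mhsd_pareto`: list with `non_dominated`
#'   (scenario ids), `dominated` (tibble of scenario and one dominating
#'   witness), `objectives`, `sense = "minimise"`, and `front` (the
#'   non-dominated rows).
#' @export
pareto_front <- function(table, region = NULL,
                         objectives = .OUTCOMES) {
  if (!is.null(region)) table <- table[table$region_id == region, ]
  table <- table[table$scenario_id != "baseline", ]
  if (nrow(table) == 0) stop("no scenario rows to filter")
  m <- as.matrix(table[, objectives])
  n <- nrow(m)
  ord <- do.call(order, c(as.data.frame(m), list(table$scenario_id)))
  front_idx <- integer(0)
  witness <- rep(NA_integer_, n)
  # in lexicographic order a dominator always precedes what it dominates,
  # and dominance is transitive, so checking against the running front is
  # exhaustive
  for (i in ord) {
    dom_by <- NA_integer_
    for (j in front_idx) {
      if (all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ])) { dom_by <- j; break }
    }
    if (is.na(dom_by)) front_idx <- c(front_idx, i) else witness[i] <- dom_by
  }
  front_idx <- sort(front_idx)
  dominated_idx <- which(!is.na(witness))
  structure(list(
    non_dominated = table$scenario_id[front_idx],
    dominated = tibble::tibble(
      scenario_id = table$scenario_id[dominated_idx],
      dominated_by = table$scenario_id[witness[dominated_idx]]
    ),
    objectives = objectives,
    sense = "minimise",
    front = table[front_idx, ]
  ), class = "mhsd_pareto")
}

#' @export
print.mhsd_pareto <- function(x, ...) {
  cat("<mhsd_pareto> ", length(x$non_dominated), " non-dominated of ",
      length(x$non_dominated) + nrow(x$dominated), " scenarios (",
      paste(x$objectives, collapse = ", "), "; minimise)\n", sep = "")
  invisible(x)
}

#' Best scenario for a single outcome
#'
#' Argmin of one outcome column; ties are broken lexicographically by
#' scenario id.
#'
#' @param table outcome table rows for one region.
#' @param region optional region filter.
#' @param outcome one of `"suicides"`, `"ed_presentations"`,
#'   `"disengagements"`.
#' @return The winning scenario id.
#' @export
best_per_outcome <- function(table, region = NULL, outcome = "suicides") {
  if (!outcome %in% .OUTCOMES) stop("unknown outcome: ", outcome)
  if (!is.null(region)) table <- table[table$region_id == region, ]
  table <- table[table$scenario_id != "baseline", ]
  if (nrow(table) == 0) stop("empty outcome table")
  ord <- order(table[[outcome]], table$scenario_id)
  table$scenario_id[ord[1]]
}

#' Evaluate all intervention scenarios for a set of regions
#'
#' Runs the business-as-usual baseline once per region up to the window
#' start, then continues each scenario (intervention set switched on at the
#' window start) over the evaluation window, and assembles the outcome
#' table: counts per scenario and region (including the PHN aggregate) and
#' percent reductions against baseline.
#'
#' @param configs list of [region_config()] objects.
#' @param params an [model_params()] set shared across regions.
#' @param sets scenario table from [enumerate_sets()] (default: all 4-of-12
#'   combinations).
#' @param window evaluation window in model years (default `c(10, 20)`,
#'   2021--2031).
#' @param dt integration step.
#' @param catalogue intervention catalogue.
#' @param effect_scale optional per-program effect scaling (see
#'   [apply_interventions()]).
#' @param aggregate add PHN aggregate rows (sum over regions).
#' @return An outcome table (class `mhsd_outcomes`): one row per scenario
#'   and region with outcome counts and `pct_*` reductions; includes the
#'   baseline rows with zero reductions.
#' @export
evaluate_scenarios <- function(configs, params = model_params(),
                               sets = NULL, window = c(10, 20),
                               dt = mhsd_dt(),
                               catalogue = intervention_catalogue(),
                               effect_scale = NULL, aggregate = TRUE) {
  if (inherits(configs, "mhsd_config")) configs <- list(configs)
  if (is.null(sets)) sets <- enumerate_sets(catalogue, 4)
  rows <- vector("list", length(configs) * (nrow(sets) + 1))
  k <- 0L
  for (config in configs) {
    warm <- simulate_region(config, params, t_end = window[1], dt = dt)
    state0 <- unlist(warm[nrow(warm), c(.STOCKS, .CUMS)])
    base <- simulate_region(config, params, t_end = window[2], dt = dt,
                            init = state0, t0 = window[1])
    k <- k + 1L
    rows[[k]] <- cumulative_outcomes(base, window, "baseline")
    for (i in seq_len(nrow(sets))) {
      ids <- sets$interventions[[i]]
      if (length(ids) == 0) next
      traj <- simulate_region(config, params, interventions = ids,
                              t_end = window[2], dt = dt,
                              intervention_start = window[1],
                              init = state0, t0 = window[1],
                              catalogue = catalogue,
                              effect_scale = effect_scale)
      k <- k + 1L
      rows[[k]] <- cumulative_outcomes(traj, window, sets$scenario_id[i])
    }
  }
  out <- purrr::list_rbind(rows[seq_len(k)])
  if (aggregate && length(configs) > 1) {
    phn <- aggregate_regions(out)
    out <- dplyr::bind_rows(out, phn)
  }
  out <- dplyr::group_by(out, .data$region_id)
  out <- dplyr::mutate(
    out,
    pct_suicides = percent_reduction(
      .data$suicides[.data$scenario_id == "baseline"], .data$suicides),
    pct_ed_presentations = percent_reduction(
      .data$ed_presentations[.data$scenario_id == "baseline"],
      .data$ed_presentations),
    pct_disengagements = percent_reduction(
      .data$disengagements[.data$scenario_id == "baseline"],
      .data$disengagements)
  )
  out <- dplyr::ungroup(out)
  structure(out, class = c("mhsd_outcomes", class(out)), window = window)
}
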