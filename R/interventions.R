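# Catalogue of the 12 modelled programs and capacity levers, and the
# mapping from an intervention set to modified model parameters.

#' The intervention catalogue
#'
#' Loads the catalogue of 12 interventions: 8 programs (post-attempt
#' assertive aftercare, GP training, community education, family
#' psychoeducation, safety planning, safe-space alternatives to ED, social
#' connectedness, community-based acute care) and 4 service-capacity levers
#' (GP, psychiatrist/allied, psychiatric inpatient, CMHC). Each entry
#' declares the parameters it modifies, the transform (multiply/add/set),
#' a default effect size (an editable, literature-anchored placeholder) and,
#' for aftercare, the CMHC capacity consumed per enrolled person per week.
#'
#' @param path optional path to an alternative catalogue JSON file.
#' @return Tibble with columns `id`, `kind`, `label`, `targets` (list
#'   column of data frames with `path`, `transform`, `value`),
#'   `capacity_cost` (list column), `note`.
#' @examples
#' nrow(intervention_catalogue())  # 12
#' @export
intervention_catalogue <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "interventions.json", package = "mhsd")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tibble::tibble(
    id = vapply(raw, `[[`, character(1), "id"),
    kind = vapply(raw, `[[`, character(1), "kind"),
    label = vapply(raw, `[[`, character(1), "label"),
    targets = lapply(raw, function(e) {
      do.call(rbind, lapply(e$targets, function(tg)
        data.frame(path = tg$path, transform = tg$transform,
                   value = tg$value)))
    }),
    capacity_cost = lapply(raw, `[[`, "capacity_cost"),
    note = vapply(raw, `[[`, character(1), "note")
  )
}

#' Community-support factor
#'
#' Amplification of community-education effectiveness by active
#' social-connectedness programs: a linear multiplier `1 + 0.5 * coverage`
#' in `[0.5, 1.5]`, equal to 1 when no connectedness program is running and
#' 1.5 at full coverage.
#'
#' @param coverage connectedness program coverage in `[0, 1]`.
#' @return Dimensionless multiplier.
#' @export
community_support_factor <- function(coverage = 0) {
  pmin(1.5, pmax(0.5, 1 + 0.5 * coverage))
}

#' Apply an intervention set to the model parameters
#'
#' Produces the intervention-modified parameter set for a scenario. Effects
#' combine multiplicatively on shared rate parameters and additively on the
#' additive channels, so the result is independent of the order of `ids`.
#' Fractions pushed outside their bounds are clamped with a warning;
#' GP-pathway referral fractions are rescaled if they would exceed 1. The
#' aftercare capacity cost is recorded in `aftercare_cmhc_cost` (consumed
#' dynamically by the simulator in proportion to post-attempt enrolment).
#'
#' @param params an [model_params()] object (baseline).
#' @param ids character vector of catalogue ids (unordered, no duplicates).
#' @param catalogue the catalogue tibble (default built-in).
#' @param effect_scale optional named numeric of per-program effect scale
#'   factors (default 1): each program effect's deviation from neutral is
#'   multiplied by the factor (used by the sensitivity analysis). Capacity
#'   levers are policy settings and are never scaled.
#' @return List with `params` (modified `mhsd_params`) and `modifiers`
#'   (capacity-lever settings: `capm_gp`, `capm_specialist`,
#'   `capm_inpatient`, `cmhc_increment_per10k`).
#' @examples
#' out <- apply_interventions(model_params(),
#'                            c("safety_planning", "post_attempt_aftercare"))
#' out$params$attempt_hazard_post  # 0.25 * 0.8 * 0.8
#' @export
apply_interventions <- function(params, ids, catalogue = intervention_catalogue(),
                                effect_scale = NULL) {
  validate_params(params)
  ids <- unique(as.character(ids))
  bad <- setdiff(ids, catalogue$id)
  if (length(bad)) stop("unknown intervention id(s): ", paste(bad, collapse = ", "))
  p <- unclass(params)
  if (length(ids) == 0)
    return(list(params = params, modifiers = .lever_defaults()))

  rows <- catalogue[match(sort(ids), catalogue$id), ]
  mult <- list(); adds <- list(); sets <- list()
  for (i in seq_len(nrow(rows))) {
    sc <- 1
    if (!is.null(effect_scale) && rows$id[i] %in% names(effect_scale) &&
        rows$kind[i] == "program")
      sc <- effect_scale[[rows$id[i]]]
    tg <- rows$targets[[i]]
    for (j in seq_len(nrow(tg))) {
      path <- tg$path[j]; v <- tg$value[j]
      if (!path %in% names(p)) stop("catalogue target not in params: ", path)
      switch(tg$transform[j],
        multiply = {
          v <- 1 + sc * (v - 1)
          mult[[path]] <- (mult[[path]] %||% 1) * v
        },
        add = adds[[path]] <- (adds[[path]] %||% 0) + sc * v,
        set = {
          if (!is.null(sets[[path]]))
            stop("conflicting 'set' transforms on ", path)
          sets[[path]] <- v
        },
        stop("unknown transform: ", tg$transform[j])
      )
    }
    cost <- rows$capacity_cost[[i]]
    if (!is.null(cost)) {
      if (!identical(cost$service, "cmhc"))
        stop("capacity costs are only modelled on CMHC")
      p$aftercare_cmhc_cost <- p$aftercare_cmhc_cost +
        cost$services_per_person_week
    }
  }
  for (path in names(mult)) p[[path]] <- p[[path]] * mult[[path]]
  for (path in names(adds)) p[[path]] <- p[[path]] + adds[[path]]
  for (path in names(sets)) p[[path]] <- sets[[path]]

  # clamp fractions to their declared bounds
  for (path in intersect(names(p), .FRACTION_PARAMS)) {
    if (p[[path]] > 1 || p[[path]] < 0) {
      warning("clamping ", path, " to [0, 1]")
      p[[path]] <- min(1, max(0, p[[path]]))
    }
  }
  gp_paths <- c("frac_gp_recover", "frac_gp_specialist", "frac_gp_cmhc",
                "frac_gp_online")
  gp_sum <- sum(unlist(p[gp_paths]))
  if (gp_sum > 1) {
    warning("rescaling GP episode-end fractions to sum to 1")
    for (path in gp_paths) p[[path]] <- p[[path]] / gp_sum
  }
  if (p$attempt_hazard_in_care > p$attempt_hazard_untreated)
    p$attempt_hazard_in_care <- p$attempt_hazard_untreated

  out <- structure(p, class = "mhsd_params")
  validate_params(out)
  list(params = out,
       modifiers = list(capm_gp = p$capm_gp,
                        capm_specialist = p$capm_specialist,
                        capm_inpatient = p$capm_inpatient,
                        cmhc_increment_per10k = p$cmhc_increment_per10k))
}

.lever_defaults <- function() {
  list(capm_gp = 1, capm_specialist = 1, capm_inpatient = 1,
       cmhc_increment_per10k = 0)
}
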