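# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Annualised outcome trajectories
#'
#' Suicides, ED presentations and disengagements per year along a
#' simulated trajectory (centred one-year rolling totals).
#'
#' @param object an `mhsd_trajectory`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mhsd_trajectory <- function(object, ...) {
  ann <- annualise_trajectory(object)
  long <- tidyr::pivot_longer(
    ann[, c("time", "suicides_per_yr", "ed_presentations_per_yr",
            "disengagements_per_yr")],
    -"time", names_to = "outcome", values_to = "per_year")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time + 2011,
                                     y = .data$per_year)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~outcome, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "year", y = "events per year",
                  title = paste("Region:", attr(object, "region_id"))) +
    ggplot2::theme_minimal()
}

#' Pareto front scatter
#'
#' Non-dominated scenarios in the suicide/disengagement reduction plane,
#' sized by the ED-presentation reduction.
#'
#' @param table an `mhsd_outcomes` table.
#' @param pareto matching `mhsd_pareto` result.
#' @param region region to plot (default `"PHN"`).
#' @return A ggplot.
#' @export
plot_pareto_front <- function(table, pareto, region = "PHN") {
  tab <- table[table$region_id == region & table$scenario_id != "baseline", ]
  tab$non_dominated <- tab$scenario_id %in% pareto$non_dominated
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pct_suicides,
                                    y = .data$pct_disengagements)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$non_dominated,
                                     size = .data$pct_ed_presentations),
                        alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "suicides prevented (%)",
                  y = "disengagements prevented (%)",
                  size = "ED presentations\nprevented (%)",
                  colour = "non-dominated") +
    ggplot2::theme_minimal()
}

#' Sensitivity interval plot
#'
#' Mean percent reductions with 50% and 95% intervals per scenario and
#' outcome, from [summarise_draws()].
#'
#' @param summary tibble from [summarise_draws()].
#' @param region region to plot.
#' @return A ggplot.
#' @export
plot_sensitivity_intervals <- function(summary, region = "PHN") {
  s <- summary[summary$region_id == region, ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$scenario_id, y = .data$mean)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q2.5,
                                         ymax = .data$q97.5),
                            linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                            linewidth = 1.2, colour = "grey30") +
    ggplot2::geom_point(size = 1.8, colour = "firebrick") +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "reduction vs business as usual (%)") +
    ggplot2::theme_minimal()
}
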