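# Diagnostic ggplot2 figures.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_hline geom_pointrange
#'   geom_line facet_wrap labs position_dodge
#' @export
ggplot2::autoplot

#' Plot a design-effect decomposition
#'
#' Bar chart of the six components and their within-stratum product by
#' subpopulation; the dashed line at 1 separates variance inflation from
#' reduction.
#'
#' @param object A `df_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.df_decomposition <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = names(COMPONENT_LABELS))
  ggplot(d, aes(x = .data$component, y = .data$value, fill = .data$subpop)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "component", y = "design-effect factor", fill = "subpopulation",
         title = "Design-effect components by subpopulation")
}

#' Plot indicator estimates with jackknife intervals
#'
#' @param object A `df_estimates`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.df_estimates <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(x = .data$subpop, y = .data$prevalence)) +
    geom_pointrange(aes(ymin = .data$prevalence - 2 * .data$se,
                        ymax = .data$prevalence + 2 * .data$se)) +
    facet_wrap(~outcome, scales = "free_y") +
    labs(x = "subpopulation", y = "prevalence (Hajek, +/- 2 SE)",
         title = "Weighted indicator estimates")
}

#' Plot a coefficient-optimisation trace
#'
#' @param object A `df_coefopt`.
#' @param ... Unused.
#' @return A ggplot object showing the best objective found so far by
#'   evaluation.
#' @export
autoplot.df_coefopt <- function(object, ...) {
  tr <- object$trace
  tr$evaluation <- seq_len(nrow(tr))
  tr$best <- cummin(ifelse(is.finite(tr$objective), tr$objective, NA))
  ggplot(tr, aes(x = .data$evaluation, y = .data$best)) +
    geom_line() +
    labs(x = "objective evaluation", y = "best anticipated variance",
         title = "Targeting-coefficient optimisation trace")
}

#' Plot the targeting factor against density
#'
#' Shows how the targeting factor grows with Pacific/Asian density when the
#' meshblock and area-unit densities move together.
#'
#' @param design A [design_config()].
#' @return A ggplot object.
#' @export
plot_targeting_factor <- function(design = design_config()) {
  dens <- seq(0, 1, by = 0.01)
  d <- dplyr::bind_rows(
    tibble(density = dens, ethnicity = "pacific",
           f = targeting_factor(dens, dens, 0, 0, design$targeting_coefficients)),
    tibble(density = dens, ethnicity = "asian",
           f = targeting_factor(0, 0, dens, dens, design$targeting_coefficients))
  )
  ggplot(d, aes(x = .data$density, y = .data$f, colour = .data$ethnicity)) +
    geom_line() +
    labs(x = "meshblock = area-unit density", y = "targeting factor f",
         title = "Targeting factor vs subpopulation density")
}
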