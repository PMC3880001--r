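# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a design-effect decomposition table
#'
#' Pivots the component-by-subpopulation table to one row per component and
#' subpopulation.
#'
#' @param x A `df_decomposition`.
#' @param ... Unused.
#' @return Tibble with `component`, `description`, `subpop`, `value`.
#' @export
tidy.df_decomposition <- function(x, ...) {
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  tidyr::pivot_longer(as_tibble(x), dplyr::all_of(num),
                      names_to = "subpop", values_to = "value")
}

#' Tidy an indicator estimates table
#'
#' @param x A `df_estimates`.
#' @param ... Unused.
#' @return The underlying tibble (already one row per estimate).
#' @export
tidy.df_estimates <- function(x, ...) as_tibble(x)

#' Tidy optimised targeting coefficients
#'
#' @param x A `df_coefopt`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.df_coefopt <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' One-row summary of a coefficient optimisation
#'
#' @param x A `df_coefopt`.
#' @param ... Unused.
#' @return Tibble with `objective`, `n_evaluations`, `convergence`.
#' @export
glance.df_coefopt <- function(x, ...) {
  tibble(objective = x$objective, n_evaluations = nrow(x$trace),
         convergence = x$convergence)
}

#' One-row summary of an experiment bundle
#'
#' @param x A `df_experiment`.
#' @param ... Unused.
#' @return Tibble with replicate count, seed, config hash and the
#'   all-ethnicities variance change.
#' @export
glance.df_experiment <- function(x, ...) {
  vc <- x$variance_change
  tibble(replicates = x$provenance$replicates,
         seed = x$provenance$seed,
         config_hash = x$provenance$config_hash,
         pct_change_all = vc$pct_change[vc$subpop == "all"][1])
}
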