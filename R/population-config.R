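# Configuration objects for the synthetic population generator.

#' Specify a binary outcome to attach to a synthetic population
#'
#' Outcomes are generated from meshblock-level random prevalences so that the
#' realized overall prevalence and the within-meshblock intra-class
#' correlation (ICC) match the specification. Optional per-ethnicity
#' log-odds shifts let an outcome differ across subpopulations (the stated
#' `prevalence` then refers to the unshifted baseline).
#'
#' @param name Outcome column name.
#' @param prevalence Baseline prevalence in (0, 1).
#' @param icc Within-meshblock intra-class correlation in `[0, 1)`.
#' @param shifts Optional named numeric log-odds shifts, e.g.
#'   `c(maori = 1.1, pacific = 0.4)`.
#' @return A list of class `df_outcome_spec`.
#' @export
#' @examples
#' outcome_spec("phys_active", 0.544, icc = 0.21)
outcome_spec <- function(name, prevalence, icc = 0, shifts = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must lie strictly between 0 and 1")
  }
  if (!is.numeric(icc) || icc < 0 || icc >= 1) {
    abort("`icc` must lie in [0, 1)")
  }
  if (!is.null(shifts) && is.null(names(shifts))) {
    abort("`shifts` must be a named numeric vector")
  }
  structure(list(name = name, prevalence = prevalence, icc = icc,
                 shifts = shifts),
            class = "df_outcome_spec")
}

default_outcome_specs <- function() {
  # Prevalence/ICC magnitudes typical of adult health indicators: a highly
  # clustered behavioural indicator, a moderately clustered dietary one, and
  # a smoking indicator with strong ethnic contrast.
  list(
    outcome_spec("phys_active", 0.544, icc = 0.21),
    outcome_spec("veg_fruit", 0.442, icc = 0.06),
    outcome_spec("smoker", 0.184, icc = 0.04,
                 shifts = c(maori = 1.1, pacific = 0.45))
  )
}

#' Synthetic population configuration
#'
#' Describes the structural features of the population that the sample design
#' exploits: skewed stratum sizes (District Health Boards from about 30,000
#' to 460,000 people), meshblocks of about 40 households with a size
#' coefficient of variation near 70%, spatially clustered ethnic densities
#' that are correlated across ethnicities at meshblock level, larger average
#' household sizes for Maori/Pacific/Asian households, and electoral-roll
#' Maori-descent flags covering a configurable share of Maori adults.
#'
#' `scale` shrinks the stratum person range proportionally so that test- and
#' simulation-sized populations retain the full design's structure;
#' `total_persons` computes `scale` for you.
#'
#' @param n_strata Number of strata (District Health Boards).
#' @param stratum_person_range `(min, max)` census persons per stratum before
#'   scaling; stratum targets are log-spaced across this range.
#' @param total_persons If given, `scale` is chosen so the population totals
#'   approximately this many persons.
#' @param scale Multiplier applied to the stratum person range.
#' @param mean_households_per_mb Mean meshblock size in households.
#' @param mb_size_cv Coefficient of variation of meshblock household counts
#'   (lognormal model; the distributional form is a modelling choice).
#' @param mbs_per_au Meshblocks per area unit.
#' @param mean_household_size Mean persons per household for households with
#'   no minority ethnicity flag.
#' @param ethnic_profile Tibble with one row per ethnicity
#'   (`maori`, `pacific`, `asian`) and columns `prevalence` (person-level
#'   marginal), `clustering_sd` (latent logit-scale spatial spread) and
#'   `mean_household_size`.
#' @param target_density_correlations Named vector of target meshblock-level
#'   density correlations for the pairs `pacific_asian`, `maori_asian`,
#'   `maori_pacific`.
#' @param au_share_of_variance Share of the latent logit-scale density
#'   variance carried by the area-unit (spatially shared) component; the
#'   remainder is meshblock-level jitter around the area-unit value.
#' @param p_adult Probability that a household member beyond the first
#'   (guaranteed) adult is an adult (15+) rather than a child (0-14).
#' @param roll_coverage Fraction of Maori-descent adults whose address
#'   carries an electoral-roll Maori-descent flag (enrolment/registration
#'   coverage).
#' @param descent_extra Probability that a non-Maori-ethnicity adult
#'   nevertheless has Maori descent (descent is a broader concept than
#'   total-response ethnicity).
#' @param outcome_specs List of [outcome_spec()] objects attached at
#'   generation time.
#' @param seed Integer master seed.
#' @return An object of class `df_popconfig`.
#' @export
#' @examples
#' population_config(total_persons = 5000, seed = 42)
population_config <- function(n_strata = 21,
                              stratum_person_range = c(30000, 460000),
                              total_persons = NULL,
                              scale = 1,
                              mean_households_per_mb = 40,
                              mb_size_cv = 0.7,
                              mbs_per_au = 20,
                              mean_household_size = 2.5,
                              ethnic_profile = tibble(
                                ethnicity = c("maori", "pacific", "asian"),
                                prevalence = c(0.15, 0.07, 0.10),
                                clustering_sd = c(1.0, 1.4, 1.1),
                                mean_household_size = c(3.0, 3.6, 3.1)
                              ),
                              target_density_correlations = c(
                                pacific_asian = 0.14,
                                maori_asian = -0.15,
                                maori_pacific = 0.30
                              ),
                              au_share_of_variance = 0.3,
                              p_adult = 0.65,
                              roll_coverage = 0.8,
                              descent_extra = 0.05,
                              outcome_specs = default_outcome_specs(),
                              seed = 1L) {
  stopifnot(n_strata >= 1, length(stratum_person_range) == 2L,
            stratum_person_range[1] > 0,
            stratum_person_range[1] <= stratum_person_range[2],
            mean_households_per_mb > 0, mb_size_cv >= 0, mbs_per_au >= 1,
            mean_household_size >= 1,
            au_share_of_variance > 0, au_share_of_variance <= 1)
  assert_prob(p_adult, "p_adult")
  assert_prob(roll_coverage, "roll_coverage")
  assert_prob(descent_extra, "descent_extra")
  stopifnot(all(c("ethnicity", "prevalence", "clustering_sd",
                  "mean_household_size") %in% names(ethnic_profile)))
  if (any(ethnic_profile$prevalence < 0 | ethnic_profile$prevalence > 1)) {
    abort("ethnic prevalences must lie in [0, 1]")
  }
  if (any(abs(target_density_correlations) >= 1)) {
    abort("target density correlations must lie in (-1, 1)")
  }
  if (!is.null(total_persons)) {
    # Log-spaced stratum targets; solve for the scale that hits the total.
    targets <- exp(seq(log(stratum_person_range[1]),
                       log(stratum_person_range[2]), length.out = n_strata))
    scale <- total_persons / sum(targets)
  }
  stopifnot(scale > 0)
  for (s in outcome_specs) {
    if (!inherits(s, "df_outcome_spec")) abort("outcome_specs must be built with outcome_spec()")
  }
  structure(
    list(
      n_strata = as.integer(n_strata),
      stratum_person_range = stratum_person_range,
      scale = scale,
      mean_households_per_mb = mean_households_per_mb,
      mb_size_cv = mb_size_cv,
      mbs_per_au = as.integer(mbs_per_au),
      mean_household_size = mean_household_size,
      ethnic_profile = as_tibble(ethnic_profile),
      target_density_correlations = target_density_correlations,
      au_share_of_variance = au_share_of_variance,
      p_adult = p_adult,
      roll_coverage = roll_coverage,
      descent_extra = descent_extra,
      outcome_specs = outcome_specs,
      seed = as.integer(seed)
    ),
    class = "df_popconfig"
  )
}

#' @export
print.df_popconfig <- function(x, ...) {
  targets <- stratum_person_targets(x)
  cat("<df_popconfig>\n")
  cat(sprintf("  %d strata, target persons %s-%s (total ~%s)\n",
              x$n_strata, format(round(min(targets)), big.mark = ","),
              format(round(max(targets)), big.mark = ","),
              format(round(sum(targets)), big.mark = ",")))
  cat(sprintf("  meshblocks: mean %g households, CV %g; %d MBs per area unit\n",
              x$mean_households_per_mb, x$mb_size_cv, x$mbs_per_au))
  cat(sprintf("  ethnicities: %s\n",
              paste(sprintf("%s %.0f%%", x$ethnic_profile$ethnicity,
                            100 * x$ethnic_profile$prevalence), collapse = ", ")))
  cat(sprintf("  outcomes: %s\n",
              paste(vapply(x$outcome_specs, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

# Log-spaced stratum person targets after scaling.
stratum_person_targets <- function(config) {
  r <- config$stratum_person_range * config$scale
  if (config$n_strata == 1L) return(mean(r))
  exp(seq(log(r[1]), log(r[2]), length.out = config$n_strata))
}
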